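# plantseg3d

Simultaneous semantic and instance segmentation of single-plant 3D point
clouds, with botanical-consistency guarantees, evaluation metrics, trait
extraction and a synthetic-plant generator.

## The problem

High-throughput phenotyping reconstructs plants as 3D point clouds. To turn a
cloud into biology one must split it into organ **instances** (this leaf,
that branch) and give each instance a **semantic** class — main stem, branch,
petiole, leaf blade or apex (the bouquet of small leaves terminating a
growing axis). `plantseg3d` does both at once using spectral graph features
and explicit botanical rules, so that the result is not just a labelling but
a *botanically plausible tree of organs*: every leaf blade hangs on a
petiole, petioles sit on the stem or on branches, branches end in apices.

## The method

1. **Similarity graph.** Each point is linked to its k = 18 nearest
   neighbours; edges are weighted by inverse distance `w_ij = 1/||x_i-x_j||`.
2. **Spectral attributes.** The Fiedler eigenvector `f` of the weighted graph
   Laplacian `L = D - A` (the eigenvector of the smallest non-zero
   eigenvalue) orders points along the plant's main axis. Its *average
   directional gradient* (ADG)

   `g(i) = sum_{j in N(i)} (f(j) - f(i)) (x_j - x_i) / ||x_j - x_i||`

   has a small norm on 2-D/3-D organs (blades, apices) and follows the axis
   direction on linear organs (stem, branches, petioles).
3. **Geometric clustering.** K-means (K = 4) on `||g||` separates blades and
   apices from linear organs; region growing extracts blade/apex instances;
   linear parts are split by K-means on ADG directions (elbow-selected K) and
   adjacent clusters with similar mean directions (< 30°) are merged.
4. **Quotient graph and botany.** Contracting each cluster to a macro-node
   yields the plant's organ-level quotient graph. Blades are told from apices
   by counting local extrema of `f` (one extremum = one leaf tip). Each
   blade/apex carries a *leaf load* of 1 that accumulates along shortest
   paths to the root (the lowest node); the path with the highest
   run-counted load is the main stem. Weighted shortest paths (weight 1
   through linear nodes, infinity through botanically impossible
   adjacencies) label branches (apex paths) and petioles (blade paths),
   producing an acyclic semantic quotient tree plus a list of four kinds of
   botanical defects.
5. **Refinement.** Defective clusters are re-split locally with the relevant
   spectral attribute (norm for blade/apex clusters, direction for linear
   ones) and the semantic stage is rerun.

The package also computes per-class recall/precision/IoU/F1 and
instance-partition indices (Rand, adjusted Rand, adjusted mutual
information, completeness, homogeneity), and extracts agronomic traits:
main-stem height (Fiedler-ordered polyline), per-blade areas (least-squares
Bézier patches) and the leaf area index LAI = blade area / bounding-box base
area.

No external data are needed: `generate_plant()` builds labelled synthetic
plants (tube-sampled axes, elliptic blades, apex bouquets) with exact ground
truth, and `make_defect_fixture()` builds plants that provoke each defect
case on purpose.

## Worked example

```r
library(plantseg3d)

plant <- generate_plant(plant_spec(seed = 1))   # ~11,600 points, 5 organ classes
seg   <- run_pipeline(plant$cloud, pipeline_config(seed = 1))
seg
#> plant_segmentation: 11649 points, 30 organ instance(s), 2 defect(s)
#>
#>       apex     branch leaf_blade  main_stem    petiole
#>       1429       1008       4758       2040       2414

semantic_scores(seg$labels$class_name, plant$truth$semantic)$macro_f1
#> [1] 0.8835102

traits <- extract_traits(seg)
traits
#> trait_report: stem height 70.05, 12 blade(s), total area 1534.74, LAI 0.419
```

The printed table is the per-point class census. The macro F1 compares the
prediction against the generator's ground truth over the five classes. The trait
report gives the main-stem height in mm (the generator's true stem is
70 mm), the number of recovered blades, their total Bézier-patch area in
mm² and the dimensionless LAI. Numbers above are the actual output of this
example on this package version.

A thin command-line wrapper with subcommands `segment`, `evaluate`,
`traits`, `simulate` and `toygraph` is installed under
`system.file("cli/plantseg3d", package = "plantseg3d")`.

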