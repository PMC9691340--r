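---
title: "Graph-based organ segmentation of plant point clouds: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based organ segmentation of plant point clouds: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science implemented in `plantseg3d`: the spectral
model, the botanical rules, the tunable parameters, the synthetic data used
to validate everything, and the numerical and design choices that were
genuinely open. It states no empirical number that the test suite does not
itself compute.

## The spectral model and its assumptions

A plant scan is modelled as a weighted k-nearest-neighbour graph: nodes are
points, each point contributes directed edges to its `k = 18` nearest
neighbours, the undirected edge set is the symmetrized union, and an edge
carries weight $w_{ij} = 1/\lVert x_i - x_j\rVert$. The weighted Laplacian is
$L = D - A$ with $d_{ii} = \sum_j w_{ij}$. The degree matrix is *weighted*
even though one could also read "degree" as a neighbour count: only the
weighted form satisfies $L\,\mathbf{1} = 0$, which the spectral theory relies
on (the constant vector must be the null eigenvector). This is the single
place where the package had to commit to one of two readings of the
Laplacian definition, and it commits to the standard weighted one.

The Fiedler eigenvector $f$ — the eigenvector of the smallest non-zero
eigenvalue — assigns every point a coordinate along the dominant axis of the
graph. On a plant this is the root-to-tip axis: $f$ is monotone along the
stem, nearly constant across an organ's cross-section, and shows slope
breaks where side organs attach. Two derived attributes drive everything
downstream:

* the **ADG** (average directional gradient)
  $g(i) = \sum_{j\in N(i)} (f(j)-f(i))\,(x_j-x_i)/\lVert x_j-x_i\rVert$,
  computed over the *directed* kNN list so every node aggregates exactly
  `k` terms (no degree normalization, no edge weights). Its norm collapses
  on surface-like organs, because the flux that a thin connector must
  concentrate spreads out over a 2-D patch, and its direction follows linear
  organs;
* local extrema of $f$: every dead-end organ contains at least one strict
  local extremum (its tip), and an apex — a bouquet of leaflets — contains
  several.

Assumptions inherited from this model: the cloud samples a single connected
plant at a roughly uniform density (the kNN graph must stay within organs);
the plant's longest path runs root-to-top (otherwise the Fiedler axis is
some other axis); linear organs are thin relative to their length.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `k` | 18 | neighbours | graph connectivity vs. cost; fixed across all experiments |
| `K_norm` | 4 | clusters | K-means on $\lVert g\rVert$; the smallest-centroid cluster holds blades + apices |
| `k_max_split` | 20 | clusters | cap for elbow-selected K on ADG directions |
| `angle_threshold_deg` | 30 | degrees | stop angle for merging collinear linear clusters; density-dependent in principle |
| `min_cluster_size` | 50 | points | clusters smaller than this are fragments and get merged |
| `n_hops_extrema` | 1 | hops | extremum neighbourhood; raise to 3–5 for serrated leaf margins |
| `max_refine_iterations` | 1 | — | refinement loop cap; one pass is almost always enough |
| `seed` | 0 | — | sole source of randomness (K-means restarts) |

## From clusters to botany

The initial clustering (norm K-means, region growing, directional splits,
direction merging) gives organ-instance candidates. Contracting each cluster
gives the quotient graph; the node containing the lowest point is the root
(a manual override exists for plants with organs that sag below the stem
base). Botanical labelling then proceeds in the order: blade/apex
classification by extremum count, leaf loads, main-stem selection, branch
and petiole labelling by {1, ∞}-weighted shortest paths, defect detection.

Two systematic corrections are applied before classification. First, the
cluster holding the lowest point is forced to be linear: the stem base has a
weak field gradient and regularly falls into the low-norm cluster. Second,
clusters below `min_cluster_size` are merged into the neighbour with the
most crossing edges (preferring a neighbour that continues the fragment's
ADG direction): the geometric stage produces small by-products — blade rims
whose ADG norm rises above the coarse threshold, direction-shift bands at
junctions — and organ bodies must be complete before extrema are counted on
them.

**Extremum-free clusters.** A cluster with no local extremum at all is
ambiguous: the field flows through it, which happens both for a pass-through
band of a linear organ and for a blade whose extremal tip landed in a
neighbouring cluster. The package disambiguates by thickness: the third PCA
singular value of a surface patch is near zero, while a tube segment has
thickness of the order of the tube radius (threshold
$\sigma_3/\sigma_2 < 0.2$). Flat extremum-free clusters stay blades;
tube-like ones revert to linear and may then merge with collinear
neighbours. This replaces a blanket "default to blade" rule, which
mislabels stem and branch bands wholesale.

**Main-stem scoring.** Leaf loads are summed once per maximal run of equal
values along a path, so the score does not depend on how finely the path is
segmented (successive loads 1, 1, 5, 5 score 6, not 12). This rule
implicitly assumes the trunk stays segmented at junctions; after direction
merging a perfectly straight trunk can collapse into a *single* node, and
any path detouring through a leafy branch then picks up spurious extra runs
and out-scores the true stem. The package therefore scores candidate paths
on a junction-refined view: the Fiedler values at which leaf paths enter a
node recover the node's internal load profile, so a collapsed trunk still
contributes one run per junction. Ties prefer a path terminating in an apex
(the stem ends in the terminal bud), then the smallest node id. The terminal
apex of the winning path is remembered: its direct adjacency to the merged
stem is the axis tip and is *not* the blade-on-stem defect, and its edge to
the stem keeps weight 1.

**Deterministic paths.** All shortest paths use a deterministic BFS parent
rule (parent = smallest-id neighbour one level closer to the root), so the
union of all leaf-to-root paths is a forest by construction — the semantic
tree's acyclicity is structural, not checked-and-hoped-for.

## Defects and refinement

Four inconsistencies are detected on the labelled quotient graph: (1) a
blade (or a non-tip apex) directly on the merged stem, (2) a blade only
connected to a branch, (3) a linear node touching more than two blades or
apices (read literally: three or more), (4) two independent routes from a
blade/apex to the root (decided by edge connectivity on the full quotient
graph). Refinement re-splits the offending cluster with the attribute that
created it: K-means on the ADG norm for blade/apex clusters — locally, the
smallest-centroid sub-cluster is the surface part and the rest is the fused
linear organ — and on ADG directions for linear clusters. The terminal-bud
cluster is re-split alongside, because it tends to drag in the last stem
internode exactly as the stem base joins the low-norm cluster at the other
end. One iteration is the default; re-splitting can also *degrade* a
correct neighbouring organ (the known failure mode on synthetic data), so
the loop is capped rather than run to convergence.

## The synthetic plants

`generate_plant()` emulates a young branched forb: a vertical stem (70 mm ×
1.5 mm radius), eight petiolate leaves spiralled between 12 % and 92 % of
the stem height, two oblique branches each carrying two leaves and a
terminal apex, and a terminal bud on the stem — roughly 11,000 points at 3
points/mm². Leafy branches matter: the field gradient on an axis is driven
by the organs it subtends, so a bare branch stub has no spectral contrast
against a blade. All organs are sampled on exact surfaces (tubes, elliptic
patches, leaflet fans), so ground truth — labels, stem length, blade areas
$\pi a b (1 + \text{amplitude}^2/2)$ — is closed-form. What the generator
does **not** emulate: sensor noise beyond isotropic jitter, occlusion and
holes, curved or twisted axes, touching/overlapping canopies, soil points,
and non-uniform density. Passing tests on these clouds therefore validate
the algorithmic chain, not robustness to real scanning artefacts.

Defect fixtures force each inconsistency geometrically: petioles of 1.2 mm
(far below graph resolution) fuse a blade to the stem (case 1) or to a
branch (case 2), a whorl of three such leaves on a branch makes one linear
node touch three blades (case 3), and two leaves 26° apart at the same
height make their blades touch so region growing merges them (case 4).

## Numerical choices

* **Eigensolver.** Dense symmetric eigendecomposition up to 500 nodes;
  above that, shift-invert (sparse Cholesky of $L + \sigma I$,
  $\sigma = 10^{-6}\max_i L_{ii}$) with ARPACK, a fixed start vector and a
  pinned RNG state, making the vector bit-reproducible. The sign is fixed by
  requiring $f < 0$ at the lowest point.
* **K-means.** Fixed seed, 10 restarts, best inertia; the elbow is the point
  of maximum perpendicular distance to the first–last chord of the
  within-variance curve, ties toward smaller K.
* **Direction merging.** Energy $E = 1 - \bar D_i\cdot\bar D_j$ on running
  point-weighted means, with an *anchor* test against the dominant
  constituent's original direction to stop single-link chains of gradually
  rotating junction clusters from absorbing a 45° branch into a vertical
  stem one sub-threshold step at a time.
* **Weights as sentinels.** Botanically impossible edges carry `Inf`, never
  a large float, so "finite path" is exact.
* **Blade areas.** Least-squares tensor-product Bézier patches (bicubic by
  default) over a PCA-plane parameterization, integrated on a midpoint grid
  restricted to the convex hull of the parameter points. The bicubic patch
  smooths strongly curved rims: a full half-cylinder is recovered to within
  a few percent only at degree ≈ 6, while realistic, shallowly-curved
  blades are fine at the default. Stem height uses 20 equal-count bins along
  the Fiedler order and corrects the polyline by $B/(B-1)$ for the half-bin
  truncation at both ends.
* **Deduplication** uses voxel keying at $10^{-9}$ length units (points in
  the same tolerance cell collapse to the first).

## Problem sizes used by the test suite

Unit tests run on chains (10–200 nodes), random geometric graphs (≤ 200
nodes), single organs (a few hundred points) and a small plant of roughly
5,000 points; the end-to-end recovery checks run the full pipeline on ten
replicates of the default ~11,000-point plant and on the four defect
fixtures. These sizes were chosen to exercise every code path at desk
scale; the pipeline itself has been run on clouds an order of magnitude
larger.

## Known limitations

* Petiole boundaries are the weak spot of the whole approach:
  junction points near the stem or blade ends are regularly assigned to the
  neighbouring organ, and a petiole fused into a mis-shaped blade cluster
  can survive refinement.
* The refinement can introduce new errors while fixing others; it is capped
  at one iteration by default.
* Composed leaves (several blades per petiole), flowers and fruit have no
  classes; touching leaves are only separated indirectly via defect case 4.
* The LAI base area is the axis-aligned bounding-box base, so it is not
  invariant to arbitrary rotations about the vertical.
* Main-stem height underestimates when the last internode is carried by the
  terminal-bud cluster.
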