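Package: plantseg3d
Title: Simultaneous Semantic and Instance Segmentation of Plant 3D Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Graph-based segmentation of single-plant 3D point clouds into organ
    instances (main stem, branches, petioles, leaf blades, apices) with
    botanically consistent semantic labels. A k-nearest-neighbour similarity
    graph is built over the points, the Fiedler eigenvector of its weighted
    Laplacian and its average directional gradient (ADG) field provide spectral
    shape attributes, points are clustered into organ instances, and a quotient
    graph over the clusters is transformed into a semantic quotient tree using
    botanical rules (leaf loads, shortest paths, defect detection and local
    refinement). Includes evaluation metrics for semantic and instance
    segmentation, phenotypic trait extraction (stem height, Bezier leaf areas,
    leaf area index), and a parametric synthetic-plant generator with ground
    truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    mgcv,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
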