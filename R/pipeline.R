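# Full segmentation pipeline: similarity graph -> spectral field -> geometric
# clustering -> quotient graph -> semantic labelling -> refinement.

.CLASS_IDS <- c(main_stem = 0L, branch = 1L, petiole = 2L, leaf_blade = 3L, apex = 4L)

#' Pipeline configuration
#'
#' Holds every tunable parameter of the segmentation pipeline with its
#' default. Unknown fields are rejected.
#'
#' @param k similarity-graph neighbour count (18).
#' @param K_norm K-means clusters on the ADG norm (4).
#' @param k_max_split maximum sub-clusters per directional split (20).
#' @param angle_threshold_deg direction-merge stop angle in degrees (30).
#' @param min_cluster_size minimum quotient-node size in points (50).
#' @param n_hops_extrema neighbourhood radius for Fiedler extrema counting (1).
#' @param max_refine_iterations refinement loop cap (1).
#' @param seed master RNG seed; all pipeline randomness derives from it.
#' @param up_axis vertical axis index (3).
#' @param downsample_min_distance optional pre-processing minimum distance.
#' @param root_override optional quotient-node id to force as root.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(k = 18L, K_norm = 4L, k_max_split = 20L,
                            angle_threshold_deg = 30, min_cluster_size = 50L,
                            n_hops_extrema = 1L, max_refine_iterations = 1L,
                            seed = 0L, up_axis = 3L,
                            downsample_min_distance = NULL, root_override = NULL) {
  cfg <- list(k = as.integer(k), K_norm = as.integer(K_norm),
              k_max_split = as.integer(k_max_split),
              angle_threshold_deg = angle_threshold_deg,
              min_cluster_size = as.integer(min_cluster_size),
              n_hops_extrema = as.integer(n_hops_extrema),
              max_refine_iterations = as.integer(max_refine_iterations),
              seed = as.integer(seed), up_axis = as.integer(up_axis),
              downsample_min_distance = downsample_min_distance,
              root_override = root_override)
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a JSON file
#'
#' @param path JSON file whose keys are [pipeline_config] argument names.
#' @return A `pipeline_config`. Unknown keys raise an error.
#' @export
read_pipeline_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) .stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Run the full segmentation pipeline
#'
#' Executes: similarity-graph construction, Fiedler/ADG spectral field,
#' coarse norm clustering, region growing, elbow-selected directional
#' splitting, quotient-graph construction, direction merging, semantic
#' labelling (blade/apex classification, leaf loads, main stem, branches and
#' petioles) and the refinement loop. Fully deterministic for a given config
#' seed.
#'
#' @param points a [point_cloud] (or N x 3 matrix).
#' @param config a [pipeline_config].
#' @return An object of class `plant_segmentation`: list with `points`,
#'   `labels` (data frame: `instance_id`, `class_id`, `class_name` per
#'   point), `tree` (the `semantic_tree`), `defects`, `refinement`
#'   (the `refinement_report`), `field`, `graph`, `config`, `timings`.
#' @export
run_pipeline <- function(points, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!inherits(points, "point_cloud"))
    points <- point_cloud(points, up_axis = config$up_axis)
  if (!is.null(config$downsample_min_distance))
    points <- downsample_min_distance(points, config$downsample_min_distance)
  if (nrow(points$coords) <= config$k)
    .stopf("insufficient points: N = %d <= k = %d", nrow(points$coords), config$k)
  set.seed(config$seed)
  tic <- function() proc.time()[["elapsed"]]
  timings <- c()
  t0 <- tic()
  graph <- build_similarity_graph(points, k = config$k)
  timings["graph"] <- tic() - t0

  t0 <- tic()
  field <- compute_spectral_field(graph, points)
  timings["spectral"] <- tic() - t0

  t0 <- tic()
  clustering <- .initial_clustering(graph, field, K_norm = config$K_norm,
                                    k_max_split = config$k_max_split,
                                    seed = config$seed)
  timings["clustering"] <- tic() - t0

  t0 <- tic()
  qg <- build_quotient(graph, clustering, field)
  qg <- merge_similar_directions(qg, config$angle_threshold_deg)
  # quotient after merging is the working clustering for the semantic stage
  clustering <- list(cluster_id = qg$membership,
                     tag = ifelse(qg$nodes$tag == "blade_or_apex", "blade_or_apex", "linear"),
                     provenance = rep("merge", nrow(qg$nodes)),
                     norm_threshold = clustering$norm_threshold)
  timings["quotient"] <- tic() - t0

  t0 <- tic()
  tree <- .semantic_pass(graph, field, points, clustering, config)
  timings["semantic"] <- tic() - t0

  t0 <- tic()
  refined <- refine(graph, field, points, tree, clustering, config)
  tree <- refined$tree
  timings["refine"] <- tic() - t0

  labels <- .labels_from_tree(tree)
  structure(list(points = points, labels = labels, tree = tree,
                 defects = tree$defects, refinement = refined$report,
                 field = field, graph = graph, config = config,
                 timings = timings),
            class = "plant_segmentation")
}

# Per-point labels from the labelled quotient graph. Nodes that could not be
# assigned a final organ class (residual 'linear') are reported as branches.
.labels_from_tree <- function(tree) {
  qg <- tree$qg
  cls <- qg$nodes$class_label
  cls[cls == "linear"] <- "branch"
  name <- cls[qg$membership]
  data.frame(instance_id = qg$membership,
             class_id = unname(.CLASS_IDS[name]),
             class_name = name)
}

#' @export
print.plant_segmentation <- function(x, ...) {
  cat(sprintf("plant_segmentation: %d points, %d organ instance(s), %d defect(s)\n",
              nrow(x$points$coords), nrow(x$tree$qg$nodes), nrow(x$defects)))
  print(table(x$labels$class_name))
  invisible(x)
}
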