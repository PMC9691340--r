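# Lazy cache for expensive end-to-end runs shared by several test blocks.
.run_cache <- new.env(parent = emptyenv())

default_plant_run <- function(seed) {
  key <- paste0("plant", seed)
  if (is.null(.run_cache[[key]])) {
    pl <- generate_plant(plant_spec(seed = seed))
    seg <- suppressWarnings(run_pipeline(pl$cloud, pipeline_config(seed = seed)))
    .run_cache[[key]] <- list(pl = pl, seg = seg)
  }
  .run_cache[[key]]
}

fixture_run <- function(kind, refine = FALSE) {
  key <- paste0("fx", kind, if (refine) "r" else "")
  if (is.null(.run_cache[[key]])) {
    fx <- make_defect_fixture(kind, seed = 0)
    cfg <- pipeline_config(seed = 0,
                           max_refine_iterations = if (refine) 1L else 0L)
    seg <- suppressWarnings(run_pipeline(fx$cloud, cfg))
    .run_cache[[key]] <- list(fx = fx, seg = seg)
  }
  .run_cache[[key]]
}

# classes on a blade/apex node's finite-weight tree path to the root
tree_path_classes <- function(seg, v) {
  qg <- seg$tree$qg
  fin <- qg$edges[is.finite(qg$edges$weight), , drop = FALSE]
  adj <- plantseg3d:::.adj_list(nrow(qg$nodes), as.matrix(fin[c("a", "b")]))
  bfs <- plantseg3d:::.bfs_parents(adj, qg$root_id)
  path <- plantseg3d:::.path_to_root(bfs, v, qg$root_id)
  if (is.null(path)) return(NULL)
  qg$nodes$class_label[path[-1L]]  # classes after the blade itself
}
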