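test_that("defect detection covers the four botanical cases", {
  # case 1: blade adjacent to the merged stem
  q1 <- quotient_graph(c("leaf_blade", "main_stem"), rbind(c(1, 2)), root_id = 2)
  q1$edges$weight <- Inf
  d1 <- detect_defects(structure(list(qg = q1), class = "semantic_tree"))
  expect_true(1L %in% d1$case_id)

  # case 2: blade only connected to a branch
  q2 <- quotient_graph(c("leaf_blade", "branch", "main_stem"),
                       rbind(c(1, 2), c(2, 3)), root_id = 3)
  q2$edges$weight <- c(Inf, 1)
  d2 <- detect_defects(structure(list(qg = q2), class = "semantic_tree"))
  expect_true(2L %in% d2$case_id)

  # case 3: a linear node touching three blades
  q3 <- quotient_graph(c("leaf_blade", "leaf_blade", "leaf_blade", "branch", "main_stem"),
                       rbind(c(1, 4), c(2, 4), c(3, 4), c(4, 5)), root_id = 5)
  q3$edges$weight <- 1
  d3 <- detect_defects(structure(list(qg = q3), class = "semantic_tree"))
  expect_true(3L %in% d3$case_id)

  # case 4: two routes from a blade to the root
  q4 <- quotient_graph(c("leaf_blade", "petiole", "petiole", "main_stem"),
                       rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 4)), root_id = 4)
  q4$edges$weight <- 1
  d4 <- detect_defects(structure(list(qg = q4), class = "semantic_tree"))
  expect_true(4L %in% d4$case_id)

  # a clean tree yields no defect
  q0 <- quotient_graph(c("leaf_blade", "petiole", "main_stem"),
                       rbind(c(1, 2), c(2, 3)), root_id = 3)
  q0$edges$weight <- 1
  expect_equal(nrow(detect_defects(structure(list(qg = q0), class = "semantic_tree"))), 0)
})

test_that("refinement is a fixed point on defect-free input", {
  out <- generate_plant(small_plant_spec())
  g <- build_similarity_graph(out$cloud, k = 18)
  sf <- compute_spectral_field(g, out$cloud)
  cl <- plantseg3d:::.initial_clustering(g, sf, seed = 0L)
  qg0 <- build_quotient(g, cl, sf)
  qg0 <- merge_similar_directions(qg0, 30)
  clustering <- list(cluster_id = qg0$membership, tag = qg0$nodes$tag,
                     norm_threshold = cl$norm_threshold)
  cfg <- pipeline_config(seed = 0)
  tree <- suppressWarnings(plantseg3d:::.semantic_pass(g, sf, out$cloud, clustering, cfg))
  # force the no-defect branch by emptying the defect list
  tree0 <- tree
  tree0$defects <- tree$defects[0, , drop = FALSE]
  r0 <- refine(g, sf, out$cloud, tree0, clustering, cfg)
  expect_equal(r0$report$iterations_run, 0L)
  expect_identical(r0$tree$qg$membership, tree0$qg$membership)

  # max_iterations = 0 never touches anything, defects carried through
  rcap <- refine(g, sf, out$cloud, tree, clustering, cfg, max_iterations = 0L)
  expect_equal(rcap$report$iterations_run, 0L)
  expect_equal(rcap$report$defects_before, rcap$report$defects_after)
})

test_that("refinement only relabels: coordinates and partition survive", {
  out <- generate_plant(small_plant_spec())
  seg <- suppressWarnings(run_pipeline(out$cloud, pipeline_config(seed = 0)))
  n <- nrow(out$cloud$coords)
  expect_equal(seg$points$coords, out$cloud$coords)
  expect_equal(length(seg$labels$instance_id), n)
  expect_equal(sort(unique(seg$labels$instance_id)),
               seq_len(max(seg$labels$instance_id)))
})
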