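# petiole tube ending in a blade (or an apex bouquet) for extremum counting
organ_fixture <- function(tip = c("blade", "apex", "serrated"), seed = 3) {
  set.seed(seed)
  d <- c(1, 0, 0.3) / sqrt(1.09)
  tube <- plantseg3d:::.sample_tube(c(0, 0, 0), d, 12, 0.7, 6)
  tippts <- switch(match.arg(tip),
    blade = plantseg3d:::.sample_blade(12 * d, d, c(0, 1, 0), 9, 5.4, 6),
    serrated = plantseg3d:::.sample_blade(12 * d, d, c(0, 1, 0), 9, 5.4, 6,
                                          serration = c(0.3, 7)),
    apex = plantseg3d:::.sample_apex(12 * d, d, 3.2, 6, 6))
  pc <- point_cloud(rbind(tube, tippts))
  g <- build_similarity_graph(pc, k = 18)
  sf <- compute_spectral_field(g, pc)
  memb <- c(rep(1L, nrow(tube)), rep(2L, nrow(tippts)))
  qg <- build_quotient(g, list(cluster_id = memb, tag = c("linear", "blade_or_apex")), sf)
  list(qg = qg, g = g, sf = sf, pc = pc)
}

test_that("one Fiedler extremum means leaf blade, several mean apex", {
  fb <- organ_fixture("blade")
  expect_equal(classify_blade_vs_apex(fb$qg, fb$g, fb$sf)$nodes$class_label[2],
               "leaf_blade")
  fa <- organ_fixture("apex")
  expect_equal(classify_blade_vs_apex(fa$qg, fa$g, fa$sf)$nodes$class_label[2],
               "apex")
})

test_that("serrated margins need a larger extremum neighbourhood", {
  fs <- organ_fixture("serrated")
  expect_equal(classify_blade_vs_apex(fs$qg, fs$g, fs$sf, n_hops = 1)$nodes$class_label[2],
               "apex")        # teeth masquerade as extra tips
  expect_equal(classify_blade_vs_apex(fs$qg, fs$g, fs$sf, n_hops = 5)$nodes$class_label[2],
               "leaf_blade")  # widened neighbourhood absorbs the teeth
})

test_that("leaf loads propagate along deterministic shortest paths", {
  # root(5) - s(4) - s(3) + two leaves hanging from node 3 via petioles 1, 2
  qg <- quotient_graph(
    class_label = c("linear", "linear", "linear", "linear", "linear",
                    "leaf_blade", "leaf_blade"),
    edges = rbind(c(5, 4), c(4, 3), c(3, 1), c(3, 2), c(1, 6), c(2, 7)),
    root_id = 5)
  qg <- compute_leaf_loads(qg)
  expect_equal(qg$nodes$leaf_load, c(1L, 1L, 2L, 2L, 2L, 1L, 1L))
  expect_equal(qg$leaf_paths[["6"]], c(6L, 1L, 3L, 4L, 5L))

  # an unreachable blade is recorded and loads stay put
  qg2 <- quotient_graph(c("linear", "leaf_blade", "leaf_blade"),
                        rbind(c(1, 2)), root_id = 1)
  qg2 <- compute_leaf_loads(qg2)
  expect_equal(attr(qg2$leaf_paths, "unreachable"), 3L)
  expect_equal(qg2$nodes$leaf_load, c(1L, 1L, 1L))
})

test_that("path scores count each run of equal loads once", {
  expect_equal(path_load_score(c(1, 1, 5, 5)), 6)
  expect_equal(path_load_score(c(2, 2, 2)), 2)
  expect_equal(path_load_score(c(1, 2, 3)), 6)
  expect_equal(path_load_score(integer(0)), 0)
})

test_that("the highest-scoring path becomes the merged main stem", {
  # chain: blade 1 - petiole 2 - stem 3 - stem 4 - root 5; apex 6 at the top
  qg <- quotient_graph(
    c("leaf_blade", "linear", "linear", "linear", "linear", "apex"),
    rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(6, 3)),
    root_id = 5)
  qg <- compute_leaf_loads(qg)
  qg <- identify_main_stem(qg)
  stem <- which(qg$nodes$class_label == "main_stem")
  expect_length(stem, 1)  # stem nodes merged into one
  expect_equal(qg$nodes$class_label[qg$stem_apex_id], "apex")
  expect_error(identify_main_stem(quotient_graph("linear", matrix(0, 0, 2), 1)),
               "no stem candidate")
})

test_that("branch and petiole labels follow the weighted shortest paths", {
  # root=4(stem, merged) - linear 2 - blade 1 ; root - linear 3 - apex 5
  mk <- function() {
    qg <- quotient_graph(c("leaf_blade", "linear", "linear", "main_stem", "apex"),
                         rbind(c(1, 2), c(2, 4), c(3, 4), c(3, 5)), root_id = 4)
    qg <- compute_leaf_loads(qg)
    qg
  }
  tr <- label_branches_and_petioles(mk(), min_cluster_size = 0L)
  expect_equal(tr$qg$nodes$class_label, c("leaf_blade", "petiole", "branch",
                                          "main_stem", "apex"))
  expect_equal(nrow(tr$defects), 0)
  # the finite-weight subgraph spans the used paths and is a forest
  expect_equal(nrow(tr$tree_edges), 4)

  # blade wired straight to the merged stem raises defect case 1
  qgd <- quotient_graph(c("leaf_blade", "main_stem"), rbind(c(1, 2)), root_id = 2)
  qgd <- compute_leaf_loads(qgd)
  trd <- label_branches_and_petioles(qgd, min_cluster_size = 0L)
  expect_true(1L %in% trd$defects$case_id)
})

test_that("semantic trees from full runs are acyclic with plausible paths", {
  out <- generate_plant(small_plant_spec())
  seg <- suppressWarnings(run_pipeline(out$cloud, pipeline_config(seed = 0)))
  te <- seg$tree$tree_edges
  gt <- igraph::make_empty_graph(nrow(seg$tree$qg$nodes), directed = FALSE)
  gt <- igraph::add_edges(gt, rbind(te$a, te$b))
  expect_true(igraph::is_forest(gt))
  cls <- seg$tree$qg$nodes$class_label
  expect_true(all(cls %in% c("linear", "leaf_blade", "apex", "main_stem",
                             "branch", "petiole")))
})
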