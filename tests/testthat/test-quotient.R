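# Y-shaped cloud: vertical stem with two arms leaving from its top
y_cloud <- function() {
  set.seed(11)
  stem <- plantseg3d:::.sample_tube(c(0, 0, 0), c(0, 0, 1), 25, 1, 6)
  armA <- plantseg3d:::.sample_tube(c(0, 0, 25), c(0.7, 0, 0.7), 18, 1, 6)
  armB <- plantseg3d:::.sample_tube(c(0, 0, 25), c(-0.7, 0, 0.7), 18, 1, 6)
  pc <- point_cloud(rbind(stem, armA, armB))
  memb <- c(rep(1L, nrow(stem)), rep(2L, nrow(armA)), rep(3L, nrow(armB)))
  list(pc = pc, memb = memb)
}

test_that("quotient construction: nodes, adjacency, cross-edge counts", {
  y <- y_cloud()
  g <- build_similarity_graph(y$pc, k = 18)
  sf <- compute_spectral_field(g, y$pc)
  qg <- build_quotient(g, list(cluster_id = y$memb, tag = rep("linear", 3)), sf)
  expect_equal(nrow(qg$nodes), 3)
  expect_equal(nrow(qg$edges), 3)  # arms meet the stem and each other at the fork
  # stem--armA edge count equals the hand count of crossing edges
  cross <- sum((y$memb[g$edges[, 1]] == 1 & y$memb[g$edges[, 2]] == 2) |
               (y$memb[g$edges[, 1]] == 2 & y$memb[g$edges[, 2]] == 1))
  e <- qg$edges[qg$edges$a == 1 & qg$edges$b == 2, ]
  expect_equal(e$n_cross, cross)
  # mean directions are unit vectors
  expect_equal(sqrt(rowSums(qg$mean_dir^2)), rep(1, 3), tolerance = 1e-10)

  # a single cluster gives one node and no edges
  qg1 <- build_quotient(g, list(cluster_id = rep(1L, g$n), tag = "linear"), sf)
  expect_equal(nrow(qg1$nodes), 1)
  expect_equal(nrow(qg1$edges), 0)
})

test_that("root selection picks the lowest node, override wins, ties break low", {
  y <- y_cloud()
  g <- build_similarity_graph(y$pc, k = 18)
  qg <- build_quotient(g, list(cluster_id = y$memb, tag = rep("linear", 3)), NULL)
  qg <- select_root(qg, y$pc)
  expect_equal(qg$root_id, 1)  # the stem holds the lowest point
  expect_equal(select_root(qg, y$pc, override = 3)$root_id, 3)
  expect_error(select_root(qg, y$pc, override = 9), "not a node")
})

test_that("direction merging collapses collinear nodes and stops at the angle", {
  mk <- function(dirs, edges) {
    qg <- quotient_graph(rep("linear", nrow(dirs)), edges, root_id = 1,
                        n_points = rep(10L, nrow(dirs)))
    qg$mean_dir <- qg$anchor_dir <- dirs
    plantseg3d:::.qg_update_energies(qg)
  }
  # identical directions merge
  q <- mk(rbind(c(0, 0, 1), c(0, 0, 1)), rbind(c(1, 2)))
  expect_equal(nrow(merge_similar_directions(q)$nodes), 1)
  # perpendicular directions never merge
  q2 <- mk(rbind(c(0, 0, 1), c(1, 0, 0)), rbind(c(1, 2)))
  expect_equal(nrow(merge_similar_directions(q2)$nodes), 2)
  # a collinear chain of three collapses to one
  q3 <- mk(rbind(c(0, 0, 1), c(0, 0, 1), c(0, 0, 1)), rbind(c(1, 2), c(2, 3)))
  expect_equal(nrow(merge_similar_directions(q3)$nodes), 1)
  # 20 degrees merges under the default 30-degree threshold, 40 does not
  th <- 20 * pi / 180
  q4 <- mk(rbind(c(0, 0, 1), c(sin(th), 0, cos(th))), rbind(c(1, 2)))
  expect_equal(nrow(merge_similar_directions(q4)$nodes), 1)
  th <- 40 * pi / 180
  q5 <- mk(rbind(c(0, 0, 1), c(sin(th), 0, cos(th))), rbind(c(1, 2)))
  expect_equal(nrow(merge_similar_directions(q5)$nodes), 2)
})

test_that("merging preserves the point partition and is idempotent to rebuild", {
  out <- generate_plant(small_plant_spec())
  g <- build_similarity_graph(out$cloud, k = 18)
  sf <- compute_spectral_field(g, out$cloud)
  cl <- plantseg3d:::.initial_clustering(g, sf, seed = 0L)
  qg <- build_quotient(g, cl, sf)
  n0 <- nrow(qg$nodes)
  qgm <- merge_similar_directions(qg, 30)
  expect_lte(nrow(qgm$nodes), n0)
  n <- nrow(out$cloud$coords)
  expect_equal(length(qgm$membership), n)
  expect_equal(sum(qgm$nodes$n_points), n)
  expect_equal(sort(unique(qgm$membership)), qgm$nodes$node_id)
  # rebuilding the quotient from the merged membership reproduces the graph
  cl2 <- list(cluster_id = qgm$membership, tag = qgm$nodes$tag)
  qg2 <- build_quotient(g, cl2, sf)
  expect_equal(qg2$edges[c("a", "b", "n_cross")], qgm$edges[c("a", "b", "n_cross")])
  expect_equal(qg2$nodes$n_points, qgm$nodes$n_points)
})
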