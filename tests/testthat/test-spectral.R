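test_that("Fiedler pair matches the dense oracle on closed-form graphs", {
  # unweighted 3-node path: lambda = 1, f proportional to (1, 0, -1)/sqrt(2)
  g <- build_similarity_graph(chain_cloud(3), k = 1)
  sf <- compute_fiedler(g, chain_cloud(3))
  expect_equal(sf$lambda_f, 1, tolerance = 1e-12)
  expect_equal(abs(sf$fiedler), c(1, 0, 1) / sqrt(2), tolerance = 1e-10)
  expect_lt(sf$fiedler[1], 0)  # sign convention: negative at the lowest point

  # complete triangle with weight w: lambda = 3w; eigen residual tiny
  w <- 2.5
  coords <- rbind(c(0, 0, 0), c(1 / w, 0, 0.0001), c(0.5 / w, sqrt(3) / (2 * w), 0.0002))
  pc <- point_cloud(coords, dedup_tol = 1e-12)
  gt <- build_similarity_graph(pc, k = 2)
  sft <- compute_fiedler(gt, pc)
  L <- as.matrix(plantseg3d:::.graph_laplacian(gt))
  expect_lt(max(abs(L %*% sft$fiedler - sft$lambda_f * sft$fiedler)), 1e-8)
  expect_lt(abs(sum(sft$fiedler)), 1e-10)
  expect_equal(sum(sft$fiedler^2), 1, tolerance = 1e-12)
})

test_that("disconnected graphs are refused", {
  blobA <- matrix(runif(30), ncol = 3)
  pcA <- point_cloud(blobA)
  g <- build_similarity_graph(pcA, k = 3)
  # fake a second component by removing bridge edges directly
  g2 <- g
  g2$g <- igraph::delete_edges(g$g, igraph::E(g$g))
  g2$g <- igraph::add_edges(g2$g, c(1, 2))
  expect_error(compute_fiedler(g2, pcA), "not connected")
})

test_that("sparse shift-invert solver agrees with the dense oracle", {
  for (seed in 1:6) {
    n <- sample(40:200, 1)
    g <- random_connected_graph(n, k = 4L, seed = seed)
    pc_dummy <- structure(list(coords = matrix(seq_len(3 * n), ncol = 3), up_axis = 3L),
                          class = "point_cloud")
    sp <- compute_fiedler(g, pc_dummy, method = "arpack")
    or <- dense_fiedler_oracle(g)
    expect_equal(sp$lambda_f, or$lambda, tolerance = 1e-8)
    dv <- min(max(abs(sp$fiedler - or$vector)), max(abs(sp$fiedler + or$vector)))
    expect_lt(dv, 1e-8)
  }
})

test_that("Fiedler values are strictly monotone along a uniform chain", {
  for (n in c(10, 57, 200)) {
    g <- build_similarity_graph(chain_cloud(n), k = 2)
    f <- compute_fiedler(g, chain_cloud(n))$fiedler
    expect_true(all(diff(f) > 0))
  }
})

test_that("second differences along the main chain peak at the attachments", {
  tg <- toy_chain_graph(100, 20, attachments = c(30, 60))
  expect_equal(tg$graph$n, 140)
  expect_equal(nrow(tg$graph$edges), 139)
  f <- compute_fiedler(tg$graph, tg$coords)$fiedler
  d2 <- abs(diff(diff(f[1:100])))
  centre <- order(d2, decreasing = TRUE)[1:2] + 1L  # node at the centre of each triple
  expect_setequal(centre, c(30, 60))
})

test_that("ADG matches the closed form on a uniform chain", {
  n <- 30; d <- 0.7; s <- 2.3
  pc <- chain_cloud(n, spacing = d, axis = c(1, 0, 0))
  g <- build_similarity_graph(pc, k = 2)
  field <- structure(list(fiedler = s * d * (seq_len(n) - 1), lambda_f = 1,
                          adg = NULL, adg_norm = NULL), class = "spectral_field")
  field <- compute_adg(g, field, pc)
  interior <- 3:(n - 2)  # nodes whose two nearest neighbours flank them
  expect_equal(field$adg_norm[interior], rep(2 * s * d, length(interior)),
               tolerance = 1e-9)
  expect_equal(abs(field$adg[interior, 1]) / field$adg_norm[interior],
               rep(1, length(interior)), tolerance = 1e-9)

  # all neighbours share f: gradient vanishes
  fconst <- structure(list(fiedler = rep(1, n), lambda_f = 1, adg = NULL,
                           adg_norm = NULL), class = "spectral_field")
  expect_equal(compute_adg(g, fconst, pc)$adg_norm, rep(0, n))

  # chain endpoint with k = 2 sums its two same-side neighbours:
  # (f2-f1) + (f3-f1) toward +x gives s*d + 2*s*d
  expect_equal(field$adg[1, ], c(3 * s * d, 0, 0), tolerance = 1e-9)

  # with k = 1 the endpoint has a single neighbour: one-term sum
  g1 <- build_similarity_graph(pc, k = 1)
  f1 <- compute_adg(g1, field, pc)
  expect_equal(f1$adg[1, ], c(s * d, 0, 0), tolerance = 1e-9)
})
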