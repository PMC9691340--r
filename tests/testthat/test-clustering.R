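field_with_norms <- function(x) {
  structure(list(fiedler = NULL, lambda_f = NULL, adg = NULL, adg_norm = x),
            class = "spectral_field")
}

test_that("norm K-means isolates the smallest-centroid cluster", {
  x <- rep(c(0.01, 1, 2, 3), each = 20)
  cl <- cluster_by_norm(field_with_norms(x), K = 4, seed = 1)
  blade <- which(cl$tag == "blade_or_apex")
  expect_length(blade, 1)
  expect_setequal(which(cl$cluster_id == blade), 1:20)

  expect_warning(cl2 <- cluster_by_norm(field_with_norms(rep(1, 10))), "degenerate")
  expect_equal(cl2$tag, "blade_or_apex")

  expect_warning(cl3 <- cluster_by_norm(field_with_norms(rep(c(1, 5), 10)), K = 4),
                 "distinct")
})

test_that("region growing returns components ordered by smallest index", {
  set.seed(13)
  # three blobs; bridges connect the smaller blobs to the largest (C), so a
  # mask over A and B still has two graph components
  blobA <- matrix(runif(45), ncol = 3)
  blobB <- matrix(runif(45), ncol = 3) + 50
  blobC <- matrix(runif(90), ncol = 3) + 100
  pc <- point_cloud(rbind(blobA, blobB, blobC))
  g <- build_similarity_graph(pc, k = 4)
  inst <- extract_instances_region_growing(g, seq_len(30))
  expect_length(inst, 2)
  expect_equal(min(inst[[1]]), 1)
  expect_length(extract_instances_region_growing(g, 1:15), 1)
  expect_length(extract_instances_region_growing(g, integer(0)), 0)
})

test_that("elbow selection maximizes perpendicular chord distance", {
  brute <- function(v) {
    m <- length(v)
    d <- sapply(seq_len(m), function(K) {
      p0 <- c(1, v[1]); p1 <- c(m, v[m]); p <- c(K, v[K])
      u <- p1 - p0
      abs(u[2] * (p[1] - p0[1]) - u[1] * (p[2] - p0[2])) / sqrt(sum(u^2))
    })
    which.max(d)
  }
  v1 <- c(100, 10, 9.5, 9.3, 9.2)
  expect_equal(select_k_elbow(v1), 2)
  expect_equal(select_k_elbow(v1), brute(v1))
  for (seed in 1:5) {
    set.seed(seed)
    v <- sort(rexp(10, 0.1), decreasing = TRUE)
    expect_equal(select_k_elbow(v), brute(v))
  }
  expect_equal(select_k_elbow(seq(100, 10, length.out = 8)), 1)  # linear: ties -> 1
  expect_equal(select_k_elbow(c(5, 3)), 2)                        # argmin fallback
})

test_that("direction splitting separates perpendicular arms", {
  set.seed(5)
  armA <- plantseg3d:::.sample_tube(c(0, 0, 0), c(0, 0, 1), 30, 1, 6)
  armB <- plantseg3d:::.sample_tube(c(0, 0, 30), c(1, 0, 0), 30, 1, 6)
  pc <- point_cloud(rbind(armA, armB))
  g <- build_similarity_graph(pc, k = 18)
  sf <- compute_spectral_field(g, pc)
  subs <- split_by_direction(g, sf, seq_len(nrow(pc$coords)), seed = 1)
  expect_gt(length(subs), 1)
  arm_of <- c(rep(1L, nrow(armA)), rep(2L, nrow(armB)))
  purity <- vapply(subs, function(s) max(table(arm_of[s])) / length(s), numeric(1))
  # point-weighted share of arm-pure sub-clusters
  frac_pure <- sum(lengths(subs)[purity >= 0.95]) / nrow(pc$coords)
  expect_gt(frac_pure, 0.9)

  # a straight tube stays whole (elbow selects K = 1)
  pcs <- point_cloud(armA)
  gs <- build_similarity_graph(pcs, k = 18)
  sfs <- compute_spectral_field(gs, pcs)
  expect_length(split_by_direction(gs, sfs, seq_len(nrow(armA)), seed = 1), 1)

  # a tiny connected cluster is kept whole (size guard)
  pair <- c(1L, g$knn[1, 1])
  expect_length(split_by_direction(g, sf, pair, seed = 1), 1)
})

test_that("the initial clustering is a partition into connected clusters", {
  out <- generate_plant(small_plant_spec())
  g <- build_similarity_graph(out$cloud, k = 18)
  sf <- compute_spectral_field(g, out$cloud)
  cl <- plantseg3d:::.initial_clustering(g, sf, seed = 0L)
  n <- nrow(out$cloud$coords)
  expect_equal(sort(unique(cl$cluster_id)), seq_len(max(cl$cluster_id)))
  expect_equal(length(cl$cluster_id), n)
  expect_true(all(tabulate(cl$cluster_id) > 0))
  for (id in unique(cl$cluster_id)) {
    comp <- extract_instances_region_growing(g, which(cl$cluster_id == id))
    expect_length(comp, 1)
  }
})
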