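# Shared fixture builders. Everything is generated in code; nothing is read
# from disk.

# small plant for fast end-to-end checks (~5k points)
small_plant_spec <- function(seed = 0L) {
  plant_spec(stem_length = 50, n_branches = 1, branch_lengths = 18,
             branch_angles = 45, branch_heights = 0.5, branch_azimuths = 200,
             branch_leaf_fracs = 0.55,
             n_leaves = 4, leaf_heights = c(0.2, 0.42, 0.64, 0.86),
             leaf_azimuths = c(90, 210, 330, 60), seed = seed)
}

# straight tube cloud along +z
tube_cloud <- function(len = 70, radius = 1.5, density = 6, seed = 1L) {
  set.seed(seed)
  point_cloud(plantseg3d:::.sample_tube(c(0, 0, 0), c(0, 0, 1), len, radius, density))
}

# uniformly spaced chain along an axis, as a point cloud
chain_cloud <- function(n, spacing = 1, axis = c(0, 0, 1)) {
  point_cloud(outer(seq_len(n) - 1, axis * spacing))
}

# all set partitions of n elements, as integer label vectors
all_partitions <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_partitions(n - 1L)) {
    k <- max(p)
    for (g in seq_len(k + 1L)) out[[length(out) + 1L]] <- c(p, g)
  }
  out
}

# brute-force Rand / adjusted Rand by enumerating all point pairs
pair_rand_oracle <- function(x, y) {
  n <- length(x)
  same_x <- outer(x, x, "==")[upper.tri(diag(n))]
  same_y <- outer(y, y, "==")[upper.tri(diag(n))]
  agree <- sum(same_x == same_y)
  npairs <- n * (n - 1) / 2
  rand <- agree / npairs
  # ARI from pair counts
  n11 <- sum(same_x & same_y)
  nx <- sum(same_x); ny <- sum(same_y)
  exp11 <- nx * ny / npairs
  max11 <- (nx + ny) / 2
  ari <- if (max11 == exp11) 1 else (n11 - exp11) / (max11 - exp11)
  list(rand = rand, ari = ari)
}

# worst deviation of rand/ARI from the pair-enumeration oracle over every
# pair of set partitions of 1..nmax points
max_dev_vs_pair_oracle <- function(nmax) {
  worst <- 0
  for (n in seq(2L, nmax)) {
    parts <- all_partitions(n)
    for (i in seq_along(parts)) for (j in seq_along(parts)) {
      sc <- instance_scores(parts[[i]], parts[[j]])
      or <- pair_rand_oracle(parts[[i]], parts[[j]])
      worst <- max(worst, abs(sc$rand - or$rand), abs(sc$adjusted_rand - or$ari))
    }
  }
  worst
}

# dense-eigendecomposition Fiedler oracle for any similarity_graph-like object
dense_fiedler_oracle <- function(graph) {
  L <- as.matrix(plantseg3d:::.graph_laplacian(graph))
  e <- eigen(L, symmetric = TRUE)
  list(lambda = e$values[graph$n - 1L], vector = e$vectors[, graph$n - 1L])
}

# random connected geometric graph on <= nmax points
random_connected_graph <- function(n, k = 4L, seed = 1L) {
  set.seed(seed)
  pc <- point_cloud(matrix(rnorm(3 * n), ncol = 3))
  build_similarity_graph(pc, k = k)  # bridging enforces connectivity
}
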