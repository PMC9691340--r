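#' Build the kNN similarity graph of a point cloud
#'
#' Each point is linked to its `k` nearest neighbours; the undirected edge set
#' is the symmetrized union of the directed kNN lists and each edge carries a
#' weight equal to the inverse of the Euclidean distance between its two
#' endpoints. If the symmetrized graph is disconnected, each smaller component
#' is bridged to the largest one through the single shortest inter-component
#' link (repeated until connected); the added bridges are reported in the
#' returned object.
#'
#' @param points a [point_cloud] (or N x 3 coordinate matrix).
#' @param k number of nearest neighbours (default 18).
#' @return An object of class `similarity_graph` with elements `knn`
#'   (N x k directed neighbour index matrix), `knn_dist`, `edges` (E x 2),
#'   `weights` (1/distance), `k`, `g` (the symmetrized weighted
#'   \pkg{igraph} graph) and `bridges` (data frame of repair edges).
#' @export
build_similarity_graph <- function(points, k = 18L) {
  xyz <- .as_coords(points)
  n <- nrow(xyz)
  k <- as.integer(k)
  if (n <= k) .stopf("insufficient points: N = %d <= k = %d", n, k)
  nn <- .knn_brute(xyz, k)
  if (any(nn$dist == 0))
    .stopf("duplicate points at zero distance; deduplicate the cloud first (see point_cloud())")

  # symmetrized undirected edge set: union of directed pairs
  ii <- rep(seq_len(n), times = k)
  jj <- as.vector(nn$idx)
  dd <- as.vector(nn$dist)
  a <- pmin(ii, jj); b <- pmax(ii, jj)
  dup <- duplicated(cbind(a, b))
  edges <- cbind(a[!dup], b[!dup])
  dists <- dd[!dup]
  ord <- order(edges[, 1], edges[, 2])
  edges <- edges[ord, , drop = FALSE]
  dists <- dists[ord]
  weights <- 1 / dists

  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::E(g)$weight <- weights

  bridges <- data.frame(i = integer(0), j = integer(0), dist = numeric(0))
  comp <- igraph::components(g)
  while (comp$no > 1L) {
    main <- which.max(comp$csize)
    others <- setdiff(seq_len(comp$no), main)
    # bridge the first (smallest point index) smaller component, then recompute
    cmp_id <- others[[1L]]
    a_idx <- which(comp$membership == cmp_id)
    b_idx <- which(comp$membership == main)
    lk <- .nearest_between(xyz, as.integer(a_idx), as.integer(b_idx))
    bridges <- rbind(bridges, data.frame(i = lk[1], j = lk[2], dist = lk[3]))
    edges <- rbind(edges, c(min(lk[1:2]), max(lk[1:2])))
    weights <- c(weights, 1 / lk[3])
    g <- igraph::add_edges(g, c(lk[1], lk[2]), weight = 1 / lk[3])
    comp <- igraph::components(g)
  }

  structure(list(knn = nn$idx, knn_dist = nn$dist, edges = edges,
                 weights = weights, k = k, g = g, bridges = bridges, n = n),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("similarity_graph: %d nodes, %d undirected edges, k = %d, %d bridge(s)\n",
              x$n, nrow(x$edges), x$k, nrow(x$bridges)))
  invisible(x)
}

# Sparse weighted Laplacian L = D - A with weighted degrees (so L %*% 1 = 0).
.graph_laplacian <- function(graph) {
  n <- graph$n
  e <- graph$edges
  w <- graph$weights
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = c(w, w), dims = c(n, n))
  Matrix::Diagonal(n, Matrix::rowSums(A)) - A
}

#' Export a similarity graph as an edge-list text file
#'
#' One line per undirected edge: `i j w` with 0-based node ids.
#'
#' @param graph a `similarity_graph`.
#' @param path output path.
#' @export
export_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "similarity_graph"))
  writeLines(sprintf("%d %d %.10g", graph$edges[, 1] - 1L, graph$edges[, 2] - 1L,
                     graph$weights), path)
  invisible(path)
}
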