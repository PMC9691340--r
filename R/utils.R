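# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Normalize matrix rows to unit length; zero rows stay zero.
.unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nz <- nrm > 0
  m[nz, ] <- m[nz, , drop = FALSE] / nrm[nz]
  m
}

# Run an expression with a fixed RNG state, restoring the caller's state after.
# Used where a dependency draws from R's RNG (ARPACK start handling in igraph)
# so that results do not perturb, and are not perturbed by, the pipeline seed.
.with_fixed_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic BFS distances + parent pointers from `root` over an adjacency
# list (list of integer neighbour vectors). Parent of v = smallest-id neighbour
# at distance dist(v) - 1, so every extracted path is deterministic and the
# union of all root paths is a forest.
.bfs_parents <- function(adj, root) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  dist[root] <- 0L
  frontier <- root
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.na(dist[nxt])]
    if (!length(nxt)) break
    dist[nxt] <- dist[frontier[1L]] + 1L
    frontier <- sort(nxt)
  }
  parent <- rep(NA_integer_, n)
  for (v in seq_len(n)) {
    if (is.na(dist[v]) || v == root) next
    cand <- adj[[v]]
    cand <- cand[!is.na(dist[cand]) & dist[cand] == dist[v] - 1L]
    if (length(cand)) parent[v] <- min(cand)
  }
  list(dist = dist, parent = parent)
}

# Follow parent pointers from v to root (inclusive); NULL if unreachable.
.path_to_root <- function(bfs, v, root) {
  if (is.na(bfs$dist[v])) return(NULL)
  path <- v
  while (v != root) {
    v <- bfs$parent[v]
    if (is.na(v)) return(NULL)
    path <- c(path, v)
  }
  path
}

# Adjacency list (sorted neighbour ids) from a 2-column undirected edge matrix.
.adj_list <- function(n, edges) {
  adj <- vector("list", n)
  if (nrow(edges)) {
    ii <- c(edges[, 1L], edges[, 2L])
    jj <- c(edges[, 2L], edges[, 1L])
    sp <- split(jj, factor(ii, levels = seq_len(n)))
    adj <- lapply(sp, function(v) sort(unique(v)))
  } else {
    adj <- rep(list(integer(0)), n)
  }
  adj
}
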