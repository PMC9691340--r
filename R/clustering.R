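# Initial instance segmentation: coarse norm-based split of 2-/3-D organs from
# linear ones, region growing for blade/apex instances, elbow-selected K-means
# on ADG directions for linear organs.

#' Coarse K-means clustering on the ADG norm
#'
#' K-means (fixed seed, 10 restarts) on the scalar `||g||` values. The single
#' cluster whose centroid is smallest is tagged `blade_or_apex` (it gathers
#' leaf blades and apices, where the ADG norm drops); all other clusters are
#' tagged `linear`.
#'
#' @param field a `spectral_field` with `adg_norm`.
#' @param K number of clusters (default 4).
#' @param seed RNG seed for K-means.
#' @return List with `cluster_id` (per-point, 1..K), `tag` (per-cluster,
#'   "blade_or_apex"/"linear"), `centers` (sorted cluster centroids) and
#'   `norm_threshold` (midpoint between the two smallest centroids, used to
#'   re-tag clusters during refinement).
#' @export
cluster_by_norm <- function(field, K = 4L, seed = 0L) {
  x <- field$adg_norm
  if (is.null(x)) .stopf("adg_norm not computed; call compute_adg() first")
  ux <- unique(x)
  if (length(ux) == 1L) {
    .warnf("degenerate input: all ADG norms identical; single blade_or_apex cluster")
    return(list(cluster_id = rep(1L, length(x)), tag = "blade_or_apex",
                centers = ux, norm_threshold = ux))
  }
  if (length(ux) < K) {
    .warnf("only %d distinct norm values; reducing K from %d", length(ux), K)
    K <- length(ux)
  }
  set.seed(seed)
  km <- stats::kmeans(x, centers = K, nstart = 10, iter.max = 100)
  centers <- as.numeric(km$centers)
  tag <- rep("linear", K)
  tag[which.min(centers)] <- "blade_or_apex"
  thr <- if (K >= 2) mean(sort(centers)[1:2]) else max(x)
  list(cluster_id = as.integer(km$cluster), tag = tag, centers = centers,
       norm_threshold = thr)
}

#' Extract instances by region growing on the similarity graph
#'
#' Returns the connected components of the symmetrized similarity graph
#' restricted to `mask`, ordered by their smallest contained point index.
#'
#' @param graph a `similarity_graph`.
#' @param mask integer point indices (or logical vector over points).
#' @return List of integer index vectors, one per instance.
#' @export
extract_instances_region_growing <- function(graph, mask) {
  if (is.logical(mask)) mask <- which(mask)
  mask <- sort(unique(as.integer(mask)))
  if (!length(mask)) return(list())
  sub <- igraph::induced_subgraph(graph$g, mask)
  memb <- igraph::components(sub)$membership
  comps <- split(mask, memb)
  comps <- unname(comps)
  comps[order(vapply(comps, min, integer(1)))]
}

#' Select the number of clusters by the elbow criterion
#'
#' Given within-cluster variance values for K = 1..k_max (non-increasing
#' expected), returns the K at maximum perpendicular distance to the chord
#' joining the first and last points of the criterion curve (ties towards
#' smaller K). With fewer than 3 candidates the argmin is returned.
#'
#' @param criterion_values numeric vector, `criterion_values[K]` = criterion at K.
#' @param k_max number of candidates considered (default all).
#' @return The selected integer K.
#' @export
select_k_elbow <- function(criterion_values, k_max = length(criterion_values)) {
  v <- criterion_values[seq_len(min(k_max, length(criterion_values)))]
  m <- length(v)
  if (m < 3L) return(which.min(v))
  # perpendicular distance of (K, v[K]) to the chord (1, v[1]) -- (m, v[m])
  dx <- m - 1; dy <- v[m] - v[1]
  nrm <- sqrt(dx^2 + dy^2)
  ks <- seq_len(m)
  d <- abs(dy * (ks - 1) - dx * (v - v[1])) / nrm
  # ties (within numerical noise of the maximum) break toward smaller K;
  # the noise floor scales with the criterion values, not the distances
  tol <- 1e-9 * max(abs(v - v[1]), 1)
  which(d >= max(d) - tol)[1L]
}

# Within-cluster total sum of squares for kmeans with given K (deterministic).
.kmeans_wss <- function(x, K, seed) {
  if (K == 1L) return(sum(scale(x, scale = FALSE)^2))
  set.seed(seed + K)
  stats::kmeans(x, centers = K, nstart = 10, iter.max = 100)$tot.withinss
}

#' Split a linear cluster into sub-clusters by ADG direction
#'
#' For each connected component of `cluster` in the similarity graph, K-means
#' is run on the unit-normalized ADG vectors with K selected by the elbow
#' criterion on the within-cluster variance curve (K = 1..k_max). Each
#' K-means sub-cluster is further split into graph-connected components so
#' every returned sub-cluster is connected. Components smaller than 3 points
#' are kept whole, as are components whose directions are already coherent
#' (resultant length of the unit ADG vectors at least
#' `cos(angle_threshold_deg)`): splitting them is pointless because the
#' direction-merging stage would immediately re-fuse the parts.
#'
#' @param graph a `similarity_graph`.
#' @param field a `spectral_field` with `adg`.
#' @param cluster integer point indices of one linear cluster.
#' @param k_max maximum number of sub-clusters per component (default 20).
#' @param seed RNG seed.
#' @param angle_threshold_deg coherence angle in degrees (default 30,
#'   matching the direction-merge threshold).
#' @return List of integer index vectors (sub-clusters), ordered by smallest
#'   contained point index.
#' @export
split_by_direction <- function(graph, field, cluster, k_max = 20L, seed = 0L,
                               angle_threshold_deg = 30) {
  comps <- extract_instances_region_growing(graph, cluster)
  out <- list()
  for (comp in comps) {
    if (length(comp) < 3L) { out <- c(out, list(comp)); next }
    dirs <- .unit_rows(field$adg[comp, , drop = FALSE])
    if (sqrt(sum(colMeans(dirs)^2)) >= cos(angle_threshold_deg * pi / 180)) {
      out <- c(out, list(comp)); next
    }
    kmax <- min(k_max, length(comp) - 1L, nrow(unique(dirs)))
    if (kmax < 2L) { out <- c(out, list(comp)); next }
    wss <- vapply(seq_len(kmax), function(K) .kmeans_wss(dirs, K, seed), numeric(1))
    Kstar <- select_k_elbow(wss)
    if (Kstar == 1L) { out <- c(out, list(comp)); next }
    set.seed(seed + Kstar)
    km <- stats::kmeans(dirs, centers = Kstar, nstart = 10, iter.max = 100)
    for (sub in split(comp, km$cluster))
      out <- c(out, extract_instances_region_growing(graph, sub))
  }
  out[order(vapply(out, min, integer(1)))]
}

# Assemble the initial clustering of the whole cloud:
#  - coarse norm K-means (K = 4), smallest-centroid cluster tagged blade_or_apex
#  - region growing for blade/apex instances
#  - elbow + direction K-means + connected components for linear clusters
# Returns list(cluster_id, tag, provenance, norm_threshold).
.initial_clustering <- function(graph, field, K_norm = 4L, k_max_split = 20L, seed = 0L) {
  coarse <- cluster_by_norm(field, K = K_norm, seed = seed)
  n <- length(coarse$cluster_id)
  cluster_id <- integer(n)
  tag <- character(0)
  prov <- character(0)
  nxt <- 1L
  blade_k <- which(coarse$tag == "blade_or_apex")
  for (inst in extract_instances_region_growing(graph, which(coarse$cluster_id %in% blade_k))) {
    cluster_id[inst] <- nxt
    tag[nxt] <- "blade_or_apex"; prov[nxt] <- "region-grow"
    nxt <- nxt + 1L
  }
  for (kk in which(coarse$tag == "linear")) {
    pts <- which(coarse$cluster_id == kk)
    if (!length(pts)) next
    for (sub in split_by_direction(graph, field, pts, k_max = k_max_split, seed = seed)) {
      cluster_id[sub] <- nxt
      tag[nxt] <- "linear"; prov[nxt] <- "direction-split"
      nxt <- nxt + 1L
    }
  }
  list(cluster_id = cluster_id, tag = tag, provenance = prov,
       norm_threshold = coarse$norm_threshold)
}
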