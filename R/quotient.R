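# Quotient graph: macroscopic graph over point clusters. Nodes carry the
# member point set, a coarse tag (linear / blade_or_apex), a mean ADG
# direction for linear nodes, a semantic class label and a leaf load; edges
# carry the number of crossing similarity-graph edges, a direction energy
# E = 1 - D_i . D_j, and (during semantic labelling) a weight in {1, Inf}.

.QG_CLASSES <- c("linear", "leaf_blade", "apex", "main_stem", "branch", "petiole")

#' Construct a quotient graph explicitly
#'
#' Low-level constructor used to build small quotient graphs directly from a
#' node table and an edge list (e.g. for testing the botanical-labelling
#' rules on hand-made organ topologies). For the standard route from a point
#' cloud, see [build_quotient].
#'
#' @param class_label character vector of node classes; one of
#'   `"linear"`, `"leaf_blade"`, `"apex"`, `"main_stem"`, `"branch"`,
#'   `"petiole"`.
#' @param edges 2-column integer matrix of undirected node-id pairs.
#' @param root_id root node id (defaults to the last node).
#' @param n_points optional per-node point counts (default 1 each).
#' @param tag optional coarse tag; derived from `class_label` when missing.
#' @return A `quotient_graph` object.
#' @export
quotient_graph <- function(class_label, edges, root_id = length(class_label),
                           n_points = NULL, tag = NULL) {
  m <- length(class_label)
  stopifnot(all(class_label %in% .QG_CLASSES))
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) && (max(edges) > m || min(edges) < 1L)) .stopf("edge endpoint out of range")
  if (is.null(tag)) tag <- ifelse(class_label %in% c("leaf_blade", "apex"),
                                  "blade_or_apex", "linear")
  nodes <- data.frame(node_id = seq_len(m),
                      n_points = as.integer(n_points %||% rep(1L, m)),
                      tag = tag, class_label = class_label,
                      leaf_load = 0L, stringsAsFactors = FALSE)
  e <- data.frame(a = pmin(edges[, 1], edges[, 2]), b = pmax(edges[, 1], edges[, 2]),
                  n_cross = rep(1L, nrow(edges)), energy = rep(NA_real_, nrow(edges)),
                  weight = rep(NA_real_, nrow(edges)))
  e <- e[!duplicated(e[c("a", "b")]), , drop = FALSE]
  structure(list(nodes = nodes, edges = e, mean_dir = matrix(NA_real_, m, 3),
                 anchor_dir = matrix(NA_real_, m, 3),
                 membership = NULL, root_id = as.integer(root_id),
                 stem_apex_id = NA_integer_, leaf_paths = NULL),
            class = "quotient_graph")
}

#' Build the quotient graph of a clustering
#'
#' One macro-node per cluster; a macro-edge joins two nodes iff at least one
#' similarity-graph edge crosses the two clusters (the number of crossing
#' edges is recorded). For linear nodes the mean direction is the renormalized
#' mean of the unit ADG vectors of the member points.
#'
#' @param graph a `similarity_graph`.
#' @param clustering list with `cluster_id` (per-point, contiguous 1..C) and
#'   `tag` (per-cluster), as produced internally by the pipeline.
#' @param field a `spectral_field` with `adg` (may be NULL; mean directions
#'   then remain undefined).
#' @return A `quotient_graph`.
#' @export
build_quotient <- function(graph, clustering, field = NULL) {
  memb <- clustering$cluster_id
  m <- max(memb)
  if (!all(sort(unique(memb)) == seq_len(m))) .stopf("cluster ids must be contiguous 1..C")
  tag <- clustering$tag
  nodes <- data.frame(node_id = seq_len(m),
                      n_points = as.integer(tabulate(memb, m)),
                      tag = tag,
                      class_label = rep("linear", m),
                      leaf_load = 0L, stringsAsFactors = FALSE)
  if (any(nodes$n_points == 0L)) .stopf("empty cluster in quotient construction")
  mean_dir <- matrix(NA_real_, m, 3)
  if (!is.null(field$adg)) {
    ud <- .unit_rows(field$adg)
    for (id in which(tag == "linear")) {
      v <- colMeans(ud[memb == id, , drop = FALSE])
      nv <- sqrt(sum(v^2))
      if (nv > 0) mean_dir[id, ] <- v / nv
    }
  }
  ea <- memb[graph$edges[, 1]]
  eb <- memb[graph$edges[, 2]]
  cross <- ea != eb
  a <- pmin(ea[cross], eb[cross]); b <- pmax(ea[cross], eb[cross])
  if (length(a)) {
    key <- paste(a, b)
    agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
    ab <- do.call(rbind, strsplit(agg$key, " "))
    edges <- data.frame(a = as.integer(ab[, 1]), b = as.integer(ab[, 2]),
                        n_cross = as.integer(agg$Freq), energy = NA_real_,
                        weight = NA_real_)
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(a = integer(0), b = integer(0), n_cross = integer(0),
                        energy = numeric(0), weight = numeric(0))
  }
  qg <- structure(list(nodes = nodes, edges = edges, mean_dir = mean_dir,
                       anchor_dir = mean_dir,
                       membership = memb, root_id = NA_integer_,
                       stem_apex_id = NA_integer_, leaf_paths = NULL),
                  class = "quotient_graph")
  .qg_update_energies(qg)
}

#' @export
print.quotient_graph <- function(x, ...) {
  cat(sprintf("quotient_graph: %d nodes, %d edges, root %s\n", nrow(x$nodes),
              nrow(x$edges), ifelse(is.na(x$root_id), "<unset>", x$root_id)))
  print(table(x$nodes$class_label))
  invisible(x)
}

.qg_update_energies <- function(qg) {
  if (nrow(qg$edges)) {
    da <- qg$mean_dir[qg$edges$a, , drop = FALSE]
    db <- qg$mean_dir[qg$edges$b, , drop = FALSE]
    qg$edges$energy <- 1 - rowSums(da * db)
  }
  qg
}

# igraph view of the quotient graph; finite_only keeps weight-1 edges.
.qg_igraph <- function(qg, finite_only = FALSE) {
  e <- qg$edges
  if (finite_only) e <- e[!is.na(e$weight) & is.finite(e$weight), , drop = FALSE]
  g <- igraph::make_empty_graph(n = nrow(qg$nodes), directed = FALSE)
  if (nrow(e)) g <- igraph::add_edges(g, rbind(e$a, e$b))
  g
}

# Collapse a set of node ids into one node (the smallest id), renumbering the
# graph to contiguous ids. Point memberships, n_points, point-weighted mean
# directions and cross-edge counts are aggregated; energies recomputed.
# Class/tag of the surviving node = `keep_class_of` (default: the target).
.qg_merge_nodes <- function(qg, ids, keep_class_of = NULL) {
  ids <- sort(unique(as.integer(ids)))
  if (length(ids) < 2L) return(qg)
  target <- ids[1L]
  keep_class_of <- keep_class_of %||% target
  m <- nrow(qg$nodes)
  map <- seq_len(m)
  map[ids] <- target
  # weighted mean direction over merged linear nodes
  w <- qg$nodes$n_points[ids]
  dirs <- qg$mean_dir[ids, , drop = FALSE]
  ok <- !is.na(dirs[, 1])
  newdir <- c(NA_real_, NA_real_, NA_real_)
  if (any(ok)) {
    v <- colSums(dirs[ok, , drop = FALSE] * w[ok])
    nv <- sqrt(sum(v^2))
    if (nv > 0) newdir <- v / nv
  }
  cls <- qg$nodes$class_label[keep_class_of]
  tg <- qg$nodes$tag[keep_class_of]
  anchor <- qg$anchor_dir[ids[which.max(qg$nodes$n_points[ids])], ]
  qg$nodes$n_points[target] <- sum(qg$nodes$n_points[ids])
  qg$nodes$class_label[target] <- cls
  qg$nodes$tag[target] <- tg
  qg$nodes$leaf_load[target] <- sum(qg$nodes$leaf_load[ids])
  qg$mean_dir[target, ] <- newdir
  qg$anchor_dir[target, ] <- anchor
  # renumber to contiguous ids
  keep <- setdiff(seq_len(m), setdiff(ids, target))
  newid <- integer(m); newid[keep] <- seq_along(keep)
  map2 <- newid[map]
  qg$nodes <- qg$nodes[keep, , drop = FALSE]
  qg$nodes$node_id <- seq_len(nrow(qg$nodes))
  rownames(qg$nodes) <- NULL
  qg$mean_dir <- qg$mean_dir[keep, , drop = FALSE]
  qg$anchor_dir <- qg$anchor_dir[keep, , drop = FALSE]
  if (!is.null(qg$membership)) qg$membership <- map2[qg$membership]
  if (!is.na(qg$root_id)) qg$root_id <- map2[qg$root_id]
  if (!is.na(qg$stem_apex_id)) qg$stem_apex_id <- map2[qg$stem_apex_id]
  e <- qg$edges
  if (nrow(e)) {
    ea <- map2[e$a]; eb <- map2[e$b]
    sel <- ea != eb
    a <- pmin(ea[sel], eb[sel]); b <- pmax(ea[sel], eb[sel])
    nc <- e$n_cross[sel]
    if (length(a)) {
      key <- paste(a, b)
      first <- !duplicated(key)
      ncs <- tapply(nc, key, sum)
      e2 <- data.frame(a = a[first], b = b[first],
                       n_cross = as.integer(ncs[paste(a[first], b[first])]),
                       energy = NA_real_, weight = NA_real_)
      e2 <- e2[order(e2$a, e2$b), , drop = FALSE]
      rownames(e2) <- NULL
      qg$edges <- e2
    } else {
      qg$edges <- e[0, , drop = FALSE]
    }
  }
  qg$leaf_paths <- NULL
  .qg_update_energies(qg)
}

# Merge every cluster below min_size points (smallest first) into the
# neighbour sharing the most similarity-graph cross edges. Such fragments are
# by-products of the geometric stage (blade rims whose ADG norm rises above
# the coarse threshold, direction-shift bands at organ junctions); organ
# bodies must be complete before Fiedler extrema are counted on them. The
# root and merged main stem are never treated as fragments.
.qg_premerge_small <- function(qg, min_size) {
  repeat {
    cand <- which(qg$nodes$n_points < min_size &
                  qg$nodes$class_label != "main_stem" &
                  (is.na(qg$root_id) | qg$nodes$node_id != qg$root_id))
    cand <- cand[cand %in% c(qg$edges$a, qg$edges$b)]
    if (!length(cand)) break
    v <- cand[order(qg$nodes$n_points[cand], cand)][1L]
    inc <- qg$edges[qg$edges$a == v | qg$edges$b == v, , drop = FALSE]
    nb <- ifelse(inc$a == v, inc$b, inc$a)
    # prefer the neighbour continuing the fragment's ADG direction (the
    # method's own merge criterion); fall back to the strongest contact
    en <- 1 - as.numeric(qg$mean_dir[v, , drop = FALSE] %*% t(qg$mean_dir[nb, , drop = FALSE]))
    tgt <- if (any(!is.na(en))) nb[order(en, -inc$n_cross, nb)][1L]
           else nb[order(-inc$n_cross, nb)][1L]
    qg <- .qg_merge_nodes(qg, c(v, tgt), keep_class_of = tgt)
  }
  qg
}

#' Select the root node of a quotient graph
#'
#' The root is the node containing the point with the minimal up-axis
#' coordinate (the lowest part of the plant), unless a manual override is
#' given. Ties are broken by the smaller point index, hence the smaller
#' node id.
#'
#' @param qg a `quotient_graph` with point membership.
#' @param points the [point_cloud].
#' @param override optional node id to force as root.
#' @return The `quotient_graph` with `root_id` set.
#' @export
select_root <- function(qg, points, override = NULL) {
  if (!is.null(override)) {
    override <- as.integer(override)
    if (!override %in% qg$nodes$node_id) .stopf("override %d is not a node id", override)
    qg$root_id <- override
    return(qg)
  }
  if (is.null(qg$membership)) .stopf("quotient graph has no point membership; give an override")
  up <- .as_coords(points)[, .up_axis_of(points)]
  qg$root_id <- qg$membership[which.min(up)]
  qg
}

#' Merge adjacent linear nodes with similar mean ADG directions
#'
#' Iteratively collapses the linear-linear edge with the lowest direction
#' energy `E = 1 - D_i . D_j` while that energy is below
#' `1 - cos(angle_threshold)`. After each collapse the merged node's mean
#' direction is the point-count-weighted renormalized mean and incident
#' energies are recomputed. Blade/apex nodes never merge.
#'
#' @param qg a `quotient_graph`.
#' @param angle_threshold_deg merge threshold angle in degrees (default 30).
#'   The appropriate value can depend on the density of the point cloud.
#' @return The merged `quotient_graph`.
#' @export
merge_similar_directions <- function(qg, angle_threshold_deg = 30) {
  thr <- 1 - cos(angle_threshold_deg * pi / 180)
  repeat {
    e <- qg$edges
    if (!nrow(e)) break
    lin <- qg$nodes$tag == "linear"
    ean <- 1 - rowSums(qg$anchor_dir[e$a, , drop = FALSE] *
                         qg$anchor_dir[e$b, , drop = FALSE])
    crit <- pmax(e$energy, ean)
    ok <- lin[e$a] & lin[e$b] & !is.na(crit)
    if (!any(ok)) break
    cand <- which(ok)
    best <- cand[which.min(crit[cand])]
    if (crit[best] >= thr) break
    qg <- .qg_merge_nodes(qg, c(e$a[best], e$b[best]))
  }
  qg
}
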