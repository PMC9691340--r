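#' Construct a plant point cloud
#'
#' A `point_cloud` holds the N x 3 coordinates of a single-plant scan in
#' consistent length units (e.g. mm), together with optional per-point
#' semantic and instance labels and the index of the vertical (up) axis.
#' Points closer than `dedup_tol` are collapsed to one representative
#' (first index wins).
#'
#' @param coords numeric matrix (N x 3) of point coordinates.
#' @param semantic_label optional integer/character vector of length N.
#' @param instance_label optional integer vector of length N.
#' @param up_axis index of the vertical axis (1, 2 or 3; default 3).
#' @param dedup_tol deduplication tolerance in length units (default 1e-9).
#' @return An object of class `point_cloud` with elements `coords`,
#'   `semantic_label`, `instance_label`, `up_axis`.
#' @examples
#' pc <- point_cloud(matrix(rnorm(30), ncol = 3))
#' nrow(pc$coords)
#' @export
point_cloud <- function(coords, semantic_label = NULL, instance_label = NULL,
                        up_axis = 3L, dedup_tol = 1e-9) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) .stopf("coords must have 3 columns, got %d", ncol(coords))
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  if (any(!is.finite(coords))) .stopf("non-finite coordinates in point cloud")
  n <- nrow(coords)
  if (!is.null(semantic_label) && length(semantic_label) != n)
    .stopf("semantic_label has length %d, expected %d", length(semantic_label), n)
  if (!is.null(instance_label) && length(instance_label) != n)
    .stopf("instance_label has length %d, expected %d", length(instance_label), n)
  up_axis <- as.integer(up_axis)
  if (!up_axis %in% 1:3) .stopf("up_axis must be 1, 2 or 3")

  # Voxel-key deduplication at resolution dedup_tol: points falling in the
  # same tolerance cell are collapsed, first occurrence kept.
  key <- paste(round(coords[, 1] / dedup_tol), round(coords[, 2] / dedup_tol),
               round(coords[, 3] / dedup_tol))
  keep <- !duplicated(key)
  if (!all(keep)) {
    coords <- coords[keep, , drop = FALSE]
    if (!is.null(semantic_label)) semantic_label <- semantic_label[keep]
    if (!is.null(instance_label)) instance_label <- instance_label[keep]
  }
  if (nrow(coords) < 2L) .stopf("point cloud must contain at least 2 distinct points")
  structure(list(coords = coords, semantic_label = semantic_label,
                 instance_label = instance_label, up_axis = up_axis),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points, up axis %d%s%s\n", nrow(x$coords), x$up_axis,
              if (!is.null(x$semantic_label)) ", semantic labels" else "",
              if (!is.null(x$instance_label)) ", instance labels" else ""))
  invisible(x)
}

.as_coords <- function(points) {
  if (inherits(points, "point_cloud")) points$coords else as.matrix(points)
}

#' Down-sample a point cloud by minimum distance
#'
#' Greedy selection in index order: a point is kept iff no previously kept
#' point lies within `d_min`. Labels are carried through. This mirrors the
#' practice of thinning dense scans by slightly increasing the minimum
#' distance between any two points.
#'
#' @param points a [point_cloud].
#' @param d_min minimum allowed distance between kept points (> 0).
#' @return A down-sampled `point_cloud`.
#' @export
downsample_min_distance <- function(points, d_min) {
  stopifnot(inherits(points, "point_cloud"))
  if (!is.numeric(d_min) || d_min <= 0) .stopf("d_min must be > 0")
  xyz <- points$coords
  n <- nrow(xyz)
  # Grid hash at cell size d_min: only neighbouring cells can violate d_min.
  cell <- floor(xyz / d_min)
  keykeep <- new.env(hash = TRUE, parent = emptyenv())
  keep <- logical(n)
  kept_xyz <- matrix(0, n, 3)
  nk <- 0L
  for (i in seq_len(n)) {
    ci <- cell[i, ]
    ok <- TRUE
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      kk <- paste(ci[1] + dx, ci[2] + dy, ci[3] + dz)
      ids <- keykeep[[kk]]
      if (!is.null(ids)) {
        d2 <- (kept_xyz[ids, 1] - xyz[i, 1])^2 + (kept_xyz[ids, 2] - xyz[i, 2])^2 +
          (kept_xyz[ids, 3] - xyz[i, 3])^2
        if (any(d2 < d_min^2)) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) {
      nk <- nk + 1L
      keep[i] <- TRUE
      kept_xyz[nk, ] <- xyz[i, ]
      kk <- paste(ci[1], ci[2], ci[3])
      keykeep[[kk]] <- c(keykeep[[kk]], nk)
    }
  }
  point_cloud(xyz[keep, , drop = FALSE],
              semantic_label = points$semantic_label[keep],
              instance_label = points$instance_label[keep],
              up_axis = points$up_axis)
}
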