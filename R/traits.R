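# Agronomic trait extraction from a labelled segmentation: main stem height,
# per-blade surface area via least-squares Bezier patches, leaf area index.

#' Main stem height from the Fiedler-ordered stem points
#'
#' The Fiedler value is monotone along the stem, so ordering the main-stem
#' points by it and binning them into `bins` equal-count bins yields an
#' ordered skeleton; the stem height is the length of the polyline through
#' the bin centroids, scaled by `bins/(bins-1)` to compensate for the half-bin
#' truncation at both ends (exact for uniform sampling of a straight stem).
#' The construction only uses graph quantities and centroids, so it is
#' invariant to rigid motions of the cloud. Degenerate inputs (fewer than
#' two bins' worth of points) fall back to the up-axis extent.
#'
#' @param coords N x 3 coordinates of the main-stem points.
#' @param fiedler their Fiedler values.
#' @param bins number of equal-count bins (default 20).
#' @param up_axis fallback axis for degenerate inputs (default 3).
#' @return Stem height in the cloud's length units.
#' @export
main_stem_height <- function(coords, fiedler, bins = 20L, up_axis = 3L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n == 0L) .stopf("no main-stem points")
  b <- min(as.integer(bins), floor(n / 2))
  if (b < 2L) return(diff(range(coords[, up_axis])))
  ord <- order(fiedler)
  grp <- ceiling(seq_along(ord) / (n / b))
  grp[grp > b] <- b
  cent <- apply(coords[ord, , drop = FALSE], 2, function(col) tapply(col, grp, mean))
  seg <- sqrt(rowSums(diff(cent)^2))
  sum(seg) * b / (b - 1)
}

# Bernstein basis matrix: rows = parameter values u in [0,1], cols = 0..d.
.bernstein <- function(u, d) {
  sapply(0:d, function(i) choose(d, i) * u^i * (1 - u)^(d - i))
}
.bernstein_deriv <- function(u, d) {
  # d/du B_{i,d}(u) = d (B_{i-1,d-1} - B_{i,d-1})
  B1 <- .bernstein(u, d - 1L)
  sapply(0:d, function(i) {
    lo <- if (i >= 1) B1[, i] else 0
    hi <- if (i <= d - 1) B1[, i + 1] else 0
    d * (lo - hi)
  })
}

#' Surface area of a leaf blade by Bezier-patch fitting
#'
#' Fits a tensor-product Bezier patch of bi-degree `degree` to the blade
#' points over a PCA-plane parameterization (least squares on the Bernstein
#' basis), then integrates the surface element `||S_u x S_v||` on a
#' `grid x grid` midpoint quadrature restricted to the convex hull of the
#' parameter points (so the patch is only integrated where the blade
#' actually lies). With fewer than `(degree+1)^2` points the PCA-plane
#' convex-hull area is returned with a warning.
#'
#' @param coords N x 3 coordinates of one leaf blade.
#' @param degree Bezier bi-degree (default 3, bicubic).
#' @param grid quadrature resolution per axis (default 20).
#' @return Blade area (length units squared).
#' @export
blade_area <- function(coords, degree = 3L, grid = 20L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  ctr <- colMeans(coords)
  X <- sweep(coords, 2, ctr)
  pca <- svd(X, nu = 0, nv = 3)
  uv <- X %*% pca$v[, 1:2]
  if (n < (degree + 1L)^2) {
    .warnf("blade has %d points (< %d); falling back to convex-hull area", n, (degree + 1L)^2)
    hull <- grDevices::chull(uv)
    h <- uv[hull, , drop = FALSE]
    return(abs(sum(h[, 1] * h[c(2:nrow(h), 1), 2] - h[c(2:nrow(h), 1), 1] * h[, 2])) / 2)
  }
  rng_u <- range(uv[, 1]); rng_v <- range(uv[, 2])
  su <- diff(rng_u); sv <- diff(rng_v)
  if (su == 0 || sv == 0) return(0)
  u <- (uv[, 1] - rng_u[1]) / su
  v <- (uv[, 2] - rng_v[1]) / sv
  Bu <- .bernstein(u, degree)
  Bv <- .bernstein(v, degree)
  # design matrix: row i = kron(Bv[i,], Bu[i,]); control net solved per coordinate
  D <- matrix(0, n, (degree + 1L)^2)
  for (j in seq_len(degree + 1L))
    D[, ((j - 1L) * (degree + 1L) + 1L):(j * (degree + 1L))] <- Bu * Bv[, j]
  fit <- qr(D, LAPACK = TRUE)
  P <- qr.coef(fit, coords)        # ((d+1)^2) x 3 control points
  P[is.na(P)] <- 0
  # midpoint quadrature over the parameter-domain convex hull
  gs <- (seq_len(grid) - 0.5) / grid
  gu <- rep(gs, times = grid)
  gv <- rep(gs, each = grid)
  hull <- grDevices::chull(cbind(u, v))
  inside <- mgcv::in.out(rbind(cbind(u, v)[hull, ], cbind(u, v)[hull[1], ]),
                         cbind(gu, gv))
  if (!any(inside)) return(0)
  Bgu <- .bernstein(gu[inside], degree); Bgv <- .bernstein(gv[inside], degree)
  dBu <- .bernstein_deriv(gu[inside], degree); dBv <- .bernstein_deriv(gv[inside], degree)
  m <- sum(inside)
  Su <- matrix(0, m, 3); Sv <- matrix(0, m, 3)
  for (j in seq_len(degree + 1L)) {
    idx <- ((j - 1L) * (degree + 1L) + 1L):(j * (degree + 1L))
    Su <- Su + (dBu * Bgv[, j]) %*% P[idx, , drop = FALSE]
    Sv <- Sv + (Bgu * dBv[, j]) %*% P[idx, , drop = FALSE]
  }
  # scale parameter derivatives back to length units
  Su <- Su / su; Sv <- Sv / sv
  crossp <- cbind(Su[, 2] * Sv[, 3] - Su[, 3] * Sv[, 2],
                  Su[, 3] * Sv[, 1] - Su[, 1] * Sv[, 3],
                  Su[, 1] * Sv[, 2] - Su[, 2] * Sv[, 1])
  sum(sqrt(rowSums(crossp^2))) * (su * sv) / grid^2
}

#' Leaf area index of a plant
#'
#' `LAI = total one-sided blade area / bounding-box base area`, the base
#' being the axis-aligned extent of the whole cloud along the two non-up
#' axes (a proxy for the ground surface under the plant).
#'
#' @param blade_areas numeric vector of per-blade areas.
#' @param coords N x 3 coordinates of the whole plant.
#' @param up_axis vertical axis index (default 3).
#' @return List with `total_blade_area`, `bbox_base_area`, `lai`.
#' @export
leaf_area_index <- function(blade_areas, coords, up_axis = 3L) {
  coords <- as.matrix(coords)
  base_axes <- setdiff(1:3, up_axis)
  ext <- apply(coords[, base_axes, drop = FALSE], 2, function(x) diff(range(x)))
  base <- prod(ext)
  if (base <= 0) .stopf("degenerate bounding box: zero base area")
  total <- sum(blade_areas)
  list(total_blade_area = total, bbox_base_area = base, lai = total / base)
}

#' Extract all traits from a pipeline segmentation
#'
#' Computes the main stem height, the per-blade Bezier areas (one per
#' leaf-blade instance) and the leaf area index.
#'
#' @param seg a `plant_segmentation` (see [run_pipeline]).
#' @param bins stem-height bin count (default 20).
#' @param degree,grid Bezier fit parameters (see [blade_area]).
#' @return An object of class `trait_report`: list with `stem_height`,
#'   `blade_areas`, `total_blade_area`, `bbox_base_area`, `lai`.
#' @export
extract_traits <- function(seg, bins = 20L, degree = 3L, grid = 20L) {
  stopifnot(inherits(seg, "plant_segmentation"))
  xyz <- seg$points$coords
  up <- seg$points$up_axis
  stem <- seg$labels$class_name == "main_stem"
  if (!any(stem)) .stopf("no main-stem points in segmentation")
  height <- main_stem_height(xyz[stem, , drop = FALSE],
                             seg$field$fiedler[stem], bins = bins, up_axis = up)
  blades <- which(seg$labels$class_name == "leaf_blade")
  areas <- numeric(0)
  if (length(blades)) {
    by_inst <- split(blades, seg$labels$instance_id[blades])
    areas <- vapply(by_inst, function(idx)
      blade_area(xyz[idx, , drop = FALSE], degree = degree, grid = grid), numeric(1))
  }
  lai <- leaf_area_index(areas, xyz, up_axis = up)
  structure(list(stem_height = height, blade_areas = areas,
                 total_blade_area = lai$total_blade_area,
                 bbox_base_area = lai$bbox_base_area, lai = lai$lai),
            class = "trait_report")
}

#' @export
print.trait_report <- function(x, ...) {
  cat(sprintf("trait_report: stem height %.2f, %d blade(s), total area %.2f, LAI %.3f\n",
              x$stem_height, length(x$blade_areas), x$total_blade_area, x$lai))
  invisible(x)
}
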