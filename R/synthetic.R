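# Parametric synthetic plants with exact ground truth. Stems, branches and
# petioles are sampled on tube (cylinder) surfaces, leaf blades on flat
# (optionally serrated) elliptical patches, apices as bouquets of small
# leaflet patches at axis tips. All randomness flows from the spec seed, so
# clouds are bit-reproducible. The generator emulates the geometry of a young
# forb (Chenopodium-like): a vertical main stem, a few oblique branches each
# ending in an apex, petiolate leaves along the stem, and a terminal apex.

#' Specification of a synthetic plant
#'
#' All lengths in mm; `sampling_density` in points per mm^2 of organ surface.
#' The defaults produce a cloud of roughly 10,000 points whose organs are
#' well resolved by an 18-neighbour graph at zero noise.
#'
#' @param stem_length,stem_radius main stem tube dimensions.
#' @param n_branches number of branches.
#' @param branch_lengths,branch_angles,branch_heights,branch_azimuths,branch_radius
#'   per-branch geometry (recycled; angles in degrees from vertical, heights
#'   as fractions of stem length).
#' @param n_leaves number of stem leaves (petiole + blade).
#' @param leaf_heights,leaf_azimuths per-leaf attachment (recycled).
#' @param branch_leaf_fracs fractions along each branch where a leaf is
#'   attached (every branch carries these leaves; real branches are leafy
#'   shoots, not bare sticks). Empty vector for leafless branches.
#' @param petiole_length,petiole_radius,petiole_angle petiole tube geometry.
#' @param blade_shape ellipse half-axes `c(a, b)` of the blades.
#' @param blade_serration `c(amplitude, count)` boundary modulation
#'   `rho <= 1 + amplitude * sin(count * theta)` (0, 0 = smooth margin).
#' @param apex_blob list with `radius` (leaflet half-length) and `n_leaflets`.
#' @param sampling_density points per mm^2.
#' @param noise_sd isotropic Gaussian jitter (mm).
#' @param seed RNG seed.
#' @return An object of class `plant_spec`.
#' @export
plant_spec <- function(stem_length = 70, stem_radius = 1.5,
                       n_branches = 2, branch_lengths = c(25, 22),
                       branch_angles = c(45, 50), branch_heights = c(0.45, 0.65),
                       branch_azimuths = c(20, 200), branch_radius = 1,
                       n_leaves = 8,
                       leaf_heights = c(0.12, 0.24, 0.35, 0.47, 0.58, 0.70, 0.81, 0.92),
                       leaf_azimuths = c(90, 227, 5, 142, 280, 57, 160, 332),
                       branch_leaf_fracs = c(0.5, 0.8),
                       petiole_length = 12, petiole_radius = 0.7, petiole_angle = 55,
                       blade_shape = c(a = 9, b = 5.4),
                       blade_serration = c(amplitude = 0, count = 0),
                       apex_blob = list(radius = 3.2, n_leaflets = 8),
                       sampling_density = 3, noise_sd = 0, seed = 0L) {
  spec <- list(stem_length = stem_length, stem_radius = stem_radius,
               n_branches = n_branches,
               branch_lengths = rep_len(branch_lengths, max(1, n_branches)),
               branch_angles = rep_len(branch_angles, max(1, n_branches)),
               branch_heights = rep_len(branch_heights, max(1, n_branches)),
               branch_azimuths = rep_len(branch_azimuths, max(1, n_branches)),
               branch_radius = branch_radius,
               n_leaves = n_leaves,
               leaf_heights = rep_len(leaf_heights, max(1, n_leaves)),
               leaf_azimuths = rep_len(leaf_azimuths, max(1, n_leaves)),
               branch_leaf_fracs = branch_leaf_fracs,
               petiole_length = petiole_length, petiole_radius = petiole_radius,
               petiole_angle = petiole_angle,
               blade_shape = blade_shape, blade_serration = blade_serration,
               apex_blob = apex_blob, sampling_density = sampling_density,
               noise_sd = noise_sd, seed = as.integer(seed))
  stopifnot(stem_length > 0, stem_radius > 0, petiole_length > 0,
            all(spec$blade_shape > 0), sampling_density > 0)
  structure(spec, class = "plant_spec")
}

# Orthonormal frame completing a unit axis vector.
.frame_of <- function(d) {
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2], d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# Uniform sample on a cylinder surface of given axis.
.sample_tube <- function(p0, dir, len, radius, density) {
  n <- max(8L, round(density * 2 * pi * radius * len))
  fr <- .frame_of(dir)
  t <- stats::runif(n, 0, len)
  th <- stats::runif(n, 0, 2 * pi)
  pts <- matrix(p0, n, 3, byrow = TRUE) + outer(t, dir) +
    radius * (outer(cos(th), fr$e1) + outer(sin(th), fr$e2))
  pts
}

# Uniform sample on a flat elliptical patch (optionally serrated margin).
# base = attachment point; the patch extends from the base along e_major.
.sample_blade <- function(base, e_major, e_minor, a, b, density, serration = c(0, 0)) {
  amp <- serration[1]; cnt <- serration[2]
  area <- pi * a * b * (1 + amp^2 / 2)
  n <- max(16L, round(density * area))
  got <- matrix(0, 0, 2)
  while (nrow(got) < n) {
    m <- 2 * (n - nrow(got)) + 16L
    u <- stats::runif(m, -1 - amp, 1 + amp)
    v <- stats::runif(m, -1 - amp, 1 + amp)
    rho <- sqrt(u^2 + v^2)
    lim <- 1 + (if (cnt > 0) amp * sin(cnt * atan2(v, u)) else 0)
    keep <- rho <= lim
    got <- rbind(got, cbind(u[keep], v[keep]))
  }
  got <- got[seq_len(n), , drop = FALSE]
  ctr <- base + a * e_major
  matrix(ctr, n, 3, byrow = TRUE) + outer(got[, 1] * a, e_major) +
    outer(got[, 2] * b, e_minor)
}

# Apex: bouquet of n small leaflet patches fanned around the axis tip.
.sample_apex <- function(tip, axis_dir, radius, n_leaflets, density) {
  fr <- .frame_of(axis_dir)
  pts <- matrix(0, 0, 3)
  for (i in seq_len(n_leaflets)) {
    phi <- 2 * pi * (i - 1) / n_leaflets
    radial <- cos(phi) * fr$e1 + sin(phi) * fr$e2
    elev <- 50 * pi / 180  # leaflet tilt away from the axis
    d <- sin(elev) * radial + cos(elev) * axis_dir
    d <- d / sqrt(sum(d^2))
    side <- .frame_of(d)$e2
    pts <- rbind(pts, .sample_blade(tip, d, side, radius, 0.6 * radius, density))
  }
  pts
}

#' Generate a labelled synthetic plant point cloud
#'
#' Deterministic under the spec seed. The returned ground truth carries the
#' per-point semantic class and instance id, the true stem length and the
#' closed-form blade areas (`pi * a * b * (1 + amplitude^2/2)`).
#'
#' @param spec a [plant_spec].
#' @return List with `cloud` (a [point_cloud] with `semantic_label` and
#'   `instance_label` set) and `truth` (list: `semantic`, `instance`,
#'   `stem_length`, `blade_areas`, `class_of_instance`, `spec`).
#' @export
generate_plant <- function(spec = plant_spec()) {
  stopifnot(inherits(spec, "plant_spec"))
  # resolution guard: the smallest organ surface must carry enough points for
  # an 18-neighbour graph to stay within the organ
  min_area <- min(2 * pi * spec$petiole_radius * spec$petiole_length,
                  pi * prod(spec$blade_shape))
  if (spec$sampling_density * min_area < 40)
    .stopf("sampling density too low for k = 18 neighbourhoods; increase sampling_density (smallest organ would carry %d points)",
           round(spec$sampling_density * min_area))
  set.seed(spec$seed)
  zhat <- c(0, 0, 1)
  pts <- list(); sem <- list(); inst <- list()
  class_of_instance <- character(0)
  blade_areas <- numeric(0)
  next_inst <- 0L
  emit <- function(p, class) {
    next_inst <<- next_inst + 1L
    pts[[length(pts) + 1L]] <<- p
    sem[[length(sem) + 1L]] <<- rep(class, nrow(p))
    inst[[length(inst) + 1L]] <<- rep(next_inst, nrow(p))
    class_of_instance[next_inst] <<- class
    next_inst
  }
  radial <- function(az) c(cos(az * pi / 180), sin(az * pi / 180), 0)

  emit(.sample_tube(c(0, 0, 0), zhat, spec$stem_length, spec$stem_radius,
                    spec$sampling_density), "main_stem")

  add_leaf <- function(attach, out_dir, plen = spec$petiole_length) {
    # petiole tube from the attachment, then a blade continuing its direction
    p_end <- attach + plen * out_dir
    emit(.sample_tube(attach, out_dir, plen, spec$petiole_radius,
                      spec$sampling_density), "petiole")
    side <- .frame_of(out_dir)$e2
    id <- emit(.sample_blade(p_end, out_dir, side, spec$blade_shape[1],
                             spec$blade_shape[2], spec$sampling_density,
                             spec$blade_serration), "leaf_blade")
    blade_areas[as.character(id)] <<- pi * prod(spec$blade_shape) *
      (1 + spec$blade_serration[1]^2 / 2)
  }

  for (i in seq_len(spec$n_leaves)) {
    az <- spec$leaf_azimuths[i]
    attach <- c(0, 0, spec$leaf_heights[i] * spec$stem_length) +
      spec$stem_radius * radial(az)
    th <- spec$petiole_angle * pi / 180
    out_dir <- sin(th) * radial(az) + cos(th) * zhat
    add_leaf(attach, out_dir / sqrt(sum(out_dir^2)))
  }

  for (i in seq_len(spec$n_branches)) {
    az <- spec$branch_azimuths[i]
    attach <- c(0, 0, spec$branch_heights[i] * spec$stem_length) +
      spec$stem_radius * radial(az)
    th <- spec$branch_angles[i] * pi / 180
    d <- sin(th) * radial(az) + cos(th) * zhat
    d <- d / sqrt(sum(d^2))
    emit(.sample_tube(attach, d, spec$branch_lengths[i], spec$branch_radius,
                      spec$sampling_density), "branch")
    for (j in seq_along(spec$branch_leaf_fracs)) {
      fr <- .frame_of(d)
      roll <- (90 + 180 * (j - 1) + 40 * (i - 1)) * pi / 180
      out_dir <- cos(roll) * fr$e1 + sin(roll) * fr$e2 + 0.2 * d
      out_dir <- out_dir / sqrt(sum(out_dir^2))
      add_leaf(attach + spec$branch_leaf_fracs[j] * spec$branch_lengths[i] * d +
                 spec$branch_radius * out_dir, out_dir)
    }
    emit(.sample_apex(attach + spec$branch_lengths[i] * d, d,
                      spec$apex_blob$radius, spec$apex_blob$n_leaflets,
                      spec$sampling_density), "apex")
  }
  emit(.sample_apex(c(0, 0, spec$stem_length), zhat, spec$apex_blob$radius,
                    spec$apex_blob$n_leaflets, spec$sampling_density), "apex")

  xyz <- do.call(rbind, pts)
  if (spec$noise_sd > 0) xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, spec$noise_sd),
                                             ncol = 3)
  sem <- unlist(sem); inst <- unlist(inst)
  cloud <- point_cloud(xyz, semantic_label = sem, instance_label = inst, up_axis = 3L)
  # deduplication is a no-op at these densities, but keep labels aligned anyway
  stopifnot(nrow(cloud$coords) == length(sem))
  list(cloud = cloud,
       truth = list(semantic = sem, instance = inst,
                    stem_length = spec$stem_length, blade_areas = blade_areas,
                    class_of_instance = class_of_instance, spec = spec))
}

#' Build the toy tree-of-chains graph
#'
#' A vertical main chain of `main_len` nodes at unit spacing with
#' `length(attachments)` side chains of `side_len` nodes each, attached to
#' the given main-chain nodes, embedded in 3D with unit edge lengths and
#' unit edge weights. Useful for studying the Fiedler eigenvector: its
#' values are monotone along a bare chain and show slope breaks at the
#' attachment nodes.
#'
#' @param main_len main chain length (default 100 nodes).
#' @param side_len side chain length (default 20 nodes).
#' @param attachments integer vector of main-chain node indices (1-based)
#'   where side chains attach.
#' @return List with `graph` (a `similarity_graph`-compatible object: edges,
#'   unit weights, igraph) and `coords` (node coordinates; main chain first,
#'   then side chains in order).
#' @export
toy_chain_graph <- function(main_len = 100L, side_len = 20L, attachments = c(30L, 60L)) {
  main_len <- as.integer(main_len); side_len <- as.integer(side_len)
  attachments <- as.integer(attachments)
  if (length(attachments) && (min(attachments) < 1L || max(attachments) > main_len))
    .stopf("invalid attachment index (must be in 1..%d)", main_len)
  coords <- cbind(0, 0, seq_len(main_len) - 1)
  edges <- cbind(seq_len(main_len - 1L), 2:main_len)
  nxt <- main_len
  for (s in seq_along(attachments)) {
    a <- attachments[s]
    phi <- pi / 2 * s
    d <- c(cos(phi) * sqrt(0.5), sin(phi) * sqrt(0.5), sqrt(0.5))  # 45 deg tilt
    base <- coords[a, ]
    ids <- nxt + seq_len(side_len)
    coords <- rbind(coords, matrix(base, side_len, 3, byrow = TRUE) +
                      outer(seq_len(side_len), d))
    edges <- rbind(edges, c(a, ids[1]))
    if (side_len > 1L) edges <- rbind(edges, cbind(ids[-side_len], ids[-1L]))
    nxt <- nxt + side_len
  }
  n <- nrow(coords)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- rep(1, nrow(edges))
  graph <- structure(list(knn = NULL, knn_dist = NULL, edges = edges,
                          weights = rep(1, nrow(edges)), k = NA_integer_, g = g,
                          bridges = data.frame(), n = n),
                     class = "similarity_graph")
  list(graph = graph, coords = coords)
}

#' Build a plant whose geometry forces a specific botanical defect
#'
#' Returns a synthetic plant that makes the first-pass pipeline produce the
#' requested inconsistency: cases 1 and 2 use a petiole so short that it
#' fuses with its leaf blade (attached to the main stem for case 1, to a
#' branch for case 2); case 3 attaches a whorl of three such leaves near a
#' branch tip, so one linear node touches more than two blade/apex nodes;
#' case 4 places two leaves so close that their blades touch and region
#' growing merges them.
#'
#' @param kind defect case, 1-4.
#' @param seed RNG seed (default 0).
#' @return List with `cloud`, `truth` (as in [generate_plant]) and
#'   `description` of the injected defect.
#' @export
make_defect_fixture <- function(kind, seed = 0L) {
  kind <- as.integer(kind)
  stopifnot(kind %in% 1:4)
  # a stem clearly heavier than its single branch, so the leaf-load contest
  # always selects the true stem
  base_args <- list(stem_length = 60, n_branches = 1, branch_lengths = 18,
                    branch_angles = 45, branch_heights = 0.45, branch_azimuths = 200,
                    branch_leaf_fracs = 0.5,
                    n_leaves = 5, leaf_heights = c(0.15, 0.3, 0.5, 0.7, 0.88),
                    leaf_azimuths = c(90, 210, 330, 60, 150),
                    seed = seed)
  if (kind == 1L) {
    # extra leaf with a petiole far below graph resolution -> fuses with blade
    args <- utils::modifyList(base_args, list(
      n_leaves = 6, leaf_heights = c(0.15, 0.3, 0.5, 0.7, 0.88, 0.6),
      leaf_azimuths = c(90, 210, 330, 60, 150, 270)))
    spec <- do.call(plant_spec, args)
    spec$fx_leaf <- 6L
    spec$fx_petiole_length <- 1.2
    desc <- "leaf 6 has a 1.2 mm petiole: its blade cluster touches the main stem (case 1)"
  } else if (kind == 2L) {
    spec <- do.call(plant_spec, base_args)
    spec$fx_branch_leaf <- list(frac = 0.62, petiole_length = 1.2, roll = 270)
    desc <- "a 1.2 mm petiole leaf sits on the branch: blade only connected to a branch node (case 2)"
  } else if (kind == 3L) {
    spec <- do.call(plant_spec, base_args)
    spec$fx_whorl <- list(frac = c(0.55, 0.7, 0.85), petiole_length = 1.2,
                          roll = c(100, 220, 340))
    desc <- "three short-petiole leaves whorled on the branch: one linear node touches >2 blades (case 3)"
  } else {
    # two leaves at the same height with close azimuths: blades touch
    args <- utils::modifyList(base_args, list(
      n_leaves = 7, leaf_heights = c(0.15, 0.3, 0.5, 0.7, 0.88, 0.42, 0.42),
      leaf_azimuths = c(90, 210, 300, 60, 150, 0, 26)))
    spec <- do.call(plant_spec, args)
    desc <- "two touching blades merge under region growing: two paths to the root (case 4)"
  }
  out <- .generate_with_extras(spec)
  list(cloud = out$cloud, truth = out$truth, description = desc)
}

# generate_plant plus fixture-only extras (short-petiole leaves on stem or
# branch). Extras are sampled with the same density and carry proper ground
# truth (tiny petiole instances are real organs, merely unresolvable).
.generate_with_extras <- function(spec) {
  out <- generate_plant(spec)
  extras <- list()
  set.seed(spec$seed + 7L)
  radial <- function(az) c(cos(az * pi / 180), sin(az * pi / 180), 0)
  zhat <- c(0, 0, 1)
  add_short_leaf <- function(attach, out_dir, plen) {
    pet <- .sample_tube(attach, out_dir, plen, spec$petiole_radius, spec$sampling_density)
    side <- .frame_of(out_dir)$e2
    bl <- .sample_blade(attach + plen * out_dir, out_dir, side,
                        spec$blade_shape[1], spec$blade_shape[2],
                        spec$sampling_density, spec$blade_serration)
    list(list(p = pet, class = "petiole"), list(p = bl, class = "leaf_blade"))
  }
  if (!is.null(spec$fx_leaf)) {
    i <- spec$fx_leaf
    az <- spec$leaf_azimuths[i]
    attach <- c(0, 0, spec$leaf_heights[i] * spec$stem_length) + spec$stem_radius * radial(az)
    th <- spec$petiole_angle * pi / 180
    d <- sin(th) * radial(az) + cos(th) * zhat
    extras <- c(extras, add_short_leaf(attach, d / sqrt(sum(d^2)),
                                       spec$fx_petiole_length))
    # drop the full-length leaf i that generate_plant already produced
    drop_inst <- unique(out$truth$instance[out$truth$semantic %in% c("petiole", "leaf_blade")])
    keep <- !(out$truth$instance %in% .leaf_instances_of(out, i))
    out <- .filter_points(out, keep)
  }
  if (!is.null(spec$fx_branch_leaf)) {
    extras <- c(extras, .branch_leaf_extra(spec, spec$fx_branch_leaf$frac,
                                           spec$fx_branch_leaf$petiole_length,
                                           spec$fx_branch_leaf$roll))
  }
  if (!is.null(spec$fx_whorl)) {
    for (j in seq_along(spec$fx_whorl$frac))
      extras <- c(extras, .branch_leaf_extra(spec, spec$fx_whorl$frac[j],
                                             spec$fx_whorl$petiole_length,
                                             spec$fx_whorl$roll[j]))
  }
  if (!length(extras)) return(out)
  .append_points(out, extras)
}

# leaf (petiole+blade) attached to branch 1 at the given length fraction
.branch_leaf_extra <- function(spec, frac, plen, roll) {
  radial <- function(az) c(cos(az * pi / 180), sin(az * pi / 180), 0)
  zhat <- c(0, 0, 1)
  az <- spec$branch_azimuths[1]
  th <- spec$branch_angles[1] * pi / 180
  d <- sin(th) * radial(az) + cos(th) * zhat
  d <- d / sqrt(sum(d^2))
  base <- c(0, 0, spec$branch_heights[1] * spec$stem_length) + spec$stem_radius * radial(az)
  attach <- base + frac * spec$branch_lengths[1] * d
  fr <- .frame_of(d)
  out_dir <- cos(roll * pi / 180) * fr$e1 + sin(roll * pi / 180) * fr$e2 + 0.4 * d
  out_dir <- out_dir / sqrt(sum(out_dir^2))
  attach <- attach + spec$branch_radius * out_dir
  pet <- .sample_tube(attach, out_dir, plen, spec$petiole_radius, spec$sampling_density)
  side <- .frame_of(out_dir)$e2
  bl <- .sample_blade(attach + plen * out_dir, out_dir, side, spec$blade_shape[1],
                      spec$blade_shape[2], spec$sampling_density, spec$blade_serration)
  list(list(p = pet, class = "petiole"), list(p = bl, class = "leaf_blade"))
}

.leaf_instances_of <- function(out, leaf_index) {
  # petiole/blade instances are emitted in leaf order, two per leaf, right
  # after the stem instance (instance 1)
  c(2L * leaf_index, 2L * leaf_index + 1L)
}

.filter_points <- function(out, keep) {
  cl <- out$cloud
  out$cloud <- point_cloud(cl$coords[keep, , drop = FALSE],
                           semantic_label = cl$semantic_label[keep],
                           instance_label = cl$instance_label[keep],
                           up_axis = cl$up_axis)
  out$truth$semantic <- out$truth$semantic[keep]
  out$truth$instance <- out$truth$instance[keep]
  out
}

.append_points <- function(out, extras) {
  cl <- out$cloud
  xyz <- cl$coords; sem <- cl$semantic_label; inst <- cl$instance_label
  nxt <- max(inst)
  for (ex in extras) {
    nxt <- nxt + 1L
    xyz <- rbind(xyz, ex$p)
    sem <- c(sem, rep(ex$class, nrow(ex$p)))
    inst <- c(inst, rep(nxt, nrow(ex$p)))
    out$truth$class_of_instance[nxt] <- ex$class
    if (ex$class == "leaf_blade")
      out$truth$blade_areas[as.character(nxt)] <-
        pi * prod(out$truth$spec$blade_shape) * (1 + out$truth$spec$blade_serration[1]^2 / 2)
  }
  out$cloud <- point_cloud(xyz, semantic_label = sem, instance_label = inst,
                           up_axis = cl$up_axis)
  out$truth$semantic <- sem
  out$truth$instance <- inst
  out
}
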