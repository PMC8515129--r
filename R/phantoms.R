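#' Digital phantom specification
#'
#' Describes an analytic solid (plus two parallel carotid tubes) to be
#' digitized onto a voxel grid with closed-form morphometric truth, for
#' validating the measurement pipeline without patient data.
#'
#' Shapes: `"snowman"` — two intersecting spheres stacked along the axial
#' axis (the lower sphere plays the intrasellar part, the junction circle
#' is the waist); `"ellipsoid"` — a single axis-aligned (optionally
#' in-plane rotated) ellipsoid; `"box"` — an axis-aligned cuboid.
#'
#' @param shape `"snowman"`, `"ellipsoid"` or `"box"`.
#' @param r_upper,r_lower snowman sphere radii, mm (upper/suprasellar and
#'   lower/intrasellar).
#' @param center_distance snowman center separation along the axial axis,
#'   mm; must give intersecting spheres.
#' @param semi_axes ellipsoid semi-axes (x, y, z), mm.
#' @param box_dims box edge lengths (x, y, z), mm.
#' @param carotid_gap distance between the facing (medial) tube walls, mm.
#' @param carotid_radius tube radius, mm.
#' @param voxel isotropic voxel size, mm.
#' @param rotation_deg in-plane (xy) rotation applied to the solid before
#'   digitization.
#' @param margin grid padding around the solid, mm.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c("snowman", "ellipsoid", "box"),
                         r_upper = 12, r_lower = 9, center_distance = 15,
                         semi_axes = c(15, 10, 8),
                         box_dims = c(20, 10, 10),
                         carotid_gap = 24, carotid_radius = 2,
                         voxel = 0.5, rotation_deg = 0, margin = 3) {
  shape <- match.arg(shape)
  stopifnot(voxel > 0, carotid_gap > 0, carotid_radius > 0, margin >= 0)
  if (shape == "snowman") {
    stopifnot(r_upper > 0, r_lower > 0)
    if (center_distance >= r_upper + r_lower ||
        center_distance <= abs(r_upper - r_lower))
      stop("snowman spheres must intersect in a circle")
  }
  if (shape == "ellipsoid") stopifnot(all(semi_axes > 0))
  if (shape == "box") stopifnot(all(box_dims > 0))
  min_dim <- switch(shape,
                    snowman = 2 * min(r_upper, r_lower),
                    ellipsoid = 2 * min(semi_axes),
                    box = min(box_dims))
  if (min_dim < voxel) stop("solid smaller than one voxel")
  structure(list(shape = shape, r_upper = r_upper, r_lower = r_lower,
                 center_distance = center_distance, semi_axes = semi_axes,
                 box_dims = box_dims, carotid_gap = carotid_gap,
                 carotid_radius = carotid_radius, voxel = voxel,
                 rotation_deg = rotation_deg, margin = margin),
            class = "phantom_spec")
}

sphere_cap_volume <- function(r, h) {
  h <- max(0, min(h, 2 * r))
  pi * h^2 * (3 * r - h) / 3
}

# volume of the part of an axis-aligned ellipsoid above the plane z = z0
ellipsoid_above <- function(a, b, c, z0) {
  z0 <- max(-c, min(c, z0))
  pi * a * b * (2 * c / 3 - z0 + z0^3 / (3 * c^2))
}

#' Digitize a phantom with analytic truth
#'
#' Renders the analytic solid of a [phantom_spec()] onto an isotropic
#' voxel grid (a voxel belongs to a structure iff its center lies inside
#' the solid) together with two carotid tubes, and returns both the
#' labeled mask and the closed-form morphometric truth.
#'
#' For the snowman the truth includes the junction-plane coordinate `z0`
#' (the waist), the spherical-cap volumes above (`v1`) and below (`v2`)
#' the junction, and the analytic maximum horizontal diameters; the lower
#' sphere is centered at z = 0.  Digitization involves no randomness, so
#' identical specs yield identical masks.
#'
#' @param spec a [phantom_spec()].
#' @return List with `mask` (a [voxel_mask]) and `truth` (list with
#'   `v1`, `v2`, `tv`, `d1_intra`, `d1_whole`, `d2`, `z0`; volume fields
#'   are `NA` for shapes without a canonical partition plane).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  vx <- spec$voxel
  th <- spec$rotation_deg * pi / 180
  rot_x <- function(x, y) x * cos(th) + y * sin(th)
  rot_y <- function(x, y) -x * sin(th) + y * cos(th)

  xy_extent <- switch(spec$shape,
                      snowman = max(spec$r_upper, spec$r_lower),
                      ellipsoid = max(spec$semi_axes[1:2]),
                      box = sqrt(sum(spec$box_dims[1:2]^2)) / 2)
  z_range <- switch(spec$shape,
                    snowman = c(-spec$r_lower,
                                spec$center_distance + spec$r_upper),
                    ellipsoid = c(-spec$semi_axes[3], spec$semi_axes[3]),
                    box = c(-spec$box_dims[3] / 2, spec$box_dims[3] / 2))
  tube_cx <- spec$carotid_gap / 2 + spec$carotid_radius
  half_x <- ceiling((tube_cx + spec$carotid_radius + spec$margin) / vx)
  half_y <- ceiling((max(xy_extent, spec$carotid_radius) + spec$margin) / vx)
  xs <- (-half_x:half_x) * vx
  ys <- (-half_y:half_y) * vx
  zs <- seq(floor((z_range[1] - spec$margin) / vx),
            ceiling((z_range[2] + spec$margin) / vx)) * vx

  g <- expand.grid(x = xs, y = ys)
  xr <- rot_x(g$x, g$y)
  yr <- rot_y(g$x, g$y)
  labels <- array(0L, dim = c(length(xs), length(ys), length(zs)))
  in_tube <- (abs(g$x) - tube_cx)^2 + g$y^2 <= spec$carotid_radius^2 &
    sign(g$x) != 0
  left_tube <- in_tube & g$x < 0
  right_tube <- in_tube & g$x > 0
  for (k in seq_along(zs)) {
    z <- zs[k]
    inside <- switch(spec$shape,
      snowman = (xr^2 + yr^2 + z^2 <= spec$r_lower^2) |
        (xr^2 + yr^2 + (z - spec$center_distance)^2 <= spec$r_upper^2),
      ellipsoid = (xr / spec$semi_axes[1])^2 + (yr / spec$semi_axes[2])^2 +
        (z / spec$semi_axes[3])^2 <= 1,
      box = abs(xr) <= spec$box_dims[1] / 2 &
        abs(yr) <= spec$box_dims[2] / 2 & abs(z) <= spec$box_dims[3] / 2)
    sl <- integer(nrow(g))
    sl[left_tube] <- 2L
    sl[right_tube] <- 3L
    sl[inside] <- 1L                     # tumor has priority on overlap
    labels[, , k] <- sl
  }
  mask <- voxel_mask(labels, spacing = rep(vx, 3), axial_axis = 3,
                     origin = c(xs[1], ys[1], zs[1]))
  if (xy_extent > spec$carotid_gap / 2)
    warning("tumor may overlap the carotid tubes; the analytic D2 is ",
            "only valid on slices where they are disjoint")

  truth <- switch(spec$shape,
    snowman = {
      d <- spec$center_distance
      z0 <- (d^2 + spec$r_lower^2 - spec$r_upper^2) / (2 * d)
      v1 <- sphere_cap_volume(spec$r_upper, d + spec$r_upper - z0)
      v2 <- sphere_cap_volume(spec$r_lower, spec$r_lower + z0)
      d1_intra <- if (z0 >= 0) 2 * spec$r_lower
                  else 2 * sqrt(spec$r_lower^2 - z0^2)
      list(v1 = v1, v2 = v2, tv = v1 + v2, d1_intra = d1_intra,
           d1_whole = 2 * max(spec$r_upper, spec$r_lower),
           d2 = spec$carotid_gap, z0 = z0)
    },
    ellipsoid = list(
      v1 = NA_real_, v2 = NA_real_,
      tv = 4 * pi * prod(spec$semi_axes) / 3,
      d1_intra = NA_real_, d1_whole = 2 * max(spec$semi_axes[1:2]),
      d2 = spec$carotid_gap, z0 = NA_real_),
    box = list(
      v1 = NA_real_, v2 = NA_real_, tv = prod(spec$box_dims),
      d1_intra = NA_real_, d1_whole = sqrt(sum(spec$box_dims[1:2]^2)),
      d2 = spec$carotid_gap, z0 = NA_real_))
  list(mask = mask, truth = truth)
}

# volume of an axis-aligned ellipsoid part above z0, exported for phantom
# checks at arbitrary split planes
#' Analytic ellipsoid volume above an axial plane
#' @param semi_axes semi-axes (x, y, z), mm.
#' @param z0 plane coordinate, mm (ellipsoid centered at 0).
#' @return Volume above the plane, mm^3.
#' @export
ellipsoid_volume_above <- function(semi_axes, z0) {
  ellipsoid_above(semi_axes[1], semi_axes[2], semi_axes[3], z0)
}
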