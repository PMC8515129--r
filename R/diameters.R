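# in-plane Feret diameter of a point set (max pairwise distance, mm)
max_pairwise_distance <- function(xy) {
  n <- nrow(xy)
  if (n < 2) return(0)
  if (n > 3) {
    hull <- tryCatch(grDevices::chull(xy), error = function(e) seq_len(n))
    xy <- xy[hull, , drop = FALSE]
    n <- nrow(xy)
    if (n < 2) return(0)
  }
  max(stats::dist(xy))
}

#' Maximum horizontal tumor diameter
#'
#' For every axial slice, the in-plane diameter is the maximum pairwise
#' Euclidean distance between tumor voxel centers on that slice (the
#' planar Feret diameter, computed on the convex hull and identical to
#' brute-force all-pairs search).  D1 is the maximum of these over slices;
#' the reference slice is the slice attaining it, ties broken toward the
#' lowest slice index.
#'
#' Distances follow the voxel-center-to-center convention, which
#' understates the physical extent by up to one voxel but is unambiguous
#' and directly checkable against analytic phantoms.
#'
#' @param mask a [voxel_mask] with at least one tumor voxel (typically the
#'   intrasellar part from [split_by_plane()]).
#' @return A list with `d1` (mm) and `reference_slice` (1-based axial
#'   slice index).  A single-voxel tumor yields `d1 = 0` with a warning
#'   rather than an error, so batch runs survive degenerate masks.
#' @export
max_horizontal_diameter <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  counts <- slice_counts(mask, "tumor")
  occ <- which(counts > 0)
  if (length(occ) == 0) stop("no tumor voxels")
  best <- -1
  best_k <- NA_integer_
  for (k in occ) {
    d <- max_pairwise_distance(slice_coords(mask, k, "tumor"))
    if (d > best) {        # strict: ties keep the lowest slice
      best <- d
      best_k <- k
    }
  }
  if (best == 0)
    warning("degenerate tumor extent: maximum horizontal diameter is 0")
  list(d1 = best, reference_slice = best_k)
}

#' Intercarotid distance on a reference slice
#'
#' D2 is the minimum in-plane Euclidean distance between any left-carotid
#' voxel center and any right-carotid voxel center on the given axial
#' slice.  The minimizing pair necessarily lies on the facing (medial)
#' vessel walls, which realizes the "inner surface" distance without an
#' explicit wall-extraction step.
#'
#' @param mask a [voxel_mask] carrying both carotid labels.
#' @param reference_slice 1-based axial slice index (normally the slice
#'   where D1 is attained, from [max_horizontal_diameter()]).
#' @return D2 in mm.
#' @export
intercarotid_distance <- function(mask, reference_slice) {
  stopifnot(inherits(mask, "voxel_mask"))
  left <- slice_coords(mask, reference_slice, "left_carotid")
  right <- slice_coords(mask, reference_slice, "right_carotid")
  if (nrow(left) == 0)
    stop("left carotid not present on reference slice")
  if (nrow(right) == 0)
    stop("right carotid not present on reference slice")
  dx <- outer(left[, 1], right[, 1], "-")
  dy <- outer(left[, 2], right[, 2], "-")
  sqrt(min(dx * dx + dy * dy))
}

#' Intercarotid distance from landmark points
#'
#' Fallback when carotid masks are unavailable: D2 as the Euclidean
#' distance between two manually placed landmark points (world
#' coordinates, mm) on the medial carotid walls.
#'
#' @param left,right numeric coordinate vectors of equal length (2D or 3D,
#'   mm).
#' @return Distance in mm.
#' @export
landmark_distance <- function(left, right) {
  left <- as.numeric(left)
  right <- as.numeric(right)
  if (length(left) != length(right) || !length(left) %in% 2:3)
    stop("landmarks must be two coordinate vectors of equal length (2 or 3)")
  sqrt(sum((left - right)^2))
}
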