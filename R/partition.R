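#' Sellar partition specification
#'
#' Describes how the suprasellar/intrasellar boundary (the diaphragm sella
#' level) is obtained: either an explicit axial plane at `z0` mm, or
#' automatic detection of the "waist" of a dumbbell-shaped tumor from its
#' axial cross-sectional area profile.
#'
#' @param mode `"explicit_plane"` or `"waist_detected"`.
#' @param z0 boundary coordinate in mm along the axial axis; required for
#'   `"explicit_plane"`, ignored (recomputed) for `"waist_detected"`.
#' @return An object of class `sellar_partition`.
#' @export
sellar_partition <- function(mode = c("explicit_plane", "waist_detected"),
                             z0 = NULL) {
  mode <- match.arg(mode)
  if (mode == "explicit_plane") {
    if (is.null(z0) || !is.finite(z0))
      stop("explicit_plane partition requires a finite z0 (mm)")
    z0 <- as.numeric(z0)
  }
  structure(list(mode = mode, z0 = z0), class = "sellar_partition")
}

#' Split a tumor mask at an axial plane
#'
#' Partitions the tumor voxels of a mask at the axial coordinate `z0`
#' (mm): voxel centers strictly above `z0` go to the suprasellar part,
#' centers at or below `z0` to the intrasellar part.  Centers lying
#' exactly on the plane are intrasellar, which is conservative toward V2
#' and consistent with counting infrasellar extension into the intrasellar
#' volume.  Carotid labels are carried unchanged into both parts.
#'
#' @param mask a [voxel_mask] with at least one tumor voxel.
#' @param z0 plane coordinate in mm along the axial axis.
#' @return A list with [voxel_mask] elements `supra` and `intra`; their
#'   tumor voxel sets are a disjoint partition of the input tumor.
#' @export
split_by_plane <- function(mask, z0) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (!is.finite(z0)) stop("z0 must be finite")
  tum <- label_value(mask, "tumor")
  if (!any(mask$labels == tum)) stop("no tumor voxels")
  z <- axial_coordinates(mask)
  above <- z > z0
  drop_tumor <- function(keep_slices) {
    lab <- mask$labels
    ax <- mask$axial_axis
    drop <- which(!keep_slices)
    for (k in drop) {
      sl <- axial_slice(mask, k)
      sl[sl == tum] <- 0L
      if (ax == 1) lab[k, , ] <- sl
      else if (ax == 2) lab[, k, ] <- sl
      else lab[, , k] <- sl
    }
    out <- mask
    out$labels <- lab
    out
  }
  list(supra = drop_tumor(above), intra = drop_tumor(!above))
}

#' Detect the waist level of a dumbbell-shaped tumor
#'
#' Computes the axial cross-sectional tumor area profile A(z), smooths it
#' with a centered moving average, and returns the axial coordinate of the
#' minimum of A(z) restricted to slices strictly between the two largest
#' local maxima of the profile.  This operationalizes the "waist sign"
#' used as the supra/intrasellar boundary when the diaphragm sella is not
#' directly visible.  Ties in the minimum are broken toward the lower
#' (caudal) slice.
#'
#' @param mask a [voxel_mask] whose tumor occupies at least 3 axial slices.
#' @param smooth_window odd width (slices) of the moving-average smoother
#'   applied to the area profile before extremum search; 1 disables
#'   smoothing.  Default 3, which suppresses single-slice digitization
#'   jitter without displacing a genuine waist.
#' @return The waist coordinate `z0` in mm along the axial axis.
#' @export
detect_waist <- function(mask, smooth_window = 3) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (smooth_window < 1 || smooth_window %% 2 != 1)
    stop("smooth_window must be a positive odd integer")
  counts <- slice_counts(mask, "tumor")
  occ <- which(counts > 0)
  if (length(occ) < 3) stop("tumor must occupy at least 3 axial slices")
  rng <- occ[1]:occ[length(occ)]
  a <- counts[rng]
  if (smooth_window > 1) {
    half <- (smooth_window - 1) / 2
    padded <- c(rep(a[1], half), a, rep(a[length(a)], half))
    a <- stats::filter(padded, rep(1 / smooth_window, smooth_window),
                       sides = 2)
    a <- as.numeric(a[(half + 1):(half + length(rng))])
  }
  # run-length compression so flat plateaus count as single extrema
  r <- rle(a)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  nr <- length(r$values)
  is_max <- vapply(seq_len(nr), function(i) {
    left <- if (i > 1) r$values[i - 1] else -Inf
    right <- if (i < nr) r$values[i + 1] else -Inf
    r$values[i] > left && r$values[i] > right
  }, logical(1))
  peaks <- which(is_max)
  if (length(peaks) < 2)
    stop("no waist detected; supply explicit plane")
  top2 <- peaks[order(r$values[peaks], decreasing = TRUE)[1:2]]
  top2 <- sort(top2)
  lo <- ends[top2[1]] + 1
  hi <- starts[top2[2]] - 1
  if (lo > hi) stop("no waist detected; supply explicit plane")
  between <- a[lo:hi]
  k_local <- lo + which(between == min(between))[1] - 1  # lowest tied slice
  z <- axial_coordinates(mask)
  z[rng[k_local]]
}
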