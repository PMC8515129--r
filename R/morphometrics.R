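#' Full morphometric measurement of a labeled mask
#'
#' Runs the complete per-patient measurement: partitions the tumor at the
#' sellar boundary (explicit plane or detected waist), computes the
#' suprasellar volume V1 and intrasellar volume V2 (which by convention
#' includes any infrasellar extension), the maximum horizontal tumor
#' diameter D1 with its reference slice, the intercarotid distance D2 on
#' that slice, and the V-D score V1/V2 + D1/D2.
#'
#' @param mask a [voxel_mask] with tumor and (unless `carotid_landmarks`
#'   is given) both carotid labels.
#' @param partition a [sellar_partition].
#' @param d1_scope `"intrasellar"` (default) measures D1 on the
#'   intrasellar part only, matching the anchoring of the reference layer
#'   within the intrasellar tumor; `"whole"` measures it on the entire
#'   tumor.
#' @param carotid_landmarks optional list with elements `left` and `right`
#'   (mm coordinates); when supplied, D2 is their Euclidean distance and
#'   carotid masks are not required.
#' @return An object of class `morphometrics`: a list with fields `v1`,
#'   `v2`, `tv`, `d1`, `d2` (mm^3 / mm), `ratio_v` (V1/V2), `ratio_d`
#'   (D1/D2), `vd`, `reference_slice`, and `z0` (boundary used, mm).
#'   `tv = v1 + v2` holds exactly in voxel arithmetic.
#' @export
measure_morphometrics <- function(mask, partition,
                                  d1_scope = c("intrasellar", "whole"),
                                  carotid_landmarks = NULL) {
  stopifnot(inherits(mask, "voxel_mask"),
            inherits(partition, "sellar_partition"))
  d1_scope <- match.arg(d1_scope)
  z0 <- if (partition$mode == "waist_detected") detect_waist(mask)
        else partition$z0
  parts <- split_by_plane(mask, z0)
  v1 <- mask_volume(parts$supra, "tumor")
  v2 <- mask_volume(parts$intra, "tumor")
  if (v2 == 0) stop("V-D undefined for V2 = 0 (tumor entirely suprasellar)")
  d1_mask <- if (d1_scope == "intrasellar") parts$intra else mask
  feret <- max_horizontal_diameter(d1_mask)
  d2 <- if (!is.null(carotid_landmarks))
    landmark_distance(carotid_landmarks$left, carotid_landmarks$right)
  else intercarotid_distance(mask, feret$reference_slice)
  structure(list(v1 = v1, v2 = v2, tv = v1 + v2,
                 d1 = feret$d1, d2 = d2,
                 ratio_v = v1 / v2, ratio_d = feret$d1 / d2,
                 vd = vd_value(v1, v2, feret$d1, d2),
                 reference_slice = feret$reference_slice, z0 = z0),
            class = "morphometrics")
}

#' @export
print.morphometrics <- function(x, ...) {
  cat(sprintf("morphometrics (boundary z0 = %.2f mm)\n", x$z0))
  cat(sprintf("  V1 (suprasellar):  %10.2f mm^3\n", x$v1))
  cat(sprintf("  V2 (intrasellar):  %10.2f mm^3\n", x$v2))
  cat(sprintf("  TV (total):        %10.2f mm^3\n", x$tv))
  cat(sprintf("  D1: %.2f mm (slice %d)    D2: %.2f mm\n",
              x$d1, x$reference_slice, x$d2))
  cat(sprintf("  V1/V2 = %.4f   D1/D2 = %.4f   V-D = %.4f\n",
              x$ratio_v, x$ratio_d, x$vd))
  invisible(x)
}

#' @export
as.data.frame.morphometrics <- function(x, ...) {
  data.frame(v1 = x$v1, v2 = x$v2, tv = x$tv, d1 = x$d1, d2 = x$d2,
             ratio_v = x$ratio_v, ratio_d = x$ratio_d, vd = x$vd,
             reference_slice = x$reference_slice, z0 = x$z0)
}
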