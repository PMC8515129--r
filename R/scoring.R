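#' The V-D score
#'
#' The V-D value summarizes the longitudinal and horizontal extension of a
#' pituitary adenoma as the sum of the supra/intrasellar volume ratio and
#' the tumor-diameter/intercarotid-distance ratio:
#' `V-D = V1/V2 + D1/D2`.  All arguments are vectorized.
#'
#' @param v1 suprasellar volume, mm^3 (>= 0).
#' @param v2 intrasellar volume, mm^3 (> 0).
#' @param d1 maximum horizontal tumor diameter, mm (>= 0).
#' @param d2 intercarotid distance, mm (> 0).
#' @return The dimensionless V-D value.
#' @examples
#' vd_value(0, 1000, 20, 20)  # purely intrasellar tumor: V-D = D1/D2 = 1
#' @export
vd_value <- function(v1, v2, d1, d2) {
  ok <- stats::complete.cases(v1, v2, d1, d2)
  if (any(v2[ok] <= 0) || any(d2[ok] <= 0))
    stop("V-D undefined: V2 and D2 must be positive")
  if (any(v1[ok] < 0) || any(d1[ok] < 0))
    stop("V1 and D1 must be non-negative")
  v1 / v2 + d1 / d2
}

#' Tumor size classification
#'
#' Classifies adenomas by their largest diameter: small (< 15 mm), large
#' (15 to < 30 mm) and giant (>= 30 mm).  The boundaries are closed on the
#' upper class, so exactly 15 mm is large and exactly 30 mm is giant.
#'
#' @param d1 largest tumor diameter in mm (> 0); vectorized.
#' @return Factor with ordered levels `small < large < giant`.
#' @export
classify_size <- function(d1) {
  if (any(!is.finite(d1) | d1 <= 0))
    stop("d1 must be positive and finite")
  cls <- ifelse(d1 < 15, "small", ifelse(d1 < 30, "large", "giant"))
  factor(cls, levels = c("small", "large", "giant"), ordered = TRUE)
}

#' Recurrence classification from follow-up volumetry
#'
#' Applies the radiological recurrence rule: after total resection, any
#' follow-up tumor larger than 0.1 cm^3 (100 mm^3) is recurrent; after
#' subtotal resection, recurrence means the residual tumor grew by more
#' than 25%.  Both thresholds are strict (growth of exactly 25% is not
#' recurrence).
#'
#' @param resection_extent `"total"` or `"subtotal"`.
#' @param followup_volume tumor volume at follow-up, mm^3 (>= 0).
#' @param residual_volume immediate postoperative residual volume, mm^3;
#'   required and positive for subtotal resection.
#' @return `"recurrent"` or `"non_recurrent"`.
#' @export
classify_recurrence <- function(resection_extent = c("total", "subtotal"),
                                followup_volume, residual_volume = NULL) {
  resection_extent <- match.arg(resection_extent)
  if (!is.finite(followup_volume) || followup_volume < 0)
    stop("followup_volume must be a non-negative number (mm^3)")
  if (resection_extent == "total") {
    if (followup_volume > 100) "recurrent" else "non_recurrent"
  } else {
    if (is.null(residual_volume) || !is.finite(residual_volume) ||
        residual_volume <= 0)
      stop("subtotal resection requires a positive residual_volume")
    if (followup_volume > 1.25 * residual_volume) "recurrent"
    else "non_recurrent"
  }
}

#' Inter-rater volume discordance flag
#'
#' Flags cases where two raters' tumor-volume estimates differ by more
#' than 20%, the trigger for senior adjudication of the segmentation.
#' The relative difference is taken against the mean of the two estimates,
#' which is symmetric in the raters.
#'
#' @param vol_a,vol_b the two raters' volumes, mm^3 (> 0).
#' @return `TRUE` if the discrepancy exceeds 20%.
#' @export
flag_rater_discordance <- function(vol_a, vol_b) {
  if (any(!is.finite(c(vol_a, vol_b))) || any(c(vol_a, vol_b) <= 0))
    stop("rater volumes must be positive")
  abs(vol_a - vol_b) / ((vol_a + vol_b) / 2) > 0.20
}
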