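#' ROC analysis with Youden-index cutoff
#'
#' Builds the full ROC curve of a score against a binary outcome (higher
#' scores indicate the positive class), sweeping every distinct observed
#' score as a threshold (rule: positive if score >= threshold).  The AUC
#' is computed by the trapezoidal rule over (1 - specificity,
#' sensitivity), which is identical to the Mann-Whitney concordance
#' probability with half-credit for ties.  The optimal cutoff maximizes
#' the Youden index J = sensitivity + specificity - 1; when the optimum
#' lies between two observed scores the midpoint is reported, and ties in
#' J are broken toward the lower cutoff (higher sensitivity).
#'
#' @param scores numeric score vector.
#' @param labels binary outcome (logical or 0/1); both classes required.
#' @return Object of class `roc_result`: list with `thresholds`,
#'   `sensitivity`, `specificity` (per threshold, including the
#'   all-negative extreme), `auc`, `youden` (J per threshold), `cutoff`,
#'   `sensitivity_at_cutoff`, `specificity_at_cutoff`, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(scores, labels) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary (0/1 or logical)")
  keep <- stats::complete.cases(scores, labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present for ROC analysis")
  s <- sort(unique(scores))
  thr <- c(s, Inf)                       # Inf = classify everything negative
  sens <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n_pos,
                 numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & labels == 0) / n_neg,
                 numeric(1))
  fpr <- 1 - spec
  ord <- order(fpr, sens)                # (1,1) ... (0,0) along the sweep
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)
  auc <- abs(auc)
  j <- sens + spec - 1
  best <- which(j == max(j))[1]          # lowest threshold among ties
  # the optimum "score >= s[k]" rule separates s[k-1] from s[k]: report
  # the midpoint when both exist
  cutoff <- if (best > 1 && is.finite(thr[best]))
    (thr[best] + s[which(s == thr[best]) - 1]) / 2
  else thr[best]
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, youden = j, cutoff = cutoff,
                 sensitivity_at_cutoff = sens[best],
                 specificity_at_cutoff = spec[best],
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' Rank-based (Mann-Whitney) AUC
#'
#' The concordance probability P(score_pos > score_neg) + 0.5 P(tie),
#' computed from midranks: `(sum of positive ranks - n1(n1+1)/2) / (n1 n0)`.
#' Equals the trapezoidal AUC of [roc_analysis()] on every input.
#'
#' @inheritParams roc_analysis
#' @return AUC in \[0, 1\].
#' @export
mann_whitney_auc <- function(scores, labels) {
  if (is.logical(labels)) labels <- as.integer(labels)
  keep <- stats::complete.cases(scores, labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)                       # midranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (n+ = %d, n- = %d)\n",
              x$auc, x$n_pos, x$n_neg))
  cat(sprintf("Youden-optimal cutoff = %.4g  (sensitivity %.3f, specificity %.3f)\n",
              x$cutoff, x$sensitivity_at_cutoff, x$specificity_at_cutoff))
  invisible(x)
}
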