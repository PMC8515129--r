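#' Kaplan-Meier recurrence-free analysis
#'
#' Product-limit (Kaplan-Meier) estimate of the recurrence-free survival
#' function, optionally stratified by a grouping variable, with a log-rank
#' test across groups.  Right-censored observations (non-recurrent
#' patients at last follow-up) are supported.  Estimation and the log-rank
#' test are delegated to the survival package.
#'
#' @param time non-negative event/censoring times (months).
#' @param event event indicator (1/TRUE = recurrence observed,
#'   0/FALSE = censored).
#' @param group optional grouping factor; every level must be non-empty.
#' @return Object of class `km_result`: list with `curves` (data frame of
#'   `group`, `time`, `n_risk`, `n_event`, `surv`), `logrank_chisq`,
#'   `logrank_df`, `logrank_p` (NA when a single group), and the
#'   underlying `survfit` object as `fit`.
#' @export
km_analysis <- function(time, event, group = NULL) {
  if (any(!is.finite(time)) || any(time < 0))
    stop("times must be finite and non-negative")
  event <- as.integer(event)
  if (!all(event %in% c(0L, 1L))) stop("event must be binary")
  if (is.null(group)) group <- rep("all", length(time))
  group <- as.factor(group)
  if (any(table(group) == 0) || nlevels(group) != length(unique(group)))
    stop("every group level must contain at least one subject")
  df <- data.frame(time = time, event = event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata <- if (is.null(fit$strata)) {
    rep(levels(group)[1], length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  curves <- data.frame(group = strata, time = fit$time,
                       n_risk = fit$n.risk, n_event = fit$n.event,
                       surv = fit$surv)
  if (nlevels(group) > 1) {
    lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
    chisq <- lr$chisq
    dfree <- length(lr$n) - 1
    p <- stats::pchisq(chisq, dfree, lower.tail = FALSE)
  } else {
    chisq <- NA_real_; dfree <- NA_integer_; p <- NA_real_
  }
  structure(list(curves = curves, logrank_chisq = chisq,
                 logrank_df = dfree, logrank_p = p, fit = fit),
            class = "km_result")
}

#' Survival probability at given times
#'
#' Step-function evaluation of a Kaplan-Meier curve: S(t) for one group
#' of a [km_analysis()] result (right-continuous, S(t) = 1 before the
#' first event).
#'
#' @param km a `km_result`.
#' @param times evaluation times.
#' @param group group level (defaults to the first).
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(km, times, group = NULL) {
  stopifnot(inherits(km, "km_result"))
  cv <- km$curves
  if (is.null(group)) group <- cv$group[1]
  cv <- cv[cv$group == group, ]
  vapply(times, function(t) {
    i <- which(cv$time <= t)
    if (length(i) == 0) 1 else cv$surv[max(i)]
  }, numeric(1))
}

#' @export
print.km_result <- function(x, ...) {
  ng <- length(unique(x$curves$group))
  cat(sprintf("Kaplan-Meier recurrence-free analysis (%d group%s)\n",
              ng, if (ng > 1) "s" else ""))
  if (!is.na(x$logrank_p))
    cat(sprintf("log-rank chi-square = %.3f (df = %d), p = %.4g\n",
                x$logrank_chisq, x$logrank_df, x$logrank_p))
  invisible(x)
}
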