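#' Full recurrence-prediction analysis of a cohort
#'
#' Runs the complete statistical pipeline around the V-D score on a
#' validated cohort table: derived morphometric columns (TV, V1/V2,
#' D1/D2, V-D, size class), a baseline group-summary table by recurrence
#' status, the Spearman correlation matrix of the score against Ki-67 and
#' hormone levels, univariate and multivariate logistic regressions of
#' recurrence on the radiological and clinical factors, ROC curves for
#' the V-D score and its comparators (Knosp grade, size class, V1/V2,
#' D1/D2), and a Kaplan-Meier analysis of recurrence-free time stratified
#' at the Youden-optimal V-D cutoff.  Patients with a V-D value exactly
#' equal to the cutoff are assigned to the high-V-D group.
#'
#' @param cohort cohort data frame in the [cohort_column_dictionary()]
#'   layout (validated on entry; all violations are reported together).
#' @param cutoff optional fixed V-D cutoff for the KM stratification;
#'   defaults to the Youden-optimal cutoff from the V-D ROC.
#' @param normality_alpha Shapiro-Wilk level of the summary-table
#'   normality gate.
#' @param min_group minimum number of patients required in each outcome
#'   group.
#' @return Object of class `vd_analysis_report`: list with
#'   `summary_table`, `spearman`, `logistic_univariate`,
#'   `logistic_multivariate`, `roc` (named list of [roc_analysis()]
#'   results), `cutoff`, `km` ([km_analysis()] result) and `metrics`
#'   (AUCs, cutoff, sensitivity, specificity, log-rank p).
#' @export
run_full_analysis <- function(cohort, cutoff = NULL,
                              normality_alpha = 0.05, min_group = 5) {
  cohort <- validate_cohort(cohort)
  sizes <- table(factor(cohort$recurrent, levels = 0:1))
  if (any(sizes < min_group))
    stop(sprintf(
      "each outcome group must have at least %d patients (got %d non-recurrent, %d recurrent)",
      min_group, sizes[["0"]], sizes[["1"]]))
  cohort$tv <- cohort$v1 + cohort$v2
  cohort$ratio_v <- cohort$v1 / cohort$v2
  cohort$ratio_d <- cohort$d1 / cohort$d2
  cohort$vd <- vd_value(cohort$v1, cohort$v2, cohort$d1, cohort$d2)
  cohort$size_class <- classify_size(cohort$d1)
  cohort$size_num <- as.integer(cohort$size_class)
  cohort$group <- factor(ifelse(cohort$recurrent == 1, "recurrent",
                                "non_recurrent"),
                         levels = c("non_recurrent", "recurrent"))

  summary_vars <- c("sex", "age", "knosp_f", "hardy_f", "size_class",
                    "tv", "v2", "v1", "ratio_v", "d1", "d2", "ratio_d",
                    "vd", "ki67", "prl", "testosterone", "lh", "fsh")
  cohort$knosp_f <- factor(cohort$knosp, levels = 0:4)
  cohort$hardy_f <- factor(cohort$hardy, levels = 1:5,
                           labels = c("I", "II", "III", "IV", "V"))
  summary_table <- summarize_cohort(cohort, "group", summary_vars,
                                    normality_alpha = normality_alpha)

  spearman <- spearman_matrix(
    cohort, c("vd", "ki67", "prl", "testosterone", "lh", "fsh"))

  uni_vars <- c("v2", "v1", "tv", "ratio_v", "knosp", "hardy",
                "size_num", "d1", "d2", "ratio_d", "ki67", "prl", "lh",
                "fsh", "testosterone", "vd")
  logistic_uni <- logistic_fit(cohort, "recurrent", uni_vars,
                               mode = "univariate")
  multi_vars <- c("v1", "tv", "knosp", "ratio_v", "d1", "d2", "vd")
  logistic_multi <- logistic_fit(cohort, "recurrent", multi_vars,
                                 mode = "multivariate")

  roc <- list(
    vd = roc_analysis(cohort$vd, cohort$recurrent),
    knosp = roc_analysis(cohort$knosp, cohort$recurrent),
    size = roc_analysis(cohort$size_num, cohort$recurrent),
    ratio_v = roc_analysis(cohort$ratio_v, cohort$recurrent),
    ratio_d = roc_analysis(cohort$ratio_d, cohort$recurrent))

  if (is.null(cutoff)) cutoff <- roc$vd$cutoff
  vd_group <- factor(ifelse(cohort$vd >= cutoff, "high_vd", "low_vd"),
                     levels = c("low_vd", "high_vd"))
  km <- if (nlevels(droplevels(vd_group)) == 2)
    km_analysis(cohort$time_months, cohort$recurrent, vd_group)
  else NULL

  metrics <- list(
    n = nrow(cohort),
    n_recurrent = unname(sizes[["1"]]),
    auc_vd = roc$vd$auc,
    auc_knosp = roc$knosp$auc,
    auc_size = roc$size$auc,
    auc_ratio_v = roc$ratio_v$auc,
    auc_ratio_d = roc$ratio_d$auc,
    cutoff = cutoff,
    sensitivity = roc$vd$sensitivity_at_cutoff,
    specificity = roc$vd$specificity_at_cutoff,
    logrank_p = if (is.null(km)) NA_real_ else km$logrank_p)

  structure(list(cohort = cohort, summary_table = summary_table,
                 spearman = spearman,
                 logistic_univariate = logistic_uni,
                 logistic_multivariate = logistic_multi,
                 roc = roc, cutoff = cutoff, km = km, metrics = metrics),
            class = "vd_analysis_report")
}

#' @export
print.vd_analysis_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("V-D recurrence analysis: n = %d (%d recurrent)\n",
              m$n, m$n_recurrent))
  cat(sprintf("  AUC: V-D %.3f | Knosp %.3f | size %.3f | V1/V2 %.3f | D1/D2 %.3f\n",
              m$auc_vd, m$auc_knosp, m$auc_size, m$auc_ratio_v,
              m$auc_ratio_d))
  cat(sprintf("  V-D cutoff %.3f (sensitivity %.3f, specificity %.3f)\n",
              m$cutoff, m$sensitivity, m$specificity))
  if (!is.na(m$logrank_p))
    cat(sprintf("  KM high vs low V-D: log-rank p = %.4g\n", m$logrank_p))
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Writes per-table CSVs (summary table, Spearman matrix, both logistic
#' tables, KM curves) plus a JSON metrics file (AUCs, cutoff,
#' sensitivity, specificity, log-rank p) into a report directory.
#'
#' @param report a `vd_analysis_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "vd_analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$summary_table,
                   file.path(dir, "summary_table.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$spearman),
                   file.path(dir, "spearman.csv"))
  utils::write.csv(report$logistic_univariate,
                   file.path(dir, "logistic_univariate.csv"),
                   row.names = FALSE)
  utils::write.csv(report$logistic_multivariate,
                   file.path(dir, "logistic_multivariate.csv"),
                   row.names = FALSE)
  if (!is.null(report$km))
    utils::write.csv(report$km$curves, file.path(dir, "km_curves.csv"),
                     row.names = FALSE)
  roc_points <- do.call(rbind, lapply(names(report$roc), function(nm) {
    r <- report$roc[[nm]]
    data.frame(score = nm, threshold = r$thresholds,
               sensitivity = r$sensitivity, specificity = r$specificity)
  }))
  utils::write.csv(roc_points, file.path(dir, "roc_points.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
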