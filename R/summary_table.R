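#' Baseline-style group summary table
#'
#' Summarizes each variable by a binary grouping and tests for a
#' between-group difference the way clinical baseline tables are built:
#' continuous variables are screened for normality per group
#' (Shapiro-Wilk at `normality_alpha`); if both groups pass they are
#' summarized as mean (SD) and compared with Student's t-test, otherwise
#' as median \[IQR\] with the Wilcoxon rank-sum test (normal approximation
#' with tie correction).  Categorical variables are summarized as n (%)
#' and compared with a chi-square test without continuity correction; a
#' note flags tables with any expected count below 5.  Constant variables
#' are skipped with a note instead of failing the whole table.
#'
#' @param data data frame.
#' @param group_var name of a binary grouping column.
#' @param variables character vector of columns to summarize; numeric
#'   columns are treated as continuous, everything else as categorical.
#' @param normality_alpha significance level of the Shapiro-Wilk gate.
#' @return Data frame of class `summary_table` with one row per
#'   variable (categorical variables additionally get one row per level):
#'   columns `variable`, `level`, the two group summaries, `test`, `p`,
#'   `note`.
#' @export
summarize_cohort <- function(data, group_var, variables,
                             normality_alpha = 0.05) {
  g <- data[[group_var]]
  if (is.null(g)) stop("group variable not found: ", group_var)
  g <- as.factor(g)
  if (nlevels(g) != 2) stop("group variable must be binary")
  if (any(table(g) < 2)) stop("need at least 2 records per group")
  lv <- levels(g)
  rows <- list()
  for (v in variables) {
    x <- data[[v]]
    if (is.null(x)) stop("variable not found: ", v)
    if (is.numeric(x)) {
      x1 <- x[g == lv[1] & !is.na(x)]
      x2 <- x[g == lv[2] & !is.na(x)]
      if (length(unique(c(x1, x2))) < 2) {
        rows[[v]] <- data.frame(variable = v, level = NA,
                                g1 = format_cont(x1, FALSE),
                                g2 = format_cont(x2, FALSE),
                                test = NA, p = NA_real_,
                                note = "constant variable; test skipped")
        next
      }
      normal <- length(x1) >= 3 && length(x2) >= 3 &&
        length(x1) <= 5000 && length(x2) <= 5000 &&
        stats::sd(x1) > 0 && stats::sd(x2) > 0 &&
        stats::shapiro.test(x1)$p.value > normality_alpha &&
        stats::shapiro.test(x2)$p.value > normality_alpha
      if (normal) {
        p <- stats::t.test(x1, x2, var.equal = TRUE)$p.value
        test <- "t-test"
      } else {
        p <- suppressWarnings(
          stats::wilcox.test(x1, x2, exact = FALSE, correct = TRUE)$p.value)
        test <- "wilcoxon"
      }
      rows[[v]] <- data.frame(variable = v, level = NA,
                              g1 = format_cont(x1, normal),
                              g2 = format_cont(x2, normal),
                              test = test, p = p, note = NA)
    } else {
      x <- as.factor(x)
      tab <- table(x, g)
      if (nrow(tab) < 2) {
        rows[[v]] <- data.frame(variable = v, level = NA, g1 = NA, g2 = NA,
                                test = NA, p = NA_real_,
                                note = "constant variable; test skipped")
        next
      }
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      note <- if (any(ct$expected < 5))
        "chi-square with expected count < 5" else NA
      lev_rows <- lapply(rownames(tab), function(l) {
        data.frame(variable = v, level = l,
                   g1 = sprintf("%d (%.1f%%)", tab[l, 1],
                                100 * tab[l, 1] / sum(tab[, 1])),
                   g2 = sprintf("%d (%.1f%%)", tab[l, 2],
                                100 * tab[l, 2] / sum(tab[, 2])),
                   test = NA, p = NA_real_, note = NA)
      })
      head_row <- data.frame(variable = v, level = NA, g1 = NA, g2 = NA,
                             test = "chi-square", p = ct$p.value, note = note)
      rows[[v]] <- do.call(rbind, c(list(head_row), lev_rows))
    }
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "g1"] <- lv[1]
  names(out)[names(out) == "g2"] <- lv[2]
  rownames(out) <- NULL
  attr(out, "group_sizes") <- table(g)
  class(out) <- c("summary_table", "data.frame")
  out
}

format_cont <- function(x, normal) {
  if (length(x) == 0) return(NA_character_)
  if (normal) sprintf("%.2f (%.2f)", mean(x), stats::sd(x))
  else {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    sprintf("%.2f [%.2f, %.2f]", q[2], q[1], q[3])
  }
}

#' Spearman correlation matrix
#'
#' Rank-based (midrank-tied) Spearman correlation between all pairs of
#' the given variables, with pairwise-complete observations.  Pairs with
#' fewer than 3 complete records or a constant (all-tied) member are
#' reported as `NA`; the diagonal is exactly 1.
#'
#' @param data data frame.
#' @param variables character vector of numeric columns.
#' @return Symmetric correlation matrix.
#' @export
spearman_matrix <- function(data, variables) {
  x <- data[variables]
  if (!all(vapply(x, is.numeric, logical(1))))
    stop("all variables must be numeric")
  m <- diag(1, length(variables))
  dimnames(m) <- list(variables, variables)
  for (i in seq_along(variables)) for (j in seq_len(i - 1)) {
    ok <- stats::complete.cases(x[[i]], x[[j]])
    if (sum(ok) < 3 || stats::sd(x[[i]][ok]) == 0 ||
        stats::sd(x[[j]][ok]) == 0) {
      m[i, j] <- m[j, i] <- NA_real_
    } else {
      m[i, j] <- m[j, i] <- stats::cor(x[[i]][ok], x[[j]][ok],
                                       method = "spearman")
    }
  }
  m
}
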