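#' Cohort table column dictionary
#'
#' The exchange schema between the imaging stage and the statistical
#' stage: one row per patient.  Units are mm, mm^3 and months throughout.
#'
#' @return Data frame documenting each column: name, type, constraint.
#' @export
cohort_column_dictionary <- function() {
  data.frame(
    column = c("id", "sex", "age", "knosp", "hardy", "v1", "v2", "d1",
               "d2", "ki67", "prl", "testosterone", "lh", "fsh",
               "recurrent", "time_months"),
    type = c("character", "M/F", "numeric", "integer", "integer/roman",
             "numeric", "numeric", "numeric", "numeric", "numeric",
             "numeric", "numeric", "numeric", "numeric", "0/1",
             "numeric"),
    constraint = c("unique", "M or F", ">= 0", "0-4 (cavernous invasion)",
                   "I-V (sellar destruction)", ">= 0 (mm^3)", "> 0 (mm^3)",
                   ">= 0 (mm)", "> 0 (mm)", ">= 0 (% positive nuclei)",
                   ">= 0 (ng/ml); may be missing",
                   ">= 0 (ng/ml); may be missing",
                   ">= 0 (ng/ml); may be missing",
                   ">= 0 (ng/ml); may be missing",
                   "1 = recurrence observed",
                   ">= 0 (months to event/censoring)"),
    stringsAsFactors = FALSE)
}

roman_to_int <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  m <- match(toupper(trimws(x)), c("I", "II", "III", "IV", "V"))
  ifelse(is.na(m), suppressWarnings(as.integer(x)), m)
}

#' Schema violations of a cohort table
#'
#' Checks a cohort data frame against the column dictionary and returns
#' every violation at once (row-numbered), rather than stopping at the
#' first.
#'
#' @param df data frame in the [cohort_column_dictionary()] layout.
#' @return Character vector of violation messages; empty when valid.
#' @export
cohort_schema_errors <- function(df) {
  errs <- character(0)
  req <- cohort_column_dictionary()$column
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    return(paste("missing column:", missing_cols))
  bad_rows <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx))
      sprintf("%s (row %s)", msg, paste(idx, collapse = ", "))
    else character(0)
  }
  hardy <- roman_to_int(df$hardy)
  errs <- c(
    errs,
    bad_rows(!df$sex %in% c("M", "F"), "sex must be M or F"),
    bad_rows(!is.na(df$age) & df$age < 0, "age must be >= 0"),
    bad_rows(is.na(df$knosp) | !df$knosp %in% 0:4,
             "knosp must be in 0-4"),
    bad_rows(is.na(hardy) | !hardy %in% 1:5,
             "hardy must be in I-V (1-5)"),
    bad_rows(is.na(df$v1) | df$v1 < 0, "v1 must be >= 0"),
    bad_rows(is.na(df$v2) | df$v2 <= 0, "v2 must be > 0"),
    bad_rows(is.na(df$d1) | df$d1 < 0, "d1 must be >= 0"),
    bad_rows(is.na(df$d2) | df$d2 <= 0, "d2 must be > 0"),
    bad_rows(!is.na(df$ki67) & df$ki67 < 0, "ki67 must be >= 0"),
    bad_rows(!df$recurrent %in% c(0, 1, TRUE, FALSE),
             "recurrent must be 0/1"),
    bad_rows(is.na(df$time_months) | df$time_months < 0,
             "time_months must be >= 0"))
  if (anyDuplicated(df$id))
    errs <- c(errs, "id values must be unique")
  errs
}

#' Read and validate a cohort CSV
#'
#' Loads a per-patient cohort table and enforces the column dictionary,
#' reporting all schema violations together.  Missing hormone values may
#' be left as empty fields.  Hardy grades may be Roman (I-V) or integer
#' (1-5) and are normalized to integers.
#'
#' @param path CSV file path.
#' @return Validated cohort data frame (with `hardy` as integer and
#'   `recurrent` as integer 0/1).
#' @export
validate_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("cohort file is empty: ", path)
  validate_cohort(df)
}

#' Validate an in-memory cohort table
#'
#' @param df cohort data frame.
#' @return The validated (normalized) data frame; stops with the full
#'   list of violations otherwise.
#' @export
validate_cohort <- function(df) {
  errs <- cohort_schema_errors(df)
  if (length(errs))
    stop("cohort schema violations:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  df$hardy <- roman_to_int(df$hardy)
  df$recurrent <- as.integer(df$recurrent)
  df
}

#' Write a cohort table to CSV
#'
#' @param cohort cohort data frame.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
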