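`%||%` <- function(x, y) if (is.null(x)) y else x

#' Names of the baseline covariates carried on the patient table
#'
#' The twelve binary indicators used throughout the balance diagnostics:
#' BMI over 25, hospitalisation in the prior year, more than 13 primary-care
#' consultations in the prior year, age over 40 at first prescription, more
#' than five prescriptions of any type in the prior year, male sex, ever
#' smoked, a depression diagnosis before the index prescription, a prior
#' self-harm diagnosis, prior hypnotic and antipsychotic prescriptions, and
#' a nonzero Charlson comorbidity index.
#'
#' @return Character vector of column names.
#' @export
covariate_names <- function() {
  c("bmi_over_25", "hospitalized_prior_year", "consult_over_13",
    "age_over_40", "rx_over_5_prior_year", "male", "ever_smoked",
    "prior_depression", "prior_self_harm", "prior_hypnotic",
    "prior_antipsychotic", "charlson_positive")
}

#' Indicator matrix for calendar year of the index prescription
#'
#' Builds year dummies (reference level dropped) for use as regression
#' controls. All estimators and balance models in this package adjust for
#' index year this way rather than with a linear trend, because prescribing
#' shares shift nonlinearly over a study window.
#'
#' @param years Integer vector of calendar years.
#' @return Numeric matrix with one column per non-reference year, or `NULL`
#'   when only one distinct year is present.
#' @export
year_dummies <- function(years) {
  lv <- sort(unique(years))
  if (length(lv) < 2) return(NULL)
  out <- vapply(lv[-1], function(y) as.numeric(years == y), numeric(length(years)))
  colnames(out) <- paste0("year_", lv[-1])
  out
}

# Coerce a controls argument (NULL, matrix, or data frame) to a numeric
# matrix or NULL.
as_controls <- function(controls) {
  if (is.null(controls)) return(NULL)
  m <- as.matrix(controls)
  storage.mode(m) <- "double"
  if (ncol(m) == 0) return(NULL)
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
  m
}

# Drop control columns left constant after row subsetting (e.g. a year
# dummy with no rows once missing-BMI patients are removed).
drop_constant_cols <- function(W) {
  if (is.null(W)) return(NULL)
  keep <- apply(W, 2, function(col) length(unique(col)) > 1)
  if (!any(keep)) return(NULL)
  W[, keep, drop = FALSE]
}

# Remove control columns that are linearly dependent on the rest of the
# design (after row subsetting a year dummy can alias the intercept, e.g.
# when every row of the reference year carried a missing covariate).
prune_aliased_controls <- function(W, base) {
  if (is.null(W)) return(NULL)
  qx <- qr(cbind(base, W))
  nb <- ncol(base)
  if (qx$rank == nb + ncol(W)) return(W)
  keep_idx <- qx$pivot[seq_len(qx$rank)]
  keep <- sort(keep_idx[keep_idx > nb] - nb)
  if (!length(keep)) return(NULL)
  W[, keep, drop = FALSE]
}

assert_binary <- function(x, name) {
  v <- x[!is.na(x)]
  if (!all(v %in% c(0, 1))) {
    stop(sprintf("`%s` must be binary (0/1)", name), call. = FALSE)
  }
  invisible(x)
}
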