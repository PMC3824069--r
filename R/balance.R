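# Covariate-balance diagnostics by exposure and by instrument: adjusted
# risk differences per 100, Mahalanobis imbalance with percent reduction,
# prevalence difference ratios and the relative-bias rule, and joint
# F-tests for multi-instrument specifications.

#' Adjusted risk difference of a covariate across a binary grouping
#'
#' Least-squares coefficient of the group indicator from
#' `covariate ~ group + controls`, scaled per 100, with a
#' physician-clustered confidence interval. With no controls this reduces
#' to the plain prevalence difference between groups. Rows with a missing
#' covariate (e.g. BMI) are dropped and counted.
#'
#' @param data Cohort table.
#' @param covariate Name of a binary covariate column.
#' @param group_col Name of the binary grouping column (exposure `"X"` or
#'   instrument `"Z1"`).
#' @param controls Optional control matrix (year dummies by convention);
#'   `NULL` for crude differences.
#' @param cluster_col Name of the cluster column (default
#'   `"physician_id"`).
#' @return One-row tibble: covariate, rd_per_100, se, ci_low, ci_high, n,
#'   n_clusters, n_missing.
#' @export
adjusted_risk_difference <- function(data, covariate, group_col = "X",
                                     controls = NULL,
                                     cluster_col = "physician_id") {
  yv <- data[[covariate]]
  keep <- !is.na(yv)
  yv <- as.numeric(yv[keep])
  g <- data[[group_col]][keep]
  assert_binary(g, group_col)
  if (length(unique(yv)) < 2) {
    stop(sprintf("covariate `%s` is constant", covariate))
  }
  W <- as_controls(controls)
  if (!is.null(W)) {
    W <- drop_constant_cols(W[keep, , drop = FALSE])
    W <- prune_aliased_controls(W, cbind(1, as.numeric(g)))
  }
  res <- ols_cluster(yv, as.numeric(g), W, data[[cluster_col]][keep],
                     name = covariate)
  tibble::tibble(covariate = covariate, rd_per_100 = res$rd_per_100,
                 se = res$se, ci_low = res$ci_low, ci_high = res$ci_high,
                 n = res$n, n_clusters = res$n_clusters,
                 n_missing = sum(!keep))
}

#' Mahalanobis distance between group covariate means
#'
#' Summary of total covariate imbalance: the difference of covariate mean
#' vectors between the two groups, standardised by the pooled within-group
#' covariance, scaled by 100 for display. Affine-invariant by
#' construction.
#'
#' @param data Cohort table.
#' @param covariates Character vector of covariate columns (complete cases
#'   used).
#' @param group_col Binary grouping column.
#' @return Scalar distance (x 100).
#' @export
mahalanobis_imbalance <- function(data, covariates, group_col = "X") {
  if (length(covariates) < 2) stop("need at least 2 covariates")
  M <- as.matrix(data[, covariates])
  storage.mode(M) <- "double"
  g <- data[[group_col]]
  keep <- stats::complete.cases(M) & !is.na(g)
  M <- M[keep, , drop = FALSE]; g <- g[keep]
  m1 <- colMeans(M[g == 1, , drop = FALSE])
  m0 <- colMeans(M[g == 0, , drop = FALSE])
  n1 <- sum(g == 1); n0 <- sum(g == 0)
  S <- ((n1 - 1) * stats::cov(M[g == 1, , drop = FALSE]) +
          (n0 - 1) * stats::cov(M[g == 0, , drop = FALSE])) / (n1 + n0 - 2)
  delta <- m1 - m0
  qd <- tryCatch(solve(S, delta), error = function(e) NULL)
  if (is.null(qd)) {
    cc <- stats::cov2cor(S); diag(cc) <- 0
    ij <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
    stop(sprintf("singular pooled covariance (collinear pair: %s, %s)",
                 covariates[ij[1]], covariates[ij[2]]), call. = FALSE)
  }
  100 * sqrt(sum(delta * qd))
}

#' Percent reduction in Mahalanobis imbalance
#'
#' How much less imbalanced the instrument contrast is than the exposure
#' contrast: `100 * (1 - d_instrument / d_exposure)`. Negative when the
#' instrument is the more imbalanced of the two; display convention is to
#' round to the nearest integer percent.
#'
#' @param d_exposure,d_instrument Mahalanobis distances by exposure and by
#'   instrument.
#' @return Unrounded percentage.
#' @export
imbalance_reduction <- function(d_exposure, d_instrument) {
  if (d_exposure <= 0) stop("d_exposure must be positive")
  100 * (1 - d_instrument / d_exposure)
}

#' Prevalence difference ratio and the relative-bias flag
#'
#' Ratio of a covariate's imbalance across instrument levels to its
#' imbalance across exposure levels. When its magnitude exceeds the
#' first-stage strength E(X|Z=1) - E(X|Z=0), bias from that covariate may
#' be larger in the IV analysis than in the conventional one. Ratios with
#' a near-zero exposure difference (|rd| below `unstable_below` per 100)
#' are reported as unstable rather than as a number, since the ratio is
#' then dominated by noise.
#'
#' @param rd_instrument,rd_exposure Risk differences per 100 of the
#'   covariate by instrument and by exposure.
#' @param first_stage_strength First-stage risk difference on the
#'   probability scale, in (0, 1].
#' @param unstable_below Stability threshold on `|rd_exposure|` (per 100).
#' @return Tibble: `pdr` (dimensionless), `flag` (|pdr| exceeds strength),
#'   `unstable`.
#' @export
prevalence_difference_ratio <- function(rd_instrument, rd_exposure,
                                        first_stage_strength,
                                        unstable_below = 0.1) {
  stopifnot(first_stage_strength > 0, first_stage_strength <= 1)
  if (abs(rd_exposure) < unstable_below) {
    return(tibble::tibble(pdr = NA_real_, flag = NA, unstable = TRUE))
  }
  pdr <- rd_instrument / rd_exposure
  tibble::tibble(pdr = pdr, flag = abs(pdr) > first_stage_strength,
                 unstable = FALSE)
}

#' Joint test of instrument-covariate association
#'
#' Regresses a covariate on the full instrument set plus controls and
#' reports the cluster-robust Wald test that every instrument coefficient
#' is zero, on the F scale.
#'
#' @param data Cohort table.
#' @param covariate Covariate column name.
#' @param instrument_cols Character vector of instrument columns.
#' @param controls Optional control matrix.
#' @param cluster_col Cluster column name.
#' @return List `f`, `df1`, `df2`, `p`, `n`, `n_clusters`.
#' @export
joint_covariate_association <- function(data, covariate, instrument_cols,
                                        controls = NULL,
                                        cluster_col = "physician_id") {
  yv <- data[[covariate]]
  keep <- !is.na(yv)
  Z <- as.matrix(data[keep, instrument_cols])
  storage.mode(Z) <- "double"
  W <- as_controls(controls)
  if (!is.null(W)) {
    W <- drop_constant_cols(W[keep, , drop = FALSE])
    W <- prune_aliased_controls(W, cbind(1, Z))
  }
  X <- cbind(Z, `(Intercept)` = rep(1, sum(keep)), W)
  fit <- tryCatch(fit_cluster_lm(X, as.numeric(yv[keep]),
                                 data[[cluster_col]][keep]),
                  error = function(e) stop("collinear instrument set: ",
                                           conditionMessage(e), call. = FALSE))
  wt <- wald_block_f(fit, instrument_cols)
  c(wt, list(n = fit$n, n_clusters = fit$n_clusters))
}

#' Full balance table by exposure and by instrument
#'
#' For each covariate: year-adjusted (or crude) risk differences per 100
#' by exposure and by instrument, the prevalence difference ratio with its
#' relative-bias flag, plus a Mahalanobis imbalance summary for the two
#' contrasts and the percent reduction.
#'
#' @param cohort Cohort with exposure, instrument and covariate columns.
#' @param covariates Covariate column names (default [covariate_names()]).
#' @param exposure_col,instrument_col Column names for exposure and the
#'   single binary instrument.
#' @param adjust_year Use index-year dummies as controls (the
#'   prevalence-difference ratios inherit whichever choice is made here).
#' @return List with `rows` (one tibble row per covariate) and `summary`
#'   (d_exposure, d_instrument, reduction_pct).
#' @export
balance_table <- function(cohort, covariates = covariate_names(),
                          exposure_col = "X", instrument_col = "Z1",
                          adjust_year = TRUE) {
  W <- if (adjust_year) year_dummies(cohort$index_year) else NULL
  strength <- first_stage_diagnostics(
    cohort[[exposure_col]],
    matrix(cohort[[instrument_col]], dimnames = list(NULL, instrument_col)),
    W, cohort$physician_id)$first_stage_rd / 100
  na_row <- function(cv) {
    tibble::tibble(covariate = cv, rd_exposure = NA_real_,
                   rd_exposure_lo = NA_real_, rd_exposure_hi = NA_real_,
                   rd_instrument = NA_real_, rd_instrument_lo = NA_real_,
                   rd_instrument_hi = NA_real_, pdr = NA_real_,
                   pdr_flag = NA, pdr_unstable = NA)
  }
  rows <- lapply(covariates, function(cv) {
    v <- cohort[[cv]]
    if (length(unique(v[!is.na(v)])) < 2) return(na_row(cv))
    be <- adjusted_risk_difference(cohort, cv, exposure_col, W)
    bi <- adjusted_risk_difference(cohort, cv, instrument_col, W)
    pd <- prevalence_difference_ratio(bi$rd_per_100, be$rd_per_100,
                                      abs(strength))
    tibble::tibble(covariate = cv,
                   rd_exposure = be$rd_per_100,
                   rd_exposure_lo = be$ci_low, rd_exposure_hi = be$ci_high,
                   rd_instrument = bi$rd_per_100,
                   rd_instrument_lo = bi$ci_low,
                   rd_instrument_hi = bi$ci_high,
                   pdr = pd$pdr, pdr_flag = pd$flag,
                   pdr_unstable = pd$unstable)
  })
  usable <- covariates[vapply(covariates, function(cv) {
    v <- cohort[[cv]]
    length(unique(v[!is.na(v)])) >= 2
  }, logical(1))]
  d_exp <- mahalanobis_imbalance(cohort, usable, exposure_col)
  d_ins <- mahalanobis_imbalance(cohort, usable, instrument_col)
  list(rows = bind_rows(rows),
       summary = tibble::tibble(
         d_exposure = d_exp, d_instrument = d_ins,
         reduction_pct = imbalance_reduction(d_exp, d_ins),
         first_stage_strength = abs(strength)))
}
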