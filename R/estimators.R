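# Effect estimators and specification tests. All effects are reported as
# risk differences per 100 patients with physician-clustered sandwich
# variances (finite-sample factor G/(G-1)*(N-1)/(N-k)) and t(G-1)
# confidence intervals.

#' Cluster-robust least-squares risk difference
#'
#' Linear-probability regression of a binary outcome on a binary group
#' indicator plus controls, with standard errors clustered on `cluster`
#' (the prescribing physician, throughout this package).
#'
#' @param y Outcome vector.
#' @param x Group / exposure indicator.
#' @param controls Optional matrix or data frame of controls (typically
#'   [year_dummies()] of the index year).
#' @param cluster Cluster identifiers.
#' @param name Estimator label for the result row.
#' @return One-row tibble: `estimator`, `rd_per_100`, `se`, `ci_low`,
#'   `ci_high`, `n`, `n_clusters`.
#' @export
ols_cluster <- function(y, x, controls = NULL, cluster, name = "ols") {
  W <- as_controls(controls)
  X <- cbind(`(Intercept)` = rep(1, length(y)), x = x, W)
  fit <- fit_cluster_lm(X, y, cluster)
  estimate_result(name, fit$beta[["x"]], sqrt(fit$vcov["x", "x"]),
                  fit$n, fit$n_clusters)
}

#' Two-stage least squares with cluster-robust variance
#'
#' IV regression of `y` on a single endogenous exposure `x`, using the
#' supplied excluded instruments; the variance is computed from the
#' structural residuals `y - x b - W g`, not the second-stage plug-in
#' residuals. A first-stage partial F below 10 triggers a weak-instrument
#' warning but not a failure.
#'
#' @inheritParams ols_cluster
#' @param instruments Matrix or data frame of excluded instruments.
#' @param diagnostics Compute first-stage diagnostics (disable in tight
#'   simulation loops where only the coefficient and variance are needed).
#' @return List with `estimate` (result tibble as in [ols_cluster()]) and
#'   `first_stage` ([first_stage_diagnostics()] output, `NULL` when
#'   `diagnostics = FALSE`).
#' @export
tsls <- function(y, x, instruments, controls = NULL, cluster, name = "tsls",
                 diagnostics = TRUE) {
  Z <- as.matrix(instruments)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("Z", seq_len(ncol(Z)))
  fs <- NULL
  if (diagnostics) {
    fs <- first_stage_diagnostics(x, Z, controls, cluster)
    if (fs$partial_f < 10) {
      warning(sprintf("weak first stage: partial F = %.2f < 10", fs$partial_f))
    }
  }
  fit <- tsls_fit(y, x, Z, as_controls(controls), cluster)
  list(estimate = estimate_result(name, fit$beta[["x"]],
                                  sqrt(fit$vcov["x", "x"]),
                                  fit$n, fit$n_clusters),
       first_stage = fs)
}

#' Wald ratio for a single binary instrument
#'
#' Just-identified IV estimate from conditional means: the reduced-form
#' outcome difference across instrument levels divided by the first-stage
#' exposure difference, scaled per 100. Serves as the closed-form oracle
#' for [tsls()] with one binary instrument and no controls.
#'
#' @param y,x Outcome and exposure vectors.
#' @param z Binary instrument.
#' @return Risk difference per 100 (scalar).
#' @export
wald_ratio <- function(y, x, z) {
  assert_binary(z, "z")
  denom <- mean(x[z == 1]) - mean(x[z == 0])
  if (denom == 0) stop("zero first-stage difference; Wald ratio undefined")
  100 * (mean(y[z == 1]) - mean(y[z == 0])) / denom
}

#' First-stage strength diagnostics
#'
#' Regresses the actual prescription on the instrument block plus controls
#' and reports the instrument coefficient (per 100, for a single
#' instrument), the cluster-robust partial F of the block, and the partial
#' r-squared of exposure and instruments given the controls.
#'
#' @inheritParams tsls
#' @return Tibble-like list: `first_stage_rd` (NA for multi-column
#'   instruments), `partial_f`, `df1`, `df2`, `p`, `partial_r2`, `n`,
#'   `n_clusters`.
#' @export
first_stage_diagnostics <- function(x, instruments, controls = NULL, cluster) {
  Z <- as.matrix(instruments)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("Z", seq_len(ncol(Z)))
  W <- as_controls(controls)
  X <- cbind(Z, `(Intercept)` = rep(1, length(x)), W)
  fit <- fit_cluster_lm(X, x, cluster)
  wt <- wald_block_f(fit, colnames(Z))
  # partial r2: squared correlation of x and the instruments after both are
  # residualised on the controls
  base <- cbind(rep(1, length(x)), W)
  xr <- x - ls_fitted(base, x)
  Zr <- apply(Z, 2, function(col) col - ls_fitted(base, col))
  fitr <- ls_fitted(as.matrix(Zr), xr)
  pr2 <- if (sum(xr^2) == 0) 0 else 1 - sum((xr - fitr)^2) / sum(xr^2)
  list(first_stage_rd = if (ncol(Z) == 1) 100 * fit$beta[[colnames(Z)]] else NA_real_,
       first_stage_se = if (ncol(Z) == 1)
         100 * sqrt(fit$vcov[colnames(Z), colnames(Z)]) else NA_real_,
       partial_f = wt$f, df1 = wt$df1, df2 = wt$df2, p = wt$p,
       partial_r2 = pr2, n = fit$n, n_clusters = fit$n_clusters)
}

#' Lagrange multiplier test for added instruments
#'
#' Tests whether instruments beyond a base set explain additional exposure
#' variance: the base first-stage residuals are regressed on the added
#' instruments plus controls, and N times the R-squared is referred to a
#' chi-squared distribution with one degree of freedom per added
#' instrument.
#'
#' @param x Exposure vector.
#' @param base,added Matrices/data frames of base and added instruments;
#'   column names must not overlap.
#' @param controls Optional controls included in both regressions.
#' @return List `statistic`, `df`, `p`.
#' @export
lm_added_instruments <- function(x, base, added, controls = NULL) {
  Zb <- as.matrix(base); Za <- as.matrix(added)
  if (is.null(colnames(Zb))) colnames(Zb) <- paste0("Zb", seq_len(ncol(Zb)))
  if (is.null(colnames(Za))) colnames(Za) <- paste0("Za", seq_len(ncol(Za)))
  if (length(intersect(colnames(Zb), colnames(Za)))) {
    stop("base and added instrument sets overlap")
  }
  W <- as_controls(controls)
  ones <- rep(1, length(x))
  u <- x - ls_fitted(cbind(ones, W, Zb), x)
  fit <- ls_fitted(cbind(ones, W, Za), u)
  tss <- sum((u - mean(u))^2)
  r2 <- if (tss == 0) 0 else 1 - sum((u - fit)^2) / tss
  stat <- length(x) * r2
  df <- ncol(Za)
  list(statistic = stat, df = df,
       p = pchisq(stat, df, lower.tail = FALSE))
}

#' Durbin-Wu-Hausman endogeneity test (control-function form)
#'
#' Appends the first-stage residual to the outcome regression and tests its
#' coefficient with a cluster-robust Wald test; under the null the OLS and
#' IV estimands coincide (no exposure endogeneity). The control-function
#' form is used because the classical variance-difference statistic need
#' not be positive under clustering.
#'
#' @inheritParams tsls
#' @return List `statistic` (chi-squared, 1 df), `df`, `p`.
#' @export
hausman_dwh <- function(y, x, instruments, controls = NULL, cluster) {
  Z <- as.matrix(instruments)
  W <- as_controls(controls)
  ones <- rep(1, length(x))
  v <- x - ls_fitted(cbind(ones, W, Z), x)
  if (sd(v) < 1e-10) {
    stop("exposure is an exact function of instruments and controls; ",
         "control-function test degenerate")
  }
  X <- cbind(`(Intercept)` = ones, x = x, v = v, W)
  fit <- fit_cluster_lm(X, y, cluster)
  t2 <- fit$beta[["v"]]^2 / fit$vcov["v", "v"]
  list(statistic = t2, df = 1L, p = pchisq(t2, 1, lower.tail = FALSE))
}

#' Physician fixed-effects two-stage least squares
#'
#' Probes the exclusion restriction by absorbing an indicator for every
#' physician: outcome, exposure, instruments and controls are demeaned
#' within physician before the IV fit, so identification uses only
#' within-physician variation in the instrument (e.g. a physician whose
#' prior prescription changes over time). Errors when no instrument varies
#' within any physician.
#'
#' @inheritParams tsls
#' @param physician Physician identifiers (absorbed and used as clusters).
#' @return Result tibble as in [ols_cluster()].
#' @export
fe_tsls <- function(y, x, instruments, controls = NULL, physician,
                    name = "fe_tsls") {
  Z <- as.matrix(instruments)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("Z", seq_len(ncol(Z)))
  W <- as_controls(controls)
  f <- as.factor(as.character(physician))
  demean <- function(m) {
    m <- as.matrix(m)
    m - apply(m, 2, function(col) stats::ave(col, f))
  }
  Zd <- demean(Z)
  if (max(abs(Zd)) < 1e-12) {
    stop("no within-physician variation in the instruments; ",
         "fixed-effects IV not identified")
  }
  Wd <- NULL
  if (!is.null(W)) {
    Wd <- demean(W)
    keep <- apply(Wd, 2, function(col) max(abs(col)) > 1e-10)
    Wd <- if (any(keep)) Wd[, keep, drop = FALSE] else NULL
  }
  yd <- as.numeric(demean(y))
  xd <- as.numeric(demean(x))
  fit <- tsls_fit(yd, xd, Zd, Wd, cluster = f, add_intercept = FALSE,
                  df_absorbed = nlevels(f))
  estimate_result(name, fit$beta[["x"]], sqrt(fit$vcov["x", "x"]),
                  fit$n, fit$n_clusters)
}

#' Propensity-score matched risk difference
#'
#' Logistic propensity model for the exposure on the supplied covariates;
#' each exposed patient is matched, with replacement, to the nearest
#' control within `caliper` on the propensity score (equidistant ties go to
#' the lower control index). The estimand is the effect among the exposed.
#' The variance treats reused controls via frequency weights in a weighted
#' sandwich.
#'
#' @param y,x Outcome and exposure.
#' @param covariates Data frame of matching covariates; must be complete
#'   (BMI is conventionally excluded for this reason).
#' @param caliper Maximum propensity-score distance for a match.
#' @param with_replacement Controls may be reused (the only supported
#'   mode).
#' @return Result tibble as in [ols_cluster()] (`n_clusters` is `NA`: no
#'   clustering is applied to the matched sample), with attribute
#'   `n_unmatched` counting exposed patients without a within-caliper
#'   match.
#' @export
ps_match_rd <- function(y, x, covariates, caliper = 0.01,
                        with_replacement = TRUE) {
  if (!with_replacement) stop("only matching with replacement is supported")
  covariates <- as.data.frame(covariates)
  if (anyNA(covariates) || anyNA(y) || anyNA(x)) {
    stop("matching inputs must be complete; exclude covariates with ",
         "missing values (e.g. BMI)")
  }
  ps <- stats::fitted(glm(x ~ ., data = covariates, family = binomial()))
  ti <- which(x == 1); ci <- which(x == 0)
  if (!length(ti) || !length(ci)) stop("both exposure groups required")
  co <- ci[order(ps[ci], ci)]
  cp <- ps[co]
  pt <- ps[ti]
  pos <- findInterval(pt, cp)
  lo <- pmax(pos, 1); hi <- pmin(pos + 1, length(co))
  dlo <- abs(pt - cp[lo]); dhi <- abs(pt - cp[hi])
  pick <- ifelse(dhi < dlo, hi, lo)  # ties -> lower sorted index (lower id)
  dist <- pmin(dlo, dhi)
  ok <- dist <= caliper + 1e-12
  if (!any(ok)) stop("no exposed patient has a control within the caliper")
  mt <- ti[ok]
  mc <- co[pick[ok]]
  rd <- mean(y[mt]) - mean(y[mc])
  # frequency-weighted sandwich on the matched sample
  freq <- table(mc)
  uc <- as.integer(names(freq))
  ids <- c(mt, uc)
  w <- c(rep(1, length(mt)), as.numeric(freq))
  X <- cbind(1, x[ids])
  yy <- y[ids]
  A <- solve(crossprod(X, X * w))
  e <- yy - X %*% c(mean(y[mc]), rd)
  meat <- crossprod(X * (w * as.numeric(e)))
  V <- A %*% meat %*% A
  out <- estimate_result("ps_match", rd, sqrt(V[2, 2]),
                         n = length(mt) + length(uc), n_clusters = NA_integer_,
                         df = length(mt) - 1)
  attr(out, "n_unmatched") <- sum(!ok)
  out
}
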