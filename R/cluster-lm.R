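# Linear-algebra core shared by every estimator: least squares with a
# physician-clustered sandwich variance, and two-stage least squares whose
# variance uses the structural residuals y - D %*% beta (never the
# second-stage plug-in residuals).

# Fit y on a full-rank design matrix X and return the cluster-robust
# covariance with the finite-sample factor G/(G-1) * (N-1)/(N-k), the
# convention of Stata's cluster() option. df_absorbed counts parameters
# swept out before the fit (e.g. physician means in the fixed-effects
# estimator) so k reflects them.
fit_cluster_lm <- function(X, y, cluster, df_absorbed = 0) {
  X <- as.matrix(X)
  cluster <- as.character(cluster)
  if (anyNA(X) || anyNA(y) || anyNA(cluster)) {
    stop("missing values in regression inputs", call. = FALSE)
  }
  N <- length(y)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq.int(qx$rank + 1, ncol(X))]]
    stop("rank-deficient design matrix: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  beta <- qr.coef(qx, y)
  e <- as.numeric(y - X %*% beta)
  A <- chol2inv(qr.R(qx))  # (X'X)^{-1}; valid for unpivoted qr
  dimnames(A) <- list(colnames(X), colnames(X))
  S <- rowsum(X * e, cluster)
  G <- nrow(S)
  if (G < 2) stop("need at least 2 clusters", call. = FALSE)
  k <- ncol(X) + df_absorbed
  adj <- G / (G - 1) * (N - 1) / (N - k)
  V <- adj * A %*% crossprod(S) %*% A
  list(beta = beta, vcov = V, residuals = e, n = N, n_clusters = G,
       k = k, XtX_inv = A, fitted = as.numeric(X %*% beta))
}

# Project y onto the column space of X (first-stage helper); qr.fitted
# handles rank-deficient designs (e.g. duplicated instrument columns in
# the LM test) gracefully.
ls_fitted <- function(X, y) {
  as.numeric(qr.fitted(qr(X), y))
}

# Two-stage least squares. x is the single endogenous column, Z the excluded
# instruments, W included exogenous controls (intercept prepended unless
# add_intercept = FALSE, as in the within-transformed fixed-effects fit).
tsls_fit <- function(y, x, Z, W = NULL, cluster, add_intercept = TRUE,
                     df_absorbed = 0) {
  Z <- as.matrix(Z)
  W <- as_controls(W)
  base <- if (add_intercept) cbind(`(Intercept)` = rep(1, length(y)), W) else W
  Zfull <- cbind(Z, base)
  xhat <- ls_fitted(Zfull, x)
  D <- cbind(x = x, base)
  Dhat <- cbind(x = xhat, base)
  qd <- qr(Dhat)
  if (qd$rank < ncol(Dhat)) {
    stop("rank-deficient 2SLS design (weak or collinear instruments/controls)",
         call. = FALSE)
  }
  beta <- qr.coef(qd, y)
  e <- as.numeric(y - D %*% beta)  # structural residuals
  A <- chol2inv(qr.R(qd))
  dimnames(A) <- list(colnames(Dhat), colnames(Dhat))
  S <- rowsum(Dhat * e, as.character(cluster))
  G <- nrow(S)
  if (G < 2) stop("need at least 2 clusters", call. = FALSE)
  N <- length(y)
  k <- ncol(Dhat) + df_absorbed
  adj <- G / (G - 1) * (N - 1) / (N - k)
  V <- adj * A %*% crossprod(S) %*% A
  list(beta = beta, vcov = V, residuals = e, n = N, n_clusters = G, k = k,
       first_stage_fitted = xhat)
}

# Cluster-robust Wald test that a named block of coefficients is jointly
# zero, reported on the F scale with q numerator and G-1 denominator df.
wald_block_f <- function(fit, block) {
  b <- fit$beta[block]
  V <- fit$vcov[block, block, drop = FALSE]
  q <- length(block)
  stat <- as.numeric(crossprod(b, solve(V, b))) / q
  df2 <- fit$n_clusters - 1
  list(f = stat, df1 = q, df2 = df2, p = pf(stat, q, df2, lower.tail = FALSE))
}

# Assemble the standard one-row result tibble used by every estimator.
estimate_result <- function(name, coef, se, n, n_clusters,
                            df = max(n_clusters - 1, 1)) {
  crit <- qt(0.975, df)
  lo <- 100 * (coef - crit * se)
  hi <- 100 * (coef + crit * se)
  tibble::tibble(
    estimator = name,
    rd_per_100 = 100 * coef,
    se = 100 * se,
    ci_low = lo,
    ci_high = hi,
    n = n,
    n_clusters = n_clusters
  )
}
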