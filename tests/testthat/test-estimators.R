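test_that("singleton clusters reproduce the HC1 heteroskedasticity-robust SE", {
  skip_if_not_installed("sandwich")
  set.seed(71)
  n <- 120
  x <- rbinom(n, 1, 0.5)
  y <- 0.3 + 0.1 * x + rnorm(n, 0, 0.4)
  ours <- ols_cluster(y, x, cluster = seq_len(n))
  fit <- stats::lm(y ~ x)
  se_hc1 <- sqrt(sandwich::vcovHC(fit, type = "HC1")["x", "x"])
  expect_equal(ours$se / 100, unname(se_hc1), tolerance = 1e-10)
})

test_that("a constant outcome gives a zero coefficient and zero SE", {
  y <- rep(0.5, 40)
  x <- rbinom(40, 1, 0.5)
  res <- ols_cluster(y, x, cluster = rep(1:8, 5))
  expect_equal(res$rd_per_100, 0)
  expect_equal(res$se, 0)
})

test_that("the OLS estimator recovers an unconfounded effect", {
  sc <- simulate_cohort(quick_cfg(n_physicians = 120,
                                  patients_per_physician = 40,
                                  treatment_effect = -10, seed = 73))
  ch <- sc$cohort
  res <- ols_cluster(ch$Y, ch$X, year_dummies(ch$index_year),
                     ch$physician_id)
  expect_lt(abs(res$rd_per_100 - (-10)), 2 * res$se)
})

test_that("the Wald ratio matches hand-computed conditional means", {
  z <- c(1, 1, 1, 1, 0, 0, 0, 0)
  x <- c(1, 1, 1, 0, 1, 0, 0, 0)
  expect_equal(wald_ratio(c(1, 0, 1, 0, 1, 0, 1, 0), x, z), 0)
  expect_equal(wald_ratio(c(1, 1, 0, 0, 0, 0, 1, 0), x, z), 50)
  expect_equal(wald_ratio(x, x, z), 100)
  expect_error(wald_ratio(x, rep(0.5, 8), z), "zero first-stage")
})

test_that("2SLS with the exposure as its own instrument equals OLS", {
  sc <- simulate_cohort(quick_cfg(seed = 79))
  ch <- sc$cohort
  W <- year_dummies(ch$index_year)
  iv <- tsls(ch$Y, ch$X, matrix(ch$X, dimnames = list(NULL, "Zx")), W,
             ch$physician_id, diagnostics = FALSE)
  ols <- ols_cluster(ch$Y, ch$X, W, ch$physician_id)
  expect_equal(iv$estimate$rd_per_100, ols$rd_per_100, tolerance = 1e-10)
  expect_equal(iv$estimate$se, ols$se, tolerance = 1e-10)
})

test_that("just-identified 2SLS equals the Wald ratio and indirect least squares", {
  for (s in 1:25) {
    d <- random_iv_data(s)
    iv <- suppressWarnings(
      tsls(d$y, d$x, matrix(d$z, dimnames = list(NULL, "z")),
           cluster = seq_along(d$y), diagnostics = FALSE))
    expect_equal(iv$estimate$rd_per_100, wald_ratio(d$y, d$x, d$z),
                 tolerance = 1e-10)
  }
  # with controls: 2SLS coefficient = reduced-form / first-stage
  sc <- simulate_cohort(quick_cfg(seed = 83))
  ch <- sc$cohort
  W <- year_dummies(ch$index_year)
  iv <- tsls(ch$Y, ch$X, matrix(ch$Z1, dimnames = list(NULL, "Z1")), W,
             ch$physician_id, diagnostics = FALSE)
  rf <- ols_cluster(ch$Y, ch$Z1, W, ch$physician_id)
  fs <- ols_cluster(ch$X, ch$Z1, W, ch$physician_id)
  expect_equal(iv$estimate$rd_per_100, 100 * rf$rd_per_100 / fs$rd_per_100,
               tolerance = 1e-8)
})

test_that("first-stage partial F is the squared t for one instrument and ~1 under independence", {
  sc <- simulate_cohort(quick_cfg(seed = 89))
  ch <- sc$cohort
  W <- year_dummies(ch$index_year)
  fs <- first_stage_diagnostics(ch$X,
                                matrix(ch$Z1, dimnames = list(NULL, "Z1")),
                                W, ch$physician_id)
  expect_equal(fs$partial_f, (fs$first_stage_rd / fs$first_stage_se)^2,
               tolerance = 1e-8)
  expect_true(fs$partial_r2 >= 0 && fs$partial_r2 <= 1)
  set.seed(97)
  fstats <- replicate(300, {
    n <- 500
    first_stage_diagnostics(rbinom(n, 1, 0.5),
                            matrix(rbinom(n, 1, 0.5)),
                            cluster = rep(1:25, 20))$partial_f
  })
  expect_lt(abs(mean(fstats) - 1), 3 * sd(fstats) / sqrt(300))
})

test_that("LM test: duplicated instruments add nothing, informative ones do", {
  sc <- simulate_cohort(quick_cfg(n_physicians = 80,
                                  patients_per_physician = 40,
                                  preference_sd = 1, seed = 101),
                        depths = c(1, 7))
  ch <- sc$cohort
  W <- year_dummies(ch$index_year)
  Zb <- matrix(ch$Z1, dimnames = list(NULL, "Z1"))
  copies <- matrix(rep(ch$Z1, 2), ncol = 2,
                   dimnames = list(NULL, c("c1", "c2")))
  lm0 <- lm_added_instruments(ch$X, Zb, copies, W)
  expect_lt(lm0$statistic, 1e-8)
  ind7 <- as.matrix(ch[, paste0("Z_ind7_", 2:7)])
  lm7 <- lm_added_instruments(ch$X, Zb, ind7, W)
  expect_equal(lm7$df, 6L)
  expect_gt(lm7$statistic, stats::qchisq(0.95, 6))
  expect_error(lm_added_instruments(ch$X, Zb, cbind(Z1 = ch$Z1), W),
               "overlap")
})

test_that("DWH test rejects under strong unmeasured confounding and degenerates without a first-stage residual", {
  cfg <- sim_config(n_physicians = 500, patients_per_physician = 100,
                    treatment_effect = 0, confounder_effect_y = 50,
                    confounder_effect_rx = 1.5, preference_sd = 1, seed = 103)
  sc <- simulate_cohort(cfg)
  ch <- sc$cohort
  W <- year_dummies(ch$index_year)
  dwh <- hausman_dwh(ch$Y, ch$X, matrix(ch$Z1, dimnames = list(NULL, "Z1")),
                     W, ch$physician_id)
  expect_lt(dwh$p, 0.01)
  z <- rbinom(100, 1, 0.5)
  expect_error(hausman_dwh(rnorm(100), z, matrix(z), cluster = rep(1:10, 10)),
               "degenerate")
})

test_that("physicians without instrument variation contribute nothing to the fixed-effects fit", {
  set.seed(107)
  n_per <- 40
  make_phys <- function(id, z) {
    z <- if (length(z) == 1) rep(z, n_per) else z
    x <- rbinom(n_per, 1, 0.2 + 0.6 * z)
    y <- 0.3 - 0.1 * x + rnorm(n_per, 0, 0.1)
    tibble::tibble(phys = id, z = z, x = x, y = y)
  }
  varying <- dplyr::bind_rows(lapply(1:15, function(i)
    make_phys(paste0("v", i), rbinom(n_per, 1, 0.5))))
  constant <- make_phys("c1", 1)
  full <- dplyr::bind_rows(varying, constant)
  f_full <- fe_tsls(full$y, full$x, matrix(full$z), physician = full$phys)
  f_sub <- fe_tsls(varying$y, varying$x, matrix(varying$z),
                   physician = varying$phys)
  expect_equal(f_full$rd_per_100, f_sub$rd_per_100, tolerance = 1e-10)
  expect_error(fe_tsls(constant$y, constant$x, matrix(constant$z),
                       physician = constant$phys), "variation")
})

test_that("physician fixed effects absorb a direct preference-outcome path", {
  # preference_effect_y > 0 violates the exclusion restriction for plain
  # preference-based IV; the within-physician estimator is immune
  reps <- lapply(1:8, function(s) {
    cfg <- sim_config(n_physicians = 150, patients_per_physician = 60,
                      treatment_effect = -10, preference_effect_y = 8,
                      preference_sd = 1, seed = 300 + s)
    ch <- simulate_cohort(cfg)$cohort
    W <- year_dummies(ch$index_year)
    Z <- matrix(ch$Z1, dimnames = list(NULL, "Z1"))
    c(plain = tsls(ch$Y, ch$X, Z, W, ch$physician_id,
                   diagnostics = FALSE)$estimate$rd_per_100,
      fe = fe_tsls(ch$Y, ch$X, Z, W, ch$physician_id)$rd_per_100)
  })
  m <- do.call(rbind, reps)
  bias_plain <- mean(m[, "plain"]) + 10
  bias_fe <- mean(m[, "fe"]) + 10
  expect_gt(bias_plain, 3 * sd(m[, "plain"]) / sqrt(nrow(m)))
  expect_lt(abs(bias_fe), abs(bias_plain))
})

test_that("without physician effects, fixed-effects IV agrees with plain IV", {
  cfg <- sim_config(n_physicians = 200, patients_per_physician = 50,
                    treatment_effect = -10, preference_sd = 1, seed = 109)
  ch <- simulate_cohort(cfg)$cohort
  W <- year_dummies(ch$index_year)
  Z <- matrix(ch$Z1, dimnames = list(NULL, "Z1"))
  plain <- tsls(ch$Y, ch$X, Z, W, ch$physician_id, diagnostics = FALSE)
  fe <- fe_tsls(ch$Y, ch$X, Z, W, ch$physician_id)
  expect_lt(abs(plain$estimate$rd_per_100 - fe$rd_per_100),
            2 * sqrt(plain$estimate$se^2 + fe$se^2))
})

test_that("propensity-score matching removes observed-covariate confounding", {
  set.seed(113)
  n <- 6000
  cv <- tibble::tibble(a = rbinom(n, 1, 0.4), b = rbinom(n, 1, 0.3))
  x <- rbinom(n, 1, plogis(-0.8 + 1.2 * cv$a + 0.9 * cv$b))
  y <- rbinom(n, 1, 0.2 - 0.05 * x + 0.25 * cv$a + 0.15 * cv$b)
  crude <- 100 * (mean(y[x == 1]) - mean(y[x == 0]))
  m <- ps_match_rd(y, x, cv)
  expect_lt(abs(m$rd_per_100 - (-5)), 2 * m$se)
  expect_gt(abs(crude - (-5)), 4)  # confounded by construction
  # independent covariates: matched estimate approximates the crude one
  x2 <- rbinom(n, 1, 0.5)
  m2 <- ps_match_rd(y, x2, cv)
  crude2 <- 100 * (mean(y[x2 == 1]) - mean(y[x2 == 0]))
  expect_lt(abs(m2$rd_per_100 - crude2), 3 * m2$se)
})

test_that("a zero caliper keeps only exact propensity matches", {
  set.seed(127)
  n <- 400
  cv <- tibble::tibble(a = rbinom(n, 1, 0.5))  # two distinct scores only
  x <- rbinom(n, 1, plogis(-0.3 + 0.8 * cv$a))
  y <- rbinom(n, 1, 0.3)
  m <- ps_match_rd(y, x, cv, caliper = 0)
  expect_equal(attr(m, "n_unmatched"), 0L)
  expect_true(is.finite(m$rd_per_100))
})

test_that("rare-outcome recovery: IV unbiased, OLS bias matches the omitted-variable formula", {
  reps <- lapply(1:25, function(s) {
    cfg <- sim_config(n_physicians = 150, patients_per_physician = 80,
                      baseline_risk = 0.0015, treatment_effect = -0.05,
                      confounder_effect_y = 0.3, confounder_effect_rx = 1,
                      preference_sd = 1.5, seed = 500 + s)
    sc <- simulate_cohort(cfg)
    ch <- sc$cohort
    u <- dplyr::left_join(ch, sc$truth$patient_confounders,
                          by = "patient_id")$u
    iv <- tsls(ch$Y, ch$X, matrix(ch$Z1, dimnames = list(NULL, "Z1")),
               cluster = ch$physician_id, diagnostics = FALSE)
    ols <- ols_cluster(ch$Y, ch$X, cluster = ch$physician_id)
    # analytic omitted-variable bias of OLS for the linear generator:
    # beta_u * cov(U, X) / var(X), on the per-100 scale
    c(iv = iv$estimate$rd_per_100, ols = ols$rd_per_100,
      bias_pred = 0.3 * stats::cov(u, ch$X) / stats::var(ch$X))
  })
  m <- do.call(rbind, reps)
  mc_se_iv <- sd(m[, "iv"]) / sqrt(nrow(m))
  expect_lt(abs(mean(m[, "iv"]) - (-0.05)), 2 * mc_se_iv)
  ols_dev <- m[, "ols"] - (-0.05) - m[, "bias_pred"]
  expect_lt(abs(mean(ols_dev)), 2 * sd(ols_dev) / sqrt(nrow(m)))
})
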