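#' Configuration for the synthetic prescribing-data generator
#'
#' Bundles the parameters of the physician-clustered data-generating
#' process. Physicians carry a latent log-odds preference for the
#' comparator drug class (normal with standard deviation `preference_sd`,
#' optionally drifting linearly over calendar time); patients arrive at
#' uniform dates over the calendar window; drug choice is Bernoulli on the
#' log-odds scale combining the physician's preference, observed covariate
#' effects, an unmeasured binary confounder U ~ Bernoulli(0.5), and a
#' secular trend; the rare binary outcome follows a clipped linear risk
#' model so the configured `treatment_effect` is exactly the risk-difference
#' estimand per 100 patients.
#'
#' @param n_physicians Number of physicians (grouped five per practice).
#' @param patients_per_physician Index prescriptions issued per physician.
#' @param preference_sd SD of the physician latent log-odds preference for
#'   the comparator class (TCA).
#' @param preference_drift Per-year linear shift in preference log-odds
#'   (default 0: preferences stable over the window).
#' @param covariate_prevalences Named probabilities for the twelve baseline
#'   indicators (see [covariate_names()]); defaults emulate the reference
#'   (SSRI) arm of a UK primary-care antidepressant cohort.
#' @param casemix_sd SD of a physician-level shift applied to every
#'   covariate's log-odds; controls how strongly instruments pick up case
#'   mix (0 = covariates independent of physician).
#' @param confounder_effect_rx Log-odds effect of the unmeasured confounder
#'   U on receiving the comparator drug.
#' @param covariate_effects_rx Named log-odds effects of covariates on drug
#'   choice (defaults 0).
#' @param trend_rx Per-year log-odds drift in comparator choice.
#' @param baseline_share_rx Comparator share implied by the intercept alone
#'   (preference 0, covariates 0, U = 0) at the window start.
#' @param baseline_risk Outcome probability under the reference drug with
#'   U = 0.
#' @param treatment_effect True exposure effect, risk difference per 100.
#' @param confounder_effect_y Effect of U on outcome risk, per 100.
#' @param preference_effect_y Direct effect of the physician's preference
#'   on outcome risk, per 100 per unit of preference log-odds (default 0).
#'   A nonzero value violates the exclusion restriction for plain
#'   preference-based IV -- the scenario the physician fixed-effects
#'   estimator is designed to absorb.
#' @param paroxetine_share Share of paroxetine among SSRI prescriptions at
#'   preference 0; paroxetine choice gets its own physician random
#'   intercept with SD `preference_sd_parox`.
#' @param preference_sd_parox SD of the paroxetine-within-SSRI preference.
#' @param trend_parox Per-year log-odds drift in paroxetine choice.
#' @param bmi_missing_rate Fraction of patients with missing BMI.
#' @param history_per_physician Number of warm-up prescriptions per
#'   physician issued (before the calendar window) to patients outside the
#'   patient table. These establish prescribing history so that cohort
#'   patients can satisfy the prior-prescription-count exclusion without
#'   themselves being history; they never become cohort candidates.
#' @param calendar_start,calendar_end Calendar window (ISO dates or `Date`).
#' @param seed Integer seed; identical configurations reproduce identical
#'   tables byte for byte.
#' @return A `prefiv_sim_config` list.
#' @export
sim_config <- function(n_physicians = 100,
                       patients_per_physician = 50,
                       preference_sd = 1,
                       preference_drift = 0,
                       covariate_prevalences = NULL,
                       casemix_sd = 0.2,
                       confounder_effect_rx = 0,
                       covariate_effects_rx = NULL,
                       trend_rx = 0,
                       baseline_share_rx = 0.5,
                       baseline_risk = 0.30,
                       treatment_effect = 0,
                       confounder_effect_y = 0,
                       preference_effect_y = 0,
                       paroxetine_share = 0.3,
                       preference_sd_parox = NULL,
                       trend_parox = 0,
                       bmi_missing_rate = 0.2,
                       history_per_physician = 0,
                       calendar_start = "1995-01-01",
                       calendar_end = "2010-06-30",
                       seed = 1L) {
  default_prev <- c(
    bmi_over_25 = 0.51, hospitalized_prior_year = 0.003,
    consult_over_13 = 0.59, age_over_40 = 0.51,
    rx_over_5_prior_year = 0.49, male = 0.40, ever_smoked = 0.57,
    prior_depression = 0.62, prior_self_harm = 0.058,
    prior_hypnotic = 0.13, prior_antipsychotic = 0.02,
    charlson_positive = 0.33
  )
  prev <- default_prev
  if (!is.null(covariate_prevalences)) {
    stopifnot(all(names(covariate_prevalences) %in% names(prev)))
    prev[names(covariate_prevalences)] <- covariate_prevalences
  }
  if (any(prev <= 0 | prev >= 1)) stop("covariate prevalences must be in (0,1)")
  eff <- stats::setNames(numeric(length(prev)), names(prev))
  if (!is.null(covariate_effects_rx)) {
    stopifnot(all(names(covariate_effects_rx) %in% names(eff)))
    eff[names(covariate_effects_rx)] <- covariate_effects_rx
  }
  start <- as.Date(calendar_start); end <- as.Date(calendar_end)
  if (!(start < end)) stop("calendar_start must precede calendar_end")
  stopifnot(n_physicians >= 1, patients_per_physician >= 1,
            preference_sd >= 0, casemix_sd >= 0,
            baseline_risk > 0, baseline_risk < 1,
            baseline_share_rx > 0, baseline_share_rx < 1)
  structure(list(
    n_physicians = as.integer(n_physicians),
    patients_per_physician = as.integer(patients_per_physician),
    preference_sd = preference_sd, preference_drift = preference_drift,
    covariate_prevalences = prev, casemix_sd = casemix_sd,
    confounder_effect_rx = confounder_effect_rx,
    covariate_effects_rx = eff, trend_rx = trend_rx,
    baseline_share_rx = baseline_share_rx, baseline_risk = baseline_risk,
    treatment_effect = treatment_effect,
    confounder_effect_y = confounder_effect_y,
    preference_effect_y = preference_effect_y,
    paroxetine_share = paroxetine_share,
    preference_sd_parox = preference_sd_parox %||% preference_sd,
    trend_parox = trend_parox,
    bmi_missing_rate = bmi_missing_rate,
    history_per_physician = as.integer(history_per_physician),
    calendar_start = start, calendar_end = end,
    seed = as.integer(seed)
  ), class = "prefiv_sim_config")
}

#' Generate a physician-clustered prescribing population
#'
#' Draws a complete synthetic dataset -- prescription events, patient
#' records with baseline covariates, and outcome events within three months
#' of the index prescription -- together with the latent truth (physician
#' preferences, each patient's unmeasured confounder, the true effect)
#' needed for recovery experiments. See [sim_config()] for the model.
#'
#' The outcome uses a clipped linear risk model; the function aborts if
#' clipping touches more than 1% of patients, since that means the
#' configured effects are inconsistent with a linear risk scale.
#'
#' @param config A [sim_config()] object.
#' @return List with tibbles `prescriptions`, `patients`, `outcomes`, and
#'   `truth` (physician_preferences, patient_confounders, true_effect,
#'   linked_practices).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "prefiv_sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  np <- config$n_physicians
  ppp <- config$patients_per_physician
  N <- np * ppp
  phys_ids <- sprintf("D%05d", seq_len(np))
  practice_ids <- sprintf("G%04d", ceiling(seq_len(np) / 5))
  pref <- rnorm(np, 0, config$preference_sd)
  pref_px <- rnorm(np, 0, config$preference_sd_parox)
  casemix <- rnorm(np, 0, config$casemix_sd)

  span <- as.numeric(config$calendar_end - config$calendar_start)
  phys_idx <- rep(seq_len(np), each = ppp)
  offs <- floor(runif(N, 0, span + 1))
  ord <- order(phys_idx, offs)
  phys_idx <- phys_idx[ord]
  date <- config$calendar_start + offs[ord]
  # ids assigned after the per-physician date sort, so same-date ties are
  # ordered by patient id by construction
  patient_id <- sprintf("P%07d", seq_len(N))
  yearfrac <- as.numeric(date - config$calendar_start) / 365.25

  prev <- config$covariate_prevalences
  cm <- casemix[phys_idx]
  cov <- vapply(names(prev), function(k) {
    rbinom(N, 1, plogis(qlogis(prev[[k]]) + cm))
  }, numeric(N))
  colnames(cov) <- names(prev)

  u <- rbinom(N, 1, 0.5)

  logit_rx <- qlogis(config$baseline_share_rx) +
    pref[phys_idx] + config$preference_drift * yearfrac +
    as.numeric(cov %*% config$covariate_effects_rx) +
    config$confounder_effect_rx * u +
    config$trend_rx * yearfrac
  x <- rbinom(N, 1, plogis(logit_rx))

  drug_class <- ifelse(x == 1, "TCA", "SSRI")
  ami <- x == 1 & runif(N) < 0.5
  p_px <- plogis(qlogis(config$paroxetine_share) + pref_px[phys_idx] +
                   config$trend_parox * yearfrac)
  px <- x == 0 & runif(N) < p_px
  drug_name <- ifelse(x == 1, ifelse(ami, "amitriptyline", "dothiepin"),
                      ifelse(px, "paroxetine",
                             ifelse(runif(N) < 0.5, "fluoxetine", "citalopram")))
  dose_mg <- ifelse(drug_name == "amitriptyline",
                    sample(c(75, 100, 150), N, replace = TRUE),
                    ifelse(drug_class == "TCA", 75, 20))

  # ages: consistent with the age_over_40 indicator, never under 10
  age <- ifelse(cov[, "age_over_40"] == 1,
                41 + floor(runif(N, 0, 40)), 16 + floor(runif(N, 0, 25)))
  birth_year <- as.integer(format(date, "%Y")) - age
  bmi <- ifelse(cov[, "bmi_over_25"] == 1,
                pmin(45, 25.1 + abs(rnorm(N, 3, 3))),
                pmax(16, 25 - abs(rnorm(N, 2.5, 2))))
  bmi <- round(bmi, 1)
  bmi_na <- runif(N) < config$bmi_missing_rate
  bmi[bmi_na] <- NA_real_
  cov_obs <- cov
  cov_obs[bmi_na, "bmi_over_25"] <- NA_real_

  registration_start <- date - floor(runif(N, 400, 2500))

  risk_raw <- config$baseline_risk + config$treatment_effect / 100 * x +
    config$confounder_effect_y / 100 * u +
    config$preference_effect_y / 100 * pref[phys_idx]
  clipped <- risk_raw < 0 | risk_raw > 1
  if (mean(clipped) > 0.01) {
    stop(sprintf(paste0("linear risk model clipped for %.1f%% of patients; ",
                        "configuration inconsistent with a risk-difference scale"),
                 100 * mean(clipped)), call. = FALSE)
  }
  y <- rbinom(N, 1, pmin(1, pmax(0, risk_raw)))
  event_offset <- sample.int(91, N, replace = TRUE)
  event_type <- ifelse(runif(N) < 0.9, "self_harm_admission", "suicide_death")

  prescriptions <- tibble::tibble(
    record_id = seq_len(N),
    patient_id = patient_id,
    physician_id = phys_ids[phys_idx],
    practice_id = practice_ids[phys_idx],
    prescriber_is_physician = TRUE,
    date = date,
    drug_class = drug_class,
    drug_name = drug_name,
    dose_mg = dose_mg
  )

  h <- config$history_per_physician
  if (h > 0) {
    hk <- rep(seq_len(h), times = np)
    hp <- rep(seq_len(np), each = h)
    hdrug_tca <- (hk %% 2L) == 0L
    hpx <- !hdrug_tca & (hk %% 4L) == 1L
    history <- tibble::tibble(
      record_id = N + seq_along(hk),
      patient_id = sprintf("H%05d_%02d", hp, hk),
      physician_id = phys_ids[hp],
      practice_id = practice_ids[hp],
      prescriber_is_physician = TRUE,
      date = config$calendar_start - 7L * (h - hk + 1L),
      drug_class = ifelse(hdrug_tca, "TCA", "SSRI"),
      drug_name = ifelse(hdrug_tca, "amitriptyline",
                         ifelse(hpx, "paroxetine", "fluoxetine")),
      dose_mg = ifelse(hdrug_tca, 75, 20)
    )
    prescriptions <- bind_rows(history, prescriptions)
  }

  patients <- tibble::tibble(
    patient_id = patient_id,
    birth_year = birth_year,
    sex = ifelse(cov[, "male"] == 1, "M", "F"),
    registration_start = registration_start,
    registration_end = as.Date(NA),
    bmi = bmi
  )
  patients <- dplyr::bind_cols(patients, tibble::as_tibble(cov_obs))

  outcomes <- tibble::tibble(
    patient_id = patient_id[y == 1],
    event_date = date[y == 1] + event_offset[y == 1],
    event_type = event_type[y == 1]
  )

  truth <- list(
    physician_preferences = tibble::tibble(physician_id = phys_ids,
                                           preference = pref,
                                           preference_parox = pref_px),
    patient_confounders = tibble::tibble(patient_id = patient_id, u = u),
    true_effect = config$treatment_effect,
    linked_practices = unique(practice_ids)[
      seq_len(ceiling(length(unique(practice_ids)) / 2))]
  )

  list(prescriptions = prescriptions, patients = patients,
       outcomes = outcomes, truth = truth)
}
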