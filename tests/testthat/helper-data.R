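# Shared fixtures, built in code.

# Small generator configuration used across tests; override fields as
# needed.
quick_cfg <- function(...) {
  dots <- list(...)
  base <- list(n_physicians = 30, patients_per_physician = 30,
               preference_sd = 1, casemix_sd = 0.2, seed = 1L)
  base[names(dots)] <- dots
  do.call(sim_config, base)
}

# Hand-buildable raw tables for cohort-construction tests: one row per
# supplied prescription, minimal patient records.
tiny_tables <- function(rx, patients) {
  fill <- function(df, name, value) {
    if (!name %in% names(df)) df[[name]] <- value
    df
  }
  rx <- fill(rx, "record_id", seq_len(nrow(rx)))
  rx <- fill(rx, "practice_id", "G1")
  rx <- fill(rx, "prescriber_is_physician", TRUE)
  rx <- fill(rx, "drug_class", "SSRI")
  rx <- fill(rx, "drug_name", "fluoxetine")
  rx <- fill(rx, "dose_mg", 20)
  patients <- fill(patients, "birth_year", 1960L)
  patients <- fill(patients, "sex", "F")
  patients <- fill(patients, "registration_end", as.Date(NA))
  patients <- fill(patients, "bmi", 24)
  for (cv in covariate_names()) patients <- fill(patients, cv, 0)
  list(prescriptions = tibble::as_tibble(rx),
       patients = tibble::as_tibble(patients))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Random small binary IV dataset with a guaranteed nonzero first stage,
# for the 2SLS-vs-Wald-ratio oracle checks.
random_iv_data <- function(seed, n_max = 50) {
  set.seed(seed)
  repeat {
    n <- sample(10:n_max, 1)
    z <- rbinom(n, 1, runif(1, 0.2, 0.8))
    x <- rbinom(n, 1, plogis(-0.5 + 2 * z + rnorm(n)))
    y <- rbinom(n, 1, plogis(-0.5 + x + rnorm(n)))
    if (length(unique(z)) == 2 &&
        mean(x[z == 1]) != mean(x[z == 0])) {
      return(list(y = y, x = x, z = z))
    }
  }
}
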