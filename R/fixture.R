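# Messy-fixture construction: start from a population that passes every
# exclusion rule, then inject a requested number of violations per rule,
# each on a distinct patient so no row accidentally violates two rules.

fixture_rules <- function() {
  c("pre_registration", "missing_date", "post_deregistration",
    "index_within_12mo_of_registration", "index_outside_window",
    "prescriber_not_physician", "missing_physician_id", "age_under_10",
    "missing_birth_year", "physician_fewer_than_10_prior",
    "bmi_out_of_range", "low_dose_amitriptyline_lt13",
    "low_dose_amitriptyline_lt70")
}

#' Build a prescribing dataset with known rule violations
#'
#' Generates a clean population (every patient passes every exclusion: the
#' generator is run with enough warm-up prescribing history per physician
#' that the prior-prescription-count rule is satisfied from the first
#' cohort patient) and then mutates a distinct patient per requested
#' violation. Targets are spread round-robin across physicians so that
#' perturbations which remove a prescription from a physician's history
#' (missing physician id, reassignment to a fresh physician, a date moved
#' outside the window) can never push an untargeted patient below the
#' prior-count threshold.
#'
#' Supported rule names: the three record-validity rules
#' (`pre_registration`, `missing_date`, `post_deregistration`, injected as
#' extra prescription records that must be filtered before index
#' selection); the seven cohort exclusions
#' (`index_within_12mo_of_registration`, `index_outside_window`,
#' `prescriber_not_physician`, `missing_physician_id`, `age_under_10`,
#' `missing_birth_year`, `physician_fewer_than_10_prior`);
#' `bmi_out_of_range` (value set implausible, expected to be nulled, not
#' removed); and `low_dose_amitriptyline_lt13` / `_lt70` (index switched
#' to amitriptyline at 10 mg / 50 mg). A 10 mg row violates both dose
#' thresholds by construction, so the expected count at the 70 mg
#' threshold is the sum of the two.
#'
#' @param config A [sim_config()]; its `history_per_physician` is raised
#'   automatically to cover `min_prior` plus a safety margin.
#' @param violation_counts Named integer vector/list, names from the rule
#'   set above.
#' @param min_prior Prior-count threshold the fixture is built to satisfy.
#' @return List: `prescriptions`, `patients`, `outcomes`, `expected`
#'   (tibble rule / removed covering every rule, zero where not
#'   requested), `window`, `truth`.
#' @export
make_messy_fixture <- function(config, violation_counts = list(),
                               min_prior = 10) {
  counts <- unlist(violation_counts)
  if (length(counts)) {
    bad <- setdiff(names(counts), fixture_rules())
    if (length(bad)) stop("unknown rule(s): ", paste(bad, collapse = ", "))
  }
  total <- sum(counts)
  N <- config$n_physicians * config$patients_per_physician
  if (total > N) stop("requested violations exceed population size")
  buffer <- max(6, ceiling(total / config$n_physicians) + 2)
  cfg <- config
  cfg$history_per_physician <- as.integer(min_prior + buffer)
  pop <- generate_population(cfg)
  rx <- pop$prescriptions
  pat <- pop$patients

  # round-robin target order: each physician's first patient, then each
  # physician's second, ...
  cohort_rx <- rx[rx$patient_id %in% pat$patient_id, ] %>%
    arrange(.data$physician_id, .data$date, .data$patient_id) %>%
    group_by(.data$physician_id) %>%
    mutate(.rank = row_number()) %>%
    ungroup() %>%
    arrange(.data$.rank, .data$physician_id)
  targets <- cohort_rx$patient_id
  taken <- 0L
  take <- function(k) {
    out <- targets[seq.int(taken + 1L, taken + k)]
    taken <<- taken + as.integer(k)
    out
  }
  idx_of <- function(ids) match(ids, rx$patient_id)  # unique per patient
  pat_of <- function(ids) match(ids, pat$patient_id)
  next_record_id <- max(rx$record_id) + 1L
  new_records <- list()
  add_record <- function(base_rows, date) {
    nr <- rx[base_rows, ]
    nr$record_id <- next_record_id + seq_len(nrow(nr)) - 1L
    next_record_id <<- next_record_id + nrow(nr)
    nr$date <- date
    nr$drug_class <- "SSRI"; nr$drug_name <- "fluoxetine"; nr$dose_mg <- 20
    new_records[[length(new_records) + 1L]] <<- nr
  }

  get <- function(rule) if (rule %in% names(counts)) counts[[rule]] else 0L

  if (get("pre_registration") > 0) {
    ids <- take(get("pre_registration"))
    add_record(idx_of(ids),
               pat$registration_start[pat_of(ids)] - 30)
  }
  if (get("missing_date") > 0) {
    ids <- take(get("missing_date"))
    add_record(idx_of(ids), as.Date(NA))
  }
  if (get("post_deregistration") > 0) {
    ids <- take(get("post_deregistration"))
    idx_dates <- rx$date[idx_of(ids)]
    pat$registration_end[pat_of(ids)] <- idx_dates + 150
    add_record(idx_of(ids), idx_dates + 200)
  }
  if (get("index_within_12mo_of_registration") > 0) {
    ids <- take(get("index_within_12mo_of_registration"))
    pat$registration_start[pat_of(ids)] <- rx$date[idx_of(ids)] - 60
  }
  if (get("index_outside_window") > 0) {
    ids <- take(get("index_outside_window"))
    rx$date[idx_of(ids)] <- cfg$calendar_end + 30
  }
  if (get("prescriber_not_physician") > 0) {
    ids <- take(get("prescriber_not_physician"))
    rx$prescriber_is_physician[idx_of(ids)] <- FALSE
  }
  if (get("missing_physician_id") > 0) {
    ids <- take(get("missing_physician_id"))
    rx$physician_id[idx_of(ids)] <- NA_character_
  }
  if (get("age_under_10") > 0) {
    ids <- take(get("age_under_10"))
    pat$birth_year[pat_of(ids)] <-
      as.integer(format(rx$date[idx_of(ids)], "%Y")) - 5L
  }
  if (get("missing_birth_year") > 0) {
    ids <- take(get("missing_birth_year"))
    pat$birth_year[pat_of(ids)] <- NA_integer_
  }
  if (get("physician_fewer_than_10_prior") > 0) {
    ids <- take(get("physician_fewer_than_10_prior"))
    rows <- idx_of(ids)
    rx$physician_id[rows] <- sprintf("DX%04d", seq_along(rows))
  }
  if (get("bmi_out_of_range") > 0) {
    ids <- take(get("bmi_out_of_range"))
    rows <- pat_of(ids)
    pat$bmi[rows] <- ifelse(seq_along(rows) %% 2 == 0, 7.5, 150.2)
  }
  for (th in c(13, 70)) {
    rule <- paste0("low_dose_amitriptyline_lt", th)
    if (get(rule) > 0) {
      ids <- take(get(rule))
      rows <- idx_of(ids)
      rx$drug_class[rows] <- "TCA"
      rx$drug_name[rows] <- "amitriptyline"
      rx$dose_mg[rows] <- if (th == 13) 10 else 50
    }
  }

  if (length(new_records)) rx <- bind_rows(rx, bind_rows(new_records))

  expected <- tibble::tibble(rule = fixture_rules(),
                             removed = vapply(fixture_rules(), get, numeric(1)))
  expected$removed[expected$rule == "low_dose_amitriptyline_lt70"] <-
    get("low_dose_amitriptyline_lt70") + get("low_dose_amitriptyline_lt13")

  list(prescriptions = rx, patients = pat, outcomes = pop$outcomes,
       expected = expected,
       window = c(cfg$calendar_start, cfg$calendar_end),
       truth = pop$truth)
}
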