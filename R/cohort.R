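# Cohort construction: index prescription selection, the ordered exclusion
# cascade, outcome attachment and the sensitivity filters.

# Record-level validity filter shared by index selection and the
# prior-prescription counts: a prescription record is dropped when it
# predates the patient's registration, has no date, or postdates the
# registration end. Records for patients absent from the patient table
# (e.g. warm-up history patients) are kept -- they contribute to physician
# prescribing history but can never become cohort candidates.
valid_prescriptions <- function(prescriptions, patients) {
  reg <- patients[, c("patient_id", "registration_start", "registration_end")]
  x <- left_join(prescriptions, reg, by = "patient_id")
  known <- x$patient_id %in% patients$patient_id
  missing_date <- is.na(x$date)
  pre_reg <- !missing_date & known & !is.na(x$registration_start) &
    x$date < x$registration_start
  post_dereg <- !missing_date & known & !is.na(x$registration_end) &
    x$date > x$registration_end
  keep <- !(missing_date | pre_reg | post_dereg)
  removed <- c(pre_registration = sum(pre_reg),
               missing_date = sum(missing_date),
               post_deregistration = sum(post_dereg))
  out <- x[keep, setdiff(names(x), c("registration_start", "registration_end"))]
  attr(out, "records_removed") <- removed
  out
}

#' Select each patient's index (first valid) prescription
#'
#' Drops prescription records that predate the patient's registration, have
#' a missing date, or postdate the registration end, then keeps the
#' earliest remaining record per patient. Same-date ties are broken
#' deterministically by drug class (alphabetical), drug name, then record
#' id. Patients without a record in the patient table, or with no valid
#' dated record, do not appear in the output.
#'
#' @param prescriptions Prescription event table (see the package data
#'   schema: `patient_id`, `physician_id`, `practice_id`,
#'   `prescriber_is_physician`, `date`, `drug_class`, `drug_name`,
#'   `dose_mg`, `record_id`).
#' @param patients Patient table with registration dates.
#' @return Candidate index tibble, one row per patient, with attributes
#'   `records_removed` (per-rule counts of invalid records) and
#'   `n_duplicate_records` (count of exact `(patient, date, drug)`
#'   duplicates, also raised as a warning).
#' @export
select_index_prescriptions <- function(prescriptions, patients) {
  valid <- valid_prescriptions(prescriptions, patients)
  valid <- valid[valid$patient_id %in% patients$patient_id, ]
  dup <- duplicated(valid[, c("patient_id", "date", "drug_name")])
  if (any(dup)) {
    warning(sprintf("%d exact duplicate (patient, date, drug) records", sum(dup)))
  }
  valid <- valid[order(valid$patient_id, valid$date, valid$drug_class,
                       valid$drug_name, valid$record_id), ]
  idx <- valid[!duplicated(valid$patient_id), ] %>%
    dplyr::rename(index_date = "date") %>%
    mutate(index_year = as.integer(format(.data$index_date, "%Y")))
  attr(idx, "records_removed") <- attr(valid, "records_removed")
  attr(idx, "n_duplicate_records") <- sum(dup)
  idx
}

# Distinct earlier patients served by each candidate's physician, from the
# valid prescription records (optionally restricted to SSRIs). "Prior
# prescriptions" count distinct patients whose first valid prescription
# from that physician strictly precedes the candidate's index date, the
# patient-level (not event-level) reading of a physician's history.
prior_patient_counts <- function(candidates, valid, ssri_only = FALSE) {
  h <- valid[!is.na(valid$physician_id), ]
  if (ssri_only) h <- h[h$drug_class == "SSRI", ]
  h <- h[order(h$physician_id, h$patient_id, h$date), ]
  firsts <- h[!duplicated(paste(h$physician_id, h$patient_id, sep = "\r")), ]
  # strictly-earlier distinct patients: min-rank of the first date within
  # the physician, minus one (ties share the same count)
  firsts <- firsts[order(firsts$physician_id, firsts$date), ]
  grp_start <- !duplicated(firsts$physician_id)
  pos <- seq_len(nrow(firsts)) - rep(which(grp_start),
                                     diff(c(which(grp_start),
                                            nrow(firsts) + 1L)))
  # pos is 0-based position; convert to strictly-smaller count (min rank)
  key_pd <- paste(firsts$physician_id, firsts$date, sep = "\r")
  first_of_tie <- !duplicated(key_pd)
  minpos <- pos[first_of_tie][cumsum(first_of_tie)]
  lut <- stats::setNames(minpos, paste(firsts$physician_id,
                                       firsts$patient_id, sep = "\r"))
  out <- unname(lut[paste(candidates$physician_id, candidates$patient_id,
                          sep = "\r")])
  out[is.na(candidates$physician_id)] <- NA_real_
  out
}

#' Apply the cohort exclusion cascade
#'
#' Applies, in a fixed documented order, the exclusion rules for
#' preference-based IV cohorts: (1) index within 12 months of joining the
#' practice; (2) index outside the study calendar window; (3) prescriber
#' not a physician; (4) missing physician identifier; (5) younger than 10
#' at index; (6) missing birth year; (7) physician with fewer than
#' `min_prior` prior prescriptions; plus contrast-specific rules
#' (`tca-ssri`: physician never previously prescribed an antidepressant;
#' `parox-ssri`: drop TCA index patients and patients whose physician has
#' no prior SSRI). A row violating several rules is counted under the first
#' one only; permuting the order changes per-rule counts but never final
#' membership.
#'
#' @param candidates Output of [select_index_prescriptions()].
#' @param patients Patient table.
#' @param prescriptions Full prescription table (physician history for the
#'   prior-count rules is recomputed from its valid records).
#' @param contrast `"tca-ssri"` (exposure = TCA) or `"parox-ssri"`
#'   (exposure = paroxetine among SSRI patients).
#' @param window Length-2 calendar window for rule 2.
#' @param min_prior Prior-prescription threshold for rule 7 (default 10).
#' @param registration_days Rule-1 threshold; 12 months taken as 365 days.
#' @param rule_order Optional permutation of the rule names (a subset of
#'   the defaults is rejected). The cascade order affects which rule a
#'   doubly-violating row is charged to -- never final membership.
#' @return List with `cohort` (candidates surviving all rules, with
#'   exposure `X`, `index_year` and covariates joined from the patient
#'   table) and `attrition` (tibble rule / removed / remaining, attribute
#'   `n_input`).
#' @export
apply_exclusions <- function(candidates, patients, prescriptions,
                             contrast = c("tca-ssri", "parox-ssri"),
                             window = c("1995-01-01", "2010-06-30"),
                             min_prior = 10,
                             registration_days = 365,
                             rule_order = NULL) {
  contrast <- match.arg(contrast)
  window <- as.Date(window)
  if (window[1] >= window[2]) stop("inverted calendar window")
  valid <- valid_prescriptions(prescriptions, patients)
  # drop patient-table columns so the cascade can be re-applied to its own
  # output (idempotence) without join-name collisions
  candidates <- candidates[, setdiff(names(candidates),
                                     c("birth_year", "registration_start",
                                       "sex", "bmi", "X", covariate_names()))]
  x <- left_join(candidates,
                 patients[, c("patient_id", "birth_year", "registration_start")],
                 by = "patient_id")
  x$.prior_n <- prior_patient_counts(x, valid)
  if (contrast == "parox-ssri") {
    x$.prior_ssri <- prior_patient_counts(x, valid, ssri_only = TRUE)
  }

  age <- x$index_year - x$birth_year
  rules <- list(
    index_within_12mo_of_registration =
      !is.na(x$registration_start) &
      as.numeric(x$index_date - x$registration_start) < registration_days,
    index_outside_window =
      x$index_date < window[1] | x$index_date > window[2],
    prescriber_not_physician = !x$prescriber_is_physician,
    missing_physician_id = is.na(x$physician_id),
    age_under_10 = !is.na(age) & age < 10,
    missing_birth_year = is.na(x$birth_year),
    physician_fewer_than_10_prior = !is.na(x$.prior_n) & x$.prior_n < min_prior
  )
  if (contrast == "tca-ssri") {
    rules$physician_no_prior_antidepressant <-
      !is.na(x$.prior_n) & x$.prior_n < 1
  } else {
    rules$index_tca <- x$drug_class == "TCA"
    rules$physician_no_prior_ssri <- !is.na(x$.prior_ssri) & x$.prior_ssri < 1
  }

  if (!is.null(rule_order)) {
    if (!setequal(rule_order, names(rules))) {
      stop("rule_order must be a permutation of: ",
           paste(names(rules), collapse = ", "))
    }
    rules <- rules[rule_order]
  }

  alive <- rep(TRUE, nrow(x))
  log <- vector("list", length(rules))
  for (i in seq_along(rules)) {
    hit <- alive & rules[[i]]
    alive <- alive & !hit
    log[[i]] <- tibble::tibble(rule = names(rules)[i], removed = sum(hit),
                               remaining = sum(alive))
  }
  attrition <- bind_rows(log)
  attr(attrition, "n_input") <- nrow(x)

  cohort <- x[alive, ]
  cohort$X <- if (contrast == "tca-ssri") {
    as.integer(cohort$drug_class == "TCA")
  } else {
    as.integer(cohort$drug_name == "paroxetine")
  }
  cohort <- left_join(
    cohort,
    patients[, c("patient_id", "sex", "bmi", covariate_names())],
    by = "patient_id")
  cohort <- cohort[, setdiff(names(cohort), c(".prior_n", ".prior_ssri"))]
  list(cohort = cohort, attrition = attrition)
}

#' Attach the 3-month outcome indicator to a cohort
#'
#' Sets `Y = 1` when a qualifying event (self-harm admission or suicide
#' death) falls in the window `(index_date, index_date + window_days]`:
#' left-open so that events on the index date itself -- plausibly the
#' indication rather than a consequence -- never count, right-closed so the
#' boundary day does.
#'
#' @param cohort Cohort table with `patient_id`, `index_date`,
#'   `practice_id`.
#' @param outcomes Event table (`patient_id`, `event_date`, `event_type`).
#' @param window_days Outcome window; "3 months" taken as 91 days.
#' @param drop_prior_self_harm Remove patients with a self-harm admission
#'   on or before the index date (count kept in attribute
#'   `n_prior_self_harm_dropped`).
#' @param linked_practices Optional character vector of practices with
#'   outcome linkage; when supplied the cohort is restricted to them and a
#'   `linked` flag is set.
#' @return Cohort with `Y` attached.
#' @export
attach_outcome <- function(cohort, outcomes, window_days = 91,
                           drop_prior_self_harm = FALSE,
                           linked_practices = NULL) {
  if (window_days < 0) stop("negative outcome window")
  n_psh <- 0L
  if (drop_prior_self_harm && nrow(outcomes) > 0) {
    prior <- dplyr::inner_join(
      cohort[, c("patient_id", "index_date")],
      outcomes[outcomes$event_type == "self_harm_admission", ],
      by = "patient_id", relationship = "many-to-many")
    bad <- unique(prior$patient_id[prior$event_date <= prior$index_date])
    n_psh <- length(bad)
    cohort <- cohort[!(cohort$patient_id %in% bad), ]
  }
  if (!is.null(linked_practices)) {
    cohort <- cohort[cohort$practice_id %in% linked_practices, ]
    cohort$linked <- TRUE
  }
  qualifying <- outcomes[outcomes$event_type %in%
                           c("self_harm_admission", "suicide_death"), ]
  hits <- dplyr::inner_join(cohort[, c("patient_id", "index_date")],
                            qualifying, by = "patient_id",
                            relationship = "many-to-many")
  hits <- hits[hits$event_date > hits$index_date &
                 hits$event_date <= hits$index_date + window_days, ]
  cohort$Y <- as.integer(cohort$patient_id %in% hits$patient_id)
  attr(cohort, "n_prior_self_harm_dropped") <- n_psh
  cohort
}

#' Drop low-dose amitriptyline index prescriptions
#'
#' Sensitivity filter: removes cohort rows whose index prescription is
#' amitriptyline below `threshold_mg` (such doses are commonly issued for
#' non-depression indications like neuropathic pain). Rows with a missing
#' dose are retained; their count is kept in attribute `n_missing_dose`.
#'
#' @param cohort Cohort with `drug_name` and `dose_mg` from the index
#'   prescription.
#' @param threshold_mg Positive dose cutoff (13 and 70 mg are the
#'   conventional sensitivity thresholds).
#' @return Filtered cohort with attribute `n_removed`.
#' @export
filter_low_dose_amitriptyline <- function(cohort, threshold_mg) {
  if (threshold_mg <= 0) stop("threshold_mg must be positive")
  ami <- cohort$drug_name == "amitriptyline"
  missing_dose <- ami & is.na(cohort$dose_mg)
  drop <- ami & !is.na(cohort$dose_mg) & cohort$dose_mg < threshold_mg
  out <- cohort[!drop, ]
  attr(out, "n_removed") <- sum(drop)
  attr(out, "n_missing_dose") <- sum(missing_dose)
  out
}

#' Treat out-of-range BMI values as missing
#'
#' BMI strictly below `low` or strictly above `high` is assumed to be a
#' data-entry error and set to missing; the boundary values themselves are
#' retained. The `bmi_over_25` indicator is recomputed from the in-range
#' values only.
#'
#' @param patients Patient table with `bmi`.
#' @param low,high Plausibility bounds (defaults 15 and 100).
#' @return Patient table with cleaned `bmi` and recomputed `bmi_over_25`;
#'   attribute `n_out_of_range` counts the values set missing.
#' @export
filter_bmi_range <- function(patients, low = 15, high = 100) {
  if (low >= high) stop("low must be below high")
  bad <- !is.na(patients$bmi) & (patients$bmi < low | patients$bmi > high)
  patients$bmi[bad] <- NA_real_
  patients$bmi_over_25 <- ifelse(is.na(patients$bmi), NA_real_,
                                 as.numeric(patients$bmi > 25))
  attr(patients, "n_out_of_range") <- sum(bad)
  patients
}
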