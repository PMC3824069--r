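test_that("index selection drops invalid records and keeps the earliest", {
  tt <- tiny_tables(
    rx = tibble::tibble(
      patient_id = c("p1", "p1", "p2", "p2", "p3"),
      physician_id = "d1",
      date = as.Date(c("2000-01-05", "2000-02-09", NA, NA, "2001-05-01"))),
    patients = tibble::tibble(
      patient_id = c("p1", "p2", "p3"),
      registration_start = as.Date(c("2000-01-20", "1999-01-01",
                                     "2000-01-01"))))
  idx <- select_index_prescriptions(tt$prescriptions, tt$patients)
  # p1's day-5 record is pre-registration: index is the in-range record
  expect_equal(idx$index_date[idx$patient_id == "p1"],
               as.Date("2000-02-09"))
  # p2 has only missing-date records and is absent
  expect_false("p2" %in% idx$patient_id)
  expect_equal(unname(attr(idx, "records_removed")["missing_date"]), 2)
  expect_equal(unname(attr(idx, "records_removed")["pre_registration"]), 1)
})

test_that("post-deregistration records never become the index", {
  tt <- tiny_tables(
    rx = tibble::tibble(patient_id = "p1", physician_id = "d1",
                        date = as.Date(c("2005-06-01", "2003-03-01"))),
    patients = tibble::tibble(patient_id = "p1",
                              registration_start = as.Date("2000-01-01"),
                              registration_end = as.Date("2004-01-01")))
  idx <- select_index_prescriptions(tt$prescriptions, tt$patients)
  expect_equal(idx$index_date, as.Date("2003-03-01"))
})

test_that("exact duplicate records are counted via a warning", {
  tt <- tiny_tables(
    rx = tibble::tibble(patient_id = c("p1", "p1"), physician_id = "d1",
                        date = as.Date("2000-05-01")),
    patients = tibble::tibble(patient_id = "p1",
                              registration_start = as.Date("1999-01-01")))
  expect_warning(idx <- select_index_prescriptions(tt$prescriptions,
                                                   tt$patients),
                 "duplicate")
  expect_equal(nrow(idx), 1)
})

test_that("a doubly-violating row is charged to the first rule only", {
  tt <- tiny_tables(
    # the "h0" record gives physician d1 prescribing history without
    # adding a cohort candidate
    rx = tibble::tibble(patient_id = c("h0", "p1", "p2"),
                        physician_id = "d1",
                        date = as.Date(c("1990-01-01", "2000-06-01",
                                         "2000-06-01"))),
    patients = tibble::tibble(
      patient_id = c("p1", "p2"),
      # p1 violates both the 12-month-registration rule and age<10
      registration_start = as.Date(c("2000-05-01", "1995-01-01")),
      birth_year = c(1995L, 1960L)))
  idx <- select_index_prescriptions(tt$prescriptions, tt$patients)
  exc <- apply_exclusions(idx, tt$patients, tt$prescriptions, min_prior = 0)
  at <- exc$attrition
  expect_equal(at$removed[at$rule == "index_within_12mo_of_registration"], 1L)
  expect_equal(at$removed[at$rule == "age_under_10"], 0L)
  expect_equal(nrow(exc$cohort), 1)
})

test_that("attrition conserves rows, is idempotent, and per-rule counts are order-sensitive while membership is not", {
  cfg <- quick_cfg(n_physicians = 10, patients_per_physician = 20, seed = 13)
  fx <- make_messy_fixture(cfg, list(age_under_10 = 4,
                                     index_within_12mo_of_registration = 3,
                                     missing_physician_id = 2))
  cand <- select_index_prescriptions(fx$prescriptions, fx$patients)
  exc <- apply_exclusions(cand, fx$patients, fx$prescriptions,
                          window = fx$window)
  # conservation
  expect_equal(attr(exc$attrition, "n_input") - sum(exc$attrition$removed),
               nrow(exc$cohort))
  expect_true(all(diff(exc$attrition$remaining) <= 0))
  # idempotence: the surviving cohort passes a second cascade untouched
  again <- apply_exclusions(exc$cohort, fx$patients, fx$prescriptions,
                            window = fx$window)
  expect_equal(sum(again$attrition$removed), 0)
  # permuted order: different per-rule counts possible, same membership
  perm <- rev(c("index_within_12mo_of_registration", "index_outside_window",
                "prescriber_not_physician", "missing_physician_id",
                "age_under_10", "missing_birth_year",
                "physician_fewer_than_10_prior",
                "physician_no_prior_antidepressant"))
  exc2 <- apply_exclusions(cand, fx$patients, fx$prescriptions,
                           window = fx$window, rule_order = perm)
  expect_setequal(exc2$cohort$patient_id, exc$cohort$patient_id)
})

test_that("outcome window is left-open, right-closed", {
  cohort <- tibble::tibble(patient_id = c("p1", "p2", "p3"),
                           practice_id = "G1",
                           index_date = as.Date("2000-01-01"))
  ev <- tibble::tibble(
    patient_id = c("p1", "p2"),
    event_date = as.Date(c("2000-01-01", "2000-01-01")) + c(0, 91),
    event_type = "self_harm_admission")
  out <- attach_outcome(cohort, ev, window_days = 91)
  expect_equal(out$Y, c(0L, 1L, 0L))  # day 0 excluded, day 91 included
  none <- attach_outcome(cohort, ev[0, ], window_days = 91)
  expect_true(all(none$Y == 0))
  expect_error(attach_outcome(cohort, ev, window_days = -1), "negative")
})

test_that("prior self-harm admissions can be excluded from the outcome cohort", {
  cohort <- tibble::tibble(patient_id = c("p1", "p2"), practice_id = "G1",
                           index_date = as.Date("2000-06-01"))
  ev <- tibble::tibble(patient_id = "p1",
                       event_date = as.Date("1999-12-01"),
                       event_type = "self_harm_admission")
  out <- attach_outcome(cohort, ev, drop_prior_self_harm = TRUE)
  expect_equal(out$patient_id, "p2")
  expect_equal(attr(out, "n_prior_self_harm_dropped"), 1L)
})

test_that("incidence summary matches the published cohort arithmetic", {
  cohort <- tibble::tibble(Y = c(rep(1L, 608), rep(0L, 394846 - 608)))
  inc <- summarize_incidence(cohort)
  expect_equal(inc$rate_per_100, 0.15)
  expect_equal(summarize_incidence(tibble::tibble(Y = rep(0L, 10)))$rate_per_100, 0)
  expect_equal(summarize_incidence(tibble::tibble(Y = c(1L, 0L, 0L, 0L)))$rate_per_100, 25)
  expect_error(summarize_incidence(cohort[0, ]), "empty")
})

test_that("BMI plausibility bounds are strict and the indicator is recomputed", {
  pat <- tibble::tibble(patient_id = paste0("p", 1:6),
                        bmi = c(101, 15, 26, 100, 14.9, NA),
                        bmi_over_25 = c(1, 0, 1, 1, 0, NA))
  out <- filter_bmi_range(pat)
  expect_equal(is.na(out$bmi), c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(out$bmi_over_25, c(NA, 0, 1, 1, NA, NA))
  expect_equal(attr(out, "n_out_of_range"), 2L)
  expect_error(filter_bmi_range(pat, low = 50, high = 40), "below")
})

test_that("low-dose amitriptyline filtering respects thresholds and missing doses", {
  cohort <- tibble::tibble(
    patient_id = paste0("p", 1:4),
    drug_name = c("amitriptyline", "amitriptyline", "amitriptyline",
                  "fluoxetine"),
    dose_mg = c(10, 25, NA, 20))
  at13 <- filter_low_dose_amitriptyline(cohort, 13)
  expect_setequal(at13$patient_id, c("p2", "p3", "p4"))
  expect_equal(attr(at13, "n_missing_dose"), 1L)
  at70 <- filter_low_dose_amitriptyline(cohort, 70)
  expect_setequal(at70$patient_id, c("p3", "p4"))
  expect_error(filter_low_dose_amitriptyline(cohort, 0), "positive")
})
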