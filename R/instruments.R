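# Surrogate instruments from each physician's prescribing history: the
# most recent prior prescription, the comparator count over the previous
# three patients, and per-prescription indicators for the previous seven.

#' Specify a surrogate-instrument construction
#'
#' @param form `"most_recent"` (single binary instrument, depth 1),
#'   `"count"` (comparator count over the previous `depth` patients), or
#'   `"indicators"` (one binary column per prior prescription,
#'   most-recent-first).
#' @param depth Number of prior prescriptions used; `most_recent` requires
#'   exactly 1. The other forms allow any depth of at least 1 so that the
#'   depth-1 count coincides with the most-recent instrument.
#' @return An `prefiv_instrument_spec` list.
#' @export
instrument_spec <- function(form = c("most_recent", "count", "indicators"),
                            depth = 1L) {
  form <- match.arg(form)
  depth <- as.integer(depth)
  if (form == "most_recent" && depth != 1L) {
    stop("most_recent requires depth = 1")
  }
  if (depth < 1L) stop("depth must be at least 1")
  structure(list(form = form, depth = depth), class = "prefiv_instrument_spec")
}

#' Physician prescribing history for instrument construction
#'
#' One row per index prescription, ordered within physician by date then
#' patient id, with the comparator coding of the requested contrast
#' (TCA = 1, or paroxetine = 1 among SSRI prescriptions). Build this from
#' the pre-exclusion candidate table, so that prior patients later removed
#' by the exclusion cascade still contribute to their physician's history.
#' The current patient's own record never contributes to their instrument
#' (priors are strictly earlier rows of this table).
#'
#' @param candidates Candidate index table from
#'   [select_index_prescriptions()] (or any cohort carrying the same
#'   columns).
#' @param contrast Exposure contrast determining the comparator coding.
#' @return Tibble `physician_id`, `patient_id`, `index_date`,
#'   `comparator`.
#' @export
index_history <- function(candidates, contrast = c("tca-ssri", "parox-ssri")) {
  contrast <- match.arg(contrast)
  h <- candidates[!is.na(candidates$physician_id) &
                    candidates$prescriber_is_physician, ]
  if (contrast == "parox-ssri") {
    h <- h[h$drug_class == "SSRI", ]
    h$comparator <- as.integer(h$drug_name == "paroxetine")
  } else {
    h$comparator <- as.integer(h$drug_class == "TCA")
  }
  h %>%
    arrange(.data$physician_id, .data$index_date, .data$patient_id) %>%
    select("physician_id", "patient_id", "index_date", "comparator")
}

#' Attach surrogate-instrument columns to a cohort
#'
#' For each cohort row, locates the physician's previous `depth` index
#' prescriptions to distinct earlier patients (never the current patient's
#' own records, never anything dated on or after the row's index date given
#' the strict history ordering) and codes them with instrument = 1 denoting
#' the same drug as exposure = 1. Rows whose physician lacks `depth` prior
#' prescriptions are dropped and counted in the coverage report.
#'
#' Column naming: `Z1` (most recent), `Z_count3` (count of previous
#' `depth`), `Z_ind7_1..Z_ind7_depth` (indicators, most-recent-first).
#'
#' @param cohort Cohort rows (must carry `patient_id`, `physician_id`,
#'   `index_date`).
#' @param history History table from [index_history()]; defaults to the
#'   cohort itself when it carries the index-candidate columns. Pass the
#'   pre-exclusion candidate table so prior patients removed later by
#'   exclusions still contribute history.
#' @param spec An [instrument_spec()].
#' @param contrast Comparator coding used when `history` is derived
#'   internally.
#' @return List with `cohort` (instrument columns appended, short-history
#'   rows dropped) and `coverage` (n_before, n_after, dropped, pct).
#' @export
build_instrument <- function(cohort, history = NULL, spec = instrument_spec(),
                             contrast = c("tca-ssri", "parox-ssri")) {
  contrast <- match.arg(contrast)
  stopifnot(inherits(spec, "prefiv_instrument_spec"))
  if (is.null(history)) history <- index_history(cohort, contrast)
  d <- spec$depth
  ds <- diff(as.numeric(history$index_date))
  same <- history$physician_id[-1] == history$physician_id[-nrow(history)]
  if (nrow(history) > 1 && any(same & ds < 0)) {
    stop("physician history is not ordered by date", call. = FALSE)
  }
  h <- history %>% group_by(.data$physician_id)
  lags <- lapply(seq_len(d), function(k) {
    h %>% mutate(z = lag(.data$comparator, k)) %>% pull("z")
  })
  Zm <- do.call(cbind, lags)  # column k = k-th most recent prior
  key <- tibble::tibble(patient_id = history$patient_id)
  if (spec$form == "most_recent") {
    key$Z1 <- Zm[, 1]
  } else if (spec$form == "count") {
    key[[paste0("Z_count", d)]] <- rowSums(Zm)
  } else {
    colnames(Zm) <- paste0("Z_ind", d, "_", seq_len(d))
    key <- dplyr::bind_cols(key, tibble::as_tibble(Zm))
  }
  zcols <- setdiff(names(key), "patient_id")
  cohort <- cohort[, setdiff(names(cohort), zcols)]  # replace stale columns
  out <- left_join(cohort, key, by = "patient_id")
  ok <- stats::complete.cases(out[, zcols, drop = FALSE])
  res <- out[ok, ]
  list(cohort = res,
       coverage = instrument_coverage(nrow(cohort), nrow(res)))
}

#' Sample loss from requiring a prescribing history
#'
#' @param n_before,n_after Row counts before and after requiring the
#'   instrument's history depth (each physician's first few patients lack
#'   enough prior prescriptions). Tibbles are accepted and counted.
#' @return Tibble with `n_before`, `n_after`, `dropped` and `pct`
#'   (percentage of `n_before` lost).
#' @export
instrument_coverage <- function(n_before, n_after) {
  if (is.data.frame(n_before)) n_before <- nrow(n_before)
  if (is.data.frame(n_after)) n_after <- nrow(n_after)
  if (n_after > n_before) stop("n_after exceeds n_before")
  tibble::tibble(n_before = n_before, n_after = n_after,
                 dropped = n_before - n_after,
                 pct = 100 * (n_before - n_after) / n_before)
}
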