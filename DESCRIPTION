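Package: prefiv
Title: Physician Prescribing Preference Instrumental Variables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for preference-based instrumental variable analysis of
    physician-clustered prescribing data. Builds analysis cohorts from raw
    prescription, patient and outcome event tables; constructs surrogate
    instruments from each physician's prior prescriptions (most recent,
    count of the previous three, indicators for the previous seven);
    quantifies covariate balance by exposure and by instrument (adjusted
    risk differences, Mahalanobis distance, prevalence difference ratios);
    and estimates risk differences per 100 patients with cluster-robust
    two-stage least squares, physician fixed-effects IV, Durbin-Wu-Hausman
    and Lagrange multiplier specification tests, and propensity-score
    matching. Includes a synthetic-data generator with known latent
    physician preferences, unmeasured confounding and true treatment
    effect for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr,
    optparse
Config/testthat/edition: 3
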