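---
title: "Physician preference instruments for prescribing data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physician preference instruments for prescribing data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prefiv)
```

## The problem

Comparative studies of prescribed drugs in routine electronic health
records suffer from *confounding by indication*: the clinical reasons a
physician chooses drug A over drug B also predict the patient's outcome,
and many of those reasons (severity, frailty, suicidality) are unmeasured.
Conventional covariate adjustment cannot remove bias from what is not
recorded.

Preference-based instrumental variable (IV) analysis exploits a different
source of variation: physicians differ systematically in which drug class
they reach for, in ways that are largely unrelated to the individual
patient in front of them. The physician's *preference* is latent, but
their *prior prescriptions* are observable and proxy it — the surrogate
instrument. `prefiv` implements this methodology end to end for
antidepressant-style contrasts (a reference class vs. a comparator class,
and a single drug vs. the rest of its class): cohort construction from raw
prescription/patient/outcome tables, surrogate-instrument construction,
instrument-validity diagnostics, and cluster-robust effect estimation —
together with a synthetic-data generator with known latent structure, so
every estimator can be validated against ground truth.

## The estimators

All effects are risk differences per 100 patients, estimated by linear
probability models (least squares) rather than logistic regression, so
that estimates are collapsible and directly comparable across estimators.
Standard errors cluster on the prescribing physician with the sandwich
estimator and the finite-sample factor $\frac{G}{G-1}\cdot\frac{N-1}{N-k}$
(the convention of Stata's `cluster()`, which the field's published
analyses use); confidence intervals use $t_{G-1}$ quantiles.

* `ols_cluster()` — conventional adjusted regression.
* `tsls()` — two-stage least squares. The variance uses the *structural*
  residuals $y - x\hat\beta - W\hat\gamma$, never the second-stage
  plug-in residuals; this matters because the plug-in residuals understate
  error variance. With a single binary instrument and no controls, 2SLS
  equals the Wald ratio
  $\frac{E[Y|Z=1]-E[Y|Z=0]}{E[X|Z=1]-E[X|Z=0]}$, which `wald_ratio()`
  computes from conditional means and the tests use as a closed-form
  oracle (agreement to $10^{-10}$).
* `fe_tsls()` — 2SLS after within-physician demeaning, absorbing an
  indicator per physician. This probes the exclusion restriction: if
  physicians affect outcomes directly (not only through the drug choice),
  plain preference IV is biased while the within-physician estimator is
  not, because the preference no longer varies within physician.
* `ps_match_rd()` — propensity-score matching (logistic model, nearest
  control within a caliper of 0.01 on the score, with replacement), the
  conventional observed-confounding comparator. Matching is
  exposed-to-control, so the estimand is the effect among the exposed —
  an assumption the field's reports usually leave implicit.

Specification tests: `hausman_dwh()` implements the Durbin–Wu–Hausman
test in control-function form (append the first-stage residual to the
outcome regression and test its coefficient with the cluster-robust
variance) because the classical variance-difference statistic need not be
positive definite under clustering. `lm_added_instruments()` is the
$N R^2$ Lagrange-multiplier score test of whether deeper instruments
explain additional exposure variance. `first_stage_diagnostics()` reports
the cluster-robust partial $F$ and the partial $r^2$ of exposure and
instruments given controls.

## Surrogate instruments

`index_history()` orders each physician's *index* (first-time)
prescriptions by date, breaking same-date ties by patient id, and
`build_instrument()` derives, for each cohort row:

* `most_recent` (depth 1): the previous patient's drug, coded 1 when it is
  the same drug as exposure 1 — first-stage risk differences are then
  positive under preference persistence;
* `count` (depth $k$): comparator count over the previous $k$ patients;
* `indicators` (depth $k$): one binary column per prior prescription,
  most-recent-first.

History is patient-level, not event-level: repeat prescriptions to the
same patient never add information about preference. The current patient's
own records never contribute to their instrument, and nothing dated on or
after the row's index date can enter (tests verify this by brute-force
reconstruction). Rows whose physician lacks $k$ priors are dropped and
reported by `instrument_coverage()` — each physician's first few patients
are the price of deeper instruments. History should be built from the
*pre-exclusion* candidate table: a prior patient later excluded from the
cohort still reveals the physician's preference.

## Balance diagnostics

For each baseline covariate, `adjusted_risk_difference()` reports the
year-adjusted risk difference per 100 across exposure groups and across
instrument groups. The *prevalence difference ratio*
$\mathrm{pdr} = \frac{E[U|Z=1]-E[U|Z=0]}{E[U|X=1]-E[U|X=0]}$
compares the two: when $|\mathrm{pdr}|$ exceeds the first-stage strength
$E[X|Z=1]-E[X|Z=0]$, bias from that covariate may be *larger* in the IV
analysis than in the conventional one. Ratios whose exposure denominator
is below 0.1 per 100 are flagged unstable rather than reported — in this
regime published tables show wild values (hundreds of percent) that carry
no information. Whether the ratio is built from crude or year-adjusted
differences is a flag (`adjust_year`); adjusted is the default since
secular prescribing trends are strong and nonlinear, and year enters as
per-year indicator variables, not a linear term, for the same reason.

`mahalanobis_imbalance()` summarises total imbalance as
$100\sqrt{\Delta^\top S^{-1}\Delta}$ with $\Delta$ the difference of group
covariate-mean vectors and $S$ the pooled within-group covariance. This is
one of several variants in circulation; only the between-group distance
and the percent reduction
(`imbalance_reduction()` $=100(1-d_Z/d_X)$) are treated as reproducible
arithmetic — per-arm "distances" printed in some reports are not
reconstructible from a definition and are not attempted.

## The synthetic-data generator

`sim_config()` + `generate_population()` emulate physician-clustered
sequential prescribing:

* **Physician preference** is a random intercept on the log-odds scale,
  $\alpha_j \sim N(0, \texttt{preference\_sd}^2)$, optionally drifting
  linearly in calendar time (default drift 0: nothing in the field's
  published evidence constrains preference stability, so the simplest
  stationary process is the default). This is the simplest process that
  makes depth-$k$ instruments informative.
* **Patients** arrive at uniform dates over the calendar window
  (1995-01-01 to 2010-06-30 by default, the usual linked-records era),
  ordered within physician, ties broken by patient id — instrument
  construction needs a total order.
* **Covariates**: twelve binary indicators with configurable prevalences
  (defaults emulate the reference arm of a UK primary-care antidepressant
  cohort, e.g. 51% aged over 40, 62% prior depression diagnosis, 0.3%
  hospitalised in the prior year), plus BMI (missing for 20% of patients)
  and demographics consistent with the indicators. A physician-level
  shift of SD `casemix_sd` on every covariate's log-odds induces the
  small instrument–covariate associations seen in real data: case mix
  clusters within physicians, so prior prescriptions pick up a little of
  it. With `casemix_sd = 0` covariates are independent of physicians and
  the instrument balances exactly.
* **Drug choice** is Bernoulli with log-odds = intercept + preference +
  covariate effects + `confounder_effect_rx`·U + trend, where
  $U \sim \text{Bernoulli}(0.5)$ is the unmeasured confounder — binary so
  that omitted-variable-bias algebra stays closed-form in tests.
* **Outcome** (self-harm admission or suicide death within 3 months of
  the index date) follows a *clipped linear* risk model
  $p = \text{baseline} + \tau X/100 + \beta_U U/100$, so the configured
  $\tau$ *is* the risk-difference estimand, exactly — matching the
  least-squares estimators. The generator aborts if clipping touches more
  than 1% of patients, since then the configuration contradicts the
  linear risk scale. A `preference_effect_y` knob adds a direct
  preference→outcome path (an exclusion-restriction violation) for
  stress-testing `fe_tsls()`.

What the generator deliberately does **not** emulate: real dosing
titration and repeat-prescription streams, clinical code lists, realistic
antidepressant market shares over time, practice-level linkage mechanics,
or correlation structure among covariates beyond the shared physician
shift. Passing recovery tests therefore demonstrates that the estimators
are correct *for this class of data-generating process* — physician
random intercepts, a binary confounder, a linear risk scale — not that any
particular real-world analysis is unconfounded.

`make_messy_fixture()` starts from a population that passes every
exclusion rule (warm-up prescriptions to non-cohort patients give each
physician enough history for the prior-count rule from patient one) and
injects an exact number of violations per rule, each on a distinct
patient, spread round-robin across physicians so that perturbations
removing a record from one physician's history can never push an
untargeted patient below the prior-count threshold. The attrition log is
then exactly predictable, which is what the cohort-builder tests assert.

## Cohort construction choices

The exclusion cascade applies, in order: index within 12 months of
registration (365 days); index outside the calendar window; prescriber
not a physician; missing physician id; age under 10 at index (index year
minus birth year — year precision is all such records carry); missing
birth year; physician with fewer than 10 prior prescriptions; then
contrast-specific rules. A row violating several rules is charged to the
first; permuting the order (exposed as `rule_order`) changes per-rule
counts but never final membership, and the cascade is idempotent.

Boundary contracts, all chosen once and tested: "3 months" is 91 days,
configurable; the outcome window is left-open/right-closed — an event on
the index date itself is plausibly the indication rather than a
consequence, so day 0 never counts and day 91 does; BMI outside (15, 100)
is treated as a data error and set missing, the boundary values retained,
with the BMI>25 indicator recomputed from in-range values only; same-date
index ties break by drug class, drug name, then record id; low-dose
amitriptyline filtering (13 mg / 70 mg sensitivity thresholds — such doses
are typically for neuropathic pain, not depression) retains missing doses
and logs them.

## Numerical choices

Design matrices are factored by (unpivoted where full-rank) QR;
rank deficiency is an error naming the offending column, except in the
LM test's auxiliary projection, where `qr.fitted` tolerates deliberately
duplicated instruments. Control blocks are pruned of columns left
constant or aliased after row subsetting (a reference-year cell can
vanish when missing-BMI rows are dropped). Propensity matches break
equidistant ties toward the lower control index; matching is with
replacement, and reused controls enter the variance with frequency
weights. The multi-instrument estimator is plain 2SLS — no LIML/GMM — as
in the field's standard software defaults.

## Problem sizes used in validation

The package's own validation experiments (tests and
`scripts/acceptance.R`) use: 200 generator replicates of 500 physicians ×
100 patients for parameter recovery under unmeasured confounding
(τ = −10 per 100, confounder effects 50 per 100 on outcome and 1.5
log-odds on prescription; baseline risk 0.30 so the linear risk model
never clips); 500 replicates of 150 × 30 for specification-test
calibration; 1,000 random datasets of n ≤ 50 for the 2SLS/Wald oracle;
and a 150 × 80 rare-outcome configuration (baseline 0.15 per 100) for the
omitted-variable-bias identity. These sizes give Monte-Carlo standard
errors small enough to detect the biases of interest while keeping the
default validation run desk-sized.

## Known limitations

* Instruments identify effects in the preference-sensitive (complier)
  population under monotonicity; nothing here tests that untestable
  assumption.
* The generator's confounder is a single binary variable; continuous or
  multivariate unmeasured confounding is not simulated.
* Weak-instrument inference beyond the partial-F-below-10 warning
  (e.g. Anderson–Rubin intervals) is out of scope.
* The propensity-score variance treats matched controls via frequency
  weights; it does not implement full matching-uncertainty corrections.
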