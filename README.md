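# prefiv

Preference-based instrumental variable analysis for physician-clustered
prescribing data.

## The problem

Observational comparisons of prescribed drugs — say, tricyclic
antidepressants (TCAs) vs. selective serotonin reuptake inhibitors
(SSRIs) and a rare outcome like self-harm admission or suicide within
3 months of first prescription — are confounded by indication: the
clinical picture that drives the prescribing choice also predicts the
outcome, and much of it is unmeasured. Physicians, however, differ in
which drug they habitually reach for. That latent *prescribing
preference* U\* is associated with which drug a patient receives, but not
with the individual patient's characteristics, which makes it an
instrumental variable; the physician's **prior prescriptions** Z proxy it
as a *surrogate instrument*.

With exposure X, outcome Y, and a single binary instrument, the IV
estimand is the Wald ratio

    RD_IV = ( E[Y|Z=1] − E[Y|Z=0] ) / ( E[X|Z=1] − E[X|Z=0] )

estimated in practice by two-stage least squares with standard errors
clustered on the physician. `prefiv` implements the full workflow:

* **Cohort construction** from raw prescription / patient / outcome-event
  tables: index-prescription selection, a seven-rule exclusion cascade
  with an exact attrition log, exposure coding for two contrasts
  (TCA vs. SSRI; paroxetine vs. other SSRIs), outcome attachment in a
  91-day window, BMI-plausibility and low-dose-amitriptyline filters.
* **Surrogate instruments** from each physician's history: most recent
  prior prescription (`Z1`), count over the previous three patients,
  indicator variables for the previous seven.
* **Validity diagnostics**: cluster-robust first-stage partial *F* and
  partial *r²*; covariate risk differences per 100 by exposure and by
  instrument; prevalence difference ratios with the relative-bias rule;
  Mahalanobis imbalance and its percent reduction; joint *F*-tests for
  multi-instrument sets; Durbin–Wu–Hausman and Lagrange-multiplier
  specification tests.
* **Estimators**: cluster-robust OLS, 2SLS (single and multiple
  instruments), physician fixed-effects 2SLS, propensity-score matching —
  all reported as risk differences per 100 patients.
* **A synthetic-data generator** with known latent structure (physician
  preferences, an unmeasured confounder, the true effect), so every
  estimator is validated against ground truth, plus a messy-fixture
  builder that injects exact numbers of rule violations.

## Worked example

Simulate a confounded prescribing population (true effect τ = −10 per
100; an unmeasured confounder raises both TCA prescribing and outcome
risk; age, prior prescribing burden, depression history and smoking also
drive drug choice), build the cohort and instruments, and compare
estimators:

```r
library(prefiv)

cfg <- sim_config(
  n_physicians = 200, patients_per_physician = 60,
  preference_sd = 1, treatment_effect = -10,
  confounder_effect_y = 50, confounder_effect_rx = 1.5,
  covariate_effects_rx = c(age_over_40 = 0.9, rx_over_5_prior_year = 0.9,
                           prior_depression = -0.8, ever_smoked = -0.6),
  seed = 42)

sc <- simulate_cohort(cfg, depths = c(1, 7))
ch <- sc$cohort                      # 9,999 rows, 200 physicians
W  <- year_dummies(ch$index_year)
Z1 <- matrix(ch$Z1, dimnames = list(NULL, "Z1"))

first_stage_diagnostics(ch$X, Z1, W, ch$physician_id)
#> first stage: RD 10.89 per 100, partial F 53, partial r2 0.012

ols_cluster(ch$Y, ch$X, W, ch$physician_id)
tsls(ch$Y, ch$X, Z1, W, ch$physician_id)$estimate
tsls(ch$Y, ch$X, as.matrix(ch[, paste0("Z_ind7_", 1:7)]), W, ch$physician_id)$estimate
#>   estimator rd_per_100   se ci_low ci_high    n n_clusters
#> 1       ols       4.95 1.03   2.91    6.99 9999        200
#> 2      tsls     -22.02 9.51 -40.78   -3.25 9999        200
#> 3      tsls     -18.38 4.84 -27.92   -8.85 9999        200
```

Conventional regression is pushed to the *wrong sign* (+4.95) by the
unmeasured confounder; the IV estimates recover the protective effect
(their intervals cover −10), and the depth-7 instrument is roughly twice
as precise as depth 1. The endogeneity test flags the discrepancy:

```r
hausman_dwh(ch$Y, ch$X, Z1, W, ch$physician_id)
#> DWH statistic 8.5, p = 0.004
```

and the balance diagnostics show why the instrument is credible — the
covariates that drive prescribing are 10–20 points imbalanced across
actual prescriptions but about 1 point across prior prescriptions, a
Mahalanobis reduction of 86%, with every prevalence difference ratio
below the first-stage strength (0.109):

```r
bt <- balance_table(ch)
bt$rows[, c("covariate", "rd_exposure", "rd_instrument", "pdr", "pdr_flag")]
#>          covariate rd_exposure rd_instrument    pdr pdr_flag
#>        age_over_40          16          1.12  0.072    FALSE
#>        ever_smoked         -11          0.68 -0.059    FALSE
#>   prior_depression         -14          0.19 -0.014    FALSE
#>   ...
bt$summary
#>   d_exposure d_instrument reduction_pct first_stage_strength
#> 1       61.3         8.73          85.8                0.109
```

`run_pipeline(pipeline_config(...))` runs the same workflow end to end
and writes a reproducible report bundle (attrition log, balance tables,
first-stage table, estimate table, machine-readable summary, manifest);
`inst/cli/prefiv.R` exposes it from the shell with `simulate`, `fixture`,
`report` and `all` subcommands.

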