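# glp1traj

Weight trajectories after the **last** semaglutide or tirzepatide
prescription, from raw EHR-style extracts.

GLP-1 receptor agonists produce large weight losses on therapy, and
randomized withdrawal trials show substantial regain after protocolized
discontinuation. In routine care the observable anchor is different: the
last prescription a provider recorded. glp1traj implements the full
analysis pipeline around that real-world index event, for
pharmacoepidemiologists working with prescription, weight, demographic and
clinical-note-event tables:

* **Cohort phenotyping** from prescription timelines: a persistence run of
  ≥ 3 prescriptions of one drug, successive gaps ≤ 120 d, span ≤ 365 d,
  followed by a prescription-free washout ≥ 180 d. The *index date* is the
  earliest prescription followed by a clear washout; every excluded patient
  gets a reason code in a rejection ledger.
* **Baseline and trajectories**: baseline = weight closest to the index
  within ±90 d; every weight in −365…+180 d becomes a percent change
  100 × (w − w₀)/w₀, grouped into 30-day bins.
* **Two-stage aggregation**: per patient per bin the *median* percent
  change, then cohort mean and sample SD over patients, with
  mean ± 1.96 × SD/√n confidence intervals — so frequently measured
  patients do not dominate the curve.
* **Regain classification**: label *regain* iff any post-index measurement
  in the 6-month window is ≥ 2% above baseline; the endpoint (closest to
  day 180) change is kept separately for the follow-up histogram.
* **Maintenance-dose attainment** per brand (Ozempic 0.5, Wegovy 1.7,
  Rybelsus 7, Mounjaro 5, Zepbound 5 mg) in the pre-index year.
* **Note-event rollups** to patient-level indicators (documented
  discontinuation ±90 d, restart/switch > 60 d post, counseling, …) and
  **Pearson chi-square** (2×2, no continuity correction) comparisons of
  counseling documentation between outcome groups.
* A **seeded synthetic-EHR generator** reproducing the statistical
  structure the pipeline assumes (on-therapy loss ~7%/~11%, regain ramp to
  +4% by day 120, irregular visits, measurement noise, group-specific
  counseling rates), so everything is testable without protected data.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` methods, `autoplot()` figures.

## Worked example

```r
library(glp1traj)

res <- run_weight_study(sim_config(n_patients = 500), seed = 7)
res
#> <glp1_study> 453 accepted patients (47 rejected)
#> # A tibble: 1 × 14
#>   n_semaglutide n_tirzepatide regain_pct_semaglutide regain_pct_tirzepatide
#>           <int>         <int>                  <dbl>                  <dbl>
#> 1           284           169                   38.7                   30.8
#> # i 10 more variables: followup_mean_pct <dbl>, ...

table(cohort_ledger(res$cohort)$reason)
#>           accepted       gap_too_wide no_followup_weight         too_few_rx
#>                453                 20                 17                 10

res$maintenance
#> # A tibble: 2 × 4
#>   drug            n n_attained rate_pct
#> 1 semaglutide   284        261     91.9
#> 2 tirzepatide   169        155     91.7

res$comparisons
#>   counseling n_non_regain n_regain pct_non_regain pct_regain statistic p_value
#> 1   exercise          291      162           23.4       13.0      7.14  0.0076
#> 2       diet          291      162           19.9       22.2      0.33  0.56

autoplot(res$bins_by_group)   # trajectory curves, regain vs non-regain
autoplot(res$histogram)       # follow-up weight-change distribution
```

Reading the numbers: of 500 generated patients, 47 are rejected with the
first failing eligibility rule recorded; about 39%/31% of accepted
semaglutide/tirzepatide patients are classified as regainers (the
classifier takes a maximum over noisy measurements, so this runs a few
points above the latent 33%/28% at the default 0.8 kg noise); ~92% attained
a maintenance dose in the pre-index year; exercise counseling is documented
more often in the non-regain group (23.4% vs 13.0%, p ≈ 0.008) while diet
counseling does not differ.

Individual stages are plain functions you can chain on your own tables:
`read_ehr_table()` → `build_cohort()` → `patient_trajectories()` →
`aggregate_bins()` / `classify_regain()` → `maintenance_rate()`,
`summarize_notes()`, `table2_summary()`, `counseling_comparison()`,
`table1_summary()`, `followup_histogram()`.

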