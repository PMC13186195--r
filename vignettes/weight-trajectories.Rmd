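---
title: "Weight trajectories after the last GLP-1RA prescription: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weight trajectories after the last GLP-1RA prescription: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glp1traj)
library(dplyr)
```

## The question and the design

Semaglutide and tirzepatide produce large weight losses while prescribed,
and randomized withdrawal studies show substantial regain after protocolized
discontinuation. In routine care, though, the observable event is not
"discontinuation" but the *last prescription recorded in the EHR* — a
real-world index event shaped by pharmacology, access, adherence and
documentation. glp1traj implements a retrospective cohort design anchored on
that event:

1. **Cohort construction.** A patient qualifies if they have a persistence
   run of at least three prescriptions of one study drug, successive gaps at
   most 120 days, first-to-last span at most 365 days, inside the study
   period — followed by a washout of at least 180 days with no study-drug
   prescription. Patients with prescriptions for both drugs are excluded as
   switchers. The **index date** is the earliest prescription followed by a
   clear washout.
2. **Baseline.** The weight measurement closest to the index date within
   ±90 days (ties resolve to the earlier measurement). Patients without a
   baseline, or without any other post-index weight inside the 180-day
   follow-up window, are rejected with distinct reason codes.
3. **Trajectories.** Every weight in `[-365, +180]` days becomes a percent
   change from baseline; points are grouped into 30-day bins.
4. **Outcome groups.** A patient is labelled *regain* when any post-index
   measurement within the follow-up window is at least 2% above baseline
   (boundary inclusive); otherwise *non-regain*.
5. **Context.** Maintenance-dose attainment in the pre-index year, note-event
   rollups, and chi-square comparisons of counseling documentation between
   outcome groups.

All windows and thresholds live in `study_config()`; months are
operationalized as round day counts (4 months = 120 d, 6 months = 180 d,
12 months = 365 d), every date is handled in whole days, and files use ISO
8601 dates in plain CSV.

## Eligibility and index-date semantics

A few points of the eligibility algorithm were genuinely open and are fixed
here as package policy:

* **Gap vs span.** "At most 4 months apart" applies to successive gaps
  *within* the qualifying run; "within a 1-year period" bounds the run's
  first-to-last span. The run must be consecutive in the patient's
  (deduplicated) timeline.
* **Earliest qualifying gap.** The index is the *earliest* prescription, at
  or after the end of some qualifying run, that is followed by a clear
  washout — not the chronologically last prescription in the extract. A
  patient who restarts more than six months later therefore indexes at the
  end of the first episode; the later episode is ignored. The alternative
  (always the last prescription) would contradict the requirement that the
  washout exist at the index.
* **Half-open washout.** A prescription dated exactly `washout_days` after a
  candidate breaks the washout, reading "at least 6 months without" inclusively.
* **Washout sees all prescriptions.** Qualifying runs and index dates are
  restricted to the study period, but any study-drug prescription — even one
  dated outside the period — breaks a washout, since it is evidence of
  continued therapy.
* **Duplicates.** Same-day prescriptions collapse to one timeline event, so
  refills and corrections cannot create zero-length gaps.
* **Baseline must leave a follow-up point.** The baseline measurement never
  doubles as the post-index measurement for classification (even when it is
  dated after the index), so cohort construction requires at least one
  *other* post-index weight. This keeps `classify_regain()` total over the
  accepted cohort.

The implementation (segment-splitting on over-wide gaps, then a vectorized
span check) is tested against a brute-force oracle that enumerates every
window of three consecutive prescriptions and every candidate index date
directly from the rule text, over thousands of random timelines.

## Two-stage aggregation and intervals

Visit frequency varies enormously across patients, so naive pooling would
let frequently measured patients dominate the cohort curve. Within each
30-day bin each patient first contributes a single value — the *median* of
their in-bin percent changes (midpoint convention for even counts) — and
cohort statistics are then the mean and sample SD (n − 1) over those
patient-level values, with `mean ± 1.96 × SD/√n` intervals. Bins with a
single patient report SD 0 and a degenerate interval; empty bins are
omitted. The package uses the sample SD throughout; with bin sizes in the
hundreds the distinction from the population SD is immaterial, but it keeps
the SEM conventional.

Two regain-related statistics are deliberately separate:

* `classify_regain()` labels on the **maximum** post-index percent change —
  "at least 2% increase in the six months following" can be satisfied at any
  point in the window, and regain-group trajectories typically peak before
  month six.
* `followup_change()` is the **endpoint** statistic (baseline to the
  measurement closest to day 180), the quantity summarized by
  `followup_histogram()`.

## The synthetic-EHR generator

Real prescription/weight extracts of this kind cannot be shared, so the
package ships a seeded generator (`simulate_ehr()`) whose defaults encode
the study conditions the analysis assumes:

* therapy for 365 days with a prescription every 28 days, ending at the true
  index date, with no prescriptions afterwards;
* on-therapy weight loss of 7% (semaglutide) and 11% (tirzepatide) over the
  pre-index year, linear in time, from a starting weight drawn per drug
  (mean 103.3/108.5 kg, SD 22.6/22.8 kg);
* a latent regain outcome per patient (probability 0.33 semaglutide, 0.28
  tirzepatide): regainers ramp linearly to +4% of baseline by post-index day
  120 and plateau; non-regainers drift uniformly between −2% and +1% per
  180 days, giving the mild terminal upturn seen in non-regain cohorts;
* irregular visits (gaps uniform on 0.5–1.5 × 45 days) and Gaussian
  measurement noise (SD 0.8 kg — a generator choice, not an observed value;
  no published estimate of within-patient weight-measurement noise was
  available);
* dose titration reaching the brand's maintenance threshold with probability
  0.906/0.953 per drug; note events with exercise-counseling probability
  0.262 (non-regain) vs 0.147 (regain), diet 0.223 vs 0.235, documented
  discontinuation 0.40 within ±90 days of the index, and the remaining
  event types at their observed overall frequencies;
* a 10% contamination fraction of deliberately ineligible patients (too few
  prescriptions, over-wide gaps, or no post-index weights) to exercise the
  rejection ledger, and an optional per-patient backward date shift of 1–31
  days emulating de-identification jitter (which preserves all
  within-patient intervals, hence every analysis output).

The piecewise-linear latent model is the simplest trajectory consistent
with every summary the analysis produces; it has no autocorrelated noise,
no informative dropout, no comorbidity structure and no outside-source
medication exposure, so passing tests demonstrate the *pipeline's*
correctness under the stated conditions, not robustness to those real-data
complications.

One behaviour is intended and worth noting: the classifier takes a maximum
over noisy post-index measurements, so measurement noise inflates the
classified regain fraction above the latent rate (a non-regainer needs only
one noisy excursion past +2%). At noise SD ≤ 0.5 kg the classified fraction
recovers the latent probability within three binomial standard errors at
n = 1000 (tested); at the default 0.8 kg the classified fractions run a few
percentage points above the latent 33%/28%. With zero noise, classification
recovers the truth table exactly, because the +4% regain ramp clears the 2%
threshold and the non-regain drift (≤ +1%) never does.

## Numerical and statistical choices

* **Chi-square.** The 2×2 comparison uses the closed-form Pearson statistic
  `N(ad − bc)²/((a+b)(c+d)(a+c)(b+d))` with df = 1 and no continuity
  correction (a Yates flag exists); zero margins raise a named error rather
  than returning NaN. The implementation is cross-checked against the
  expected-counts formula and `stats::chisq.test()` and holds its nominal
  type-I error (empirically within [0.03, 0.07] at α = .05) under a
  simulated null. Raw two-sided p-values are reported with no
  multiple-testing adjustment across the two counseling comparisons.
* **Quantiles.** Cohort-summary quartiles use the inverse-ECDF convention
  (`quantile(type = 2)`), so the quartiles of a tiny cohort are attained
  data values.
* **Ties.** Baseline selection ties (equal distance before/after the index)
  resolve to the earlier measurement; the follow-up endpoint resolves
  toward the earlier date.
* **Table-1-style weight anchor.** The characteristics table anchors weight
  at the earliest measurement 270–365 days before the index (≈ 12 months
  before the last prescription) when available, falling back to the
  earliest in-window measurement; the ±90-day baseline is used everywhere
  else. These are different anchors on purpose: one describes the cohort at
  therapy start, the other normalizes trajectories.
* **Note windows.** Events are considered within an index ± 365-day horizon.
  Discontinuation documentation counts within ±90 days; restart/switch
  strictly more than 60 days post-index; the follow-up indicators (outside
  source, other anti-obesity medication, weight status, counseling) count
  strictly post-index up to the horizon rather than the 180-day weight
  window, because the note summary describes documentation "after the last
  prescription" without a six-month bound. All three windows are
  configurable.
* **Counseling denominators.** Group percentages use all patients in the
  outcome group, not only those with post-period notes.

## Problem sizes

The bundled tests run the generator at 10–500 patients for unit and
property checks, 1000 patients for label-recovery and 2000 for the
end-to-end run; the oracle-equivalence property uses 1000 random timelines
of up to eight prescriptions. These sizes give stable binomial checks (3-SE
bands of a few percentage points) while keeping the whole suite under a
minute on a single core.

## A worked run

```{r run}
res <- run_weight_study(sim_config(n_patients = 500), seed = 7)
glance(res) |> t()
head(cohort_ledger(res$cohort))
```

```{r plot, fig.width = 7, fig.height = 4}
autoplot(res$bins_by_group)
autoplot(res$histogram)
```

## Known limitations

* The eligibility semantics encode one defensible reading of
  "last prescription" (earliest qualifying gap); extracts in which
  re-initiation episodes should re-anchor the index need a different rule.
* The generator's latent model is not a substitute for real EHR data: it
  cannot detect biases from informative visit timing, documentation
  completeness, or outside-source medication use.
* The switcher exclusion covers the two study drugs only; other GLP-1RA
  ingredients are assumed excluded upstream.
* Brand-specific maintenance thresholds mean prescriptions with unknown
  brand can never attain maintenance; cohorts with poor brand capture will
  see attenuated attainment rates (the count of unscoreable prescriptions
  is attached to `maintenance_attainment()` output).
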