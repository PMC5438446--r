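---
title: "Methods: simulating and analyzing a COPD telemonitoring trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing a COPD telemonitoring trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telecopd)
```

## The problem

Digital home monitoring of chronic obstructive pulmonary disease (COPD)
rests on a simple premise: patients record a short symptom diary and pulse
oximetry every day, and a clinical team reviews the stream for signs of
deterioration. Evaluating such a system requires three distinct pieces of
computation, all implemented here:

1. **Personalized alerting.** COPD patients differ widely in their usual
   oxygen saturation, heart rate and symptom burden, so fixed alarm limits
   either miss deterioration in some patients or drown the clinic in false
   alarms for others. The remedy is to calibrate thresholds per patient
   from an initial *run-in* period of their own data.
2. **Outcome classification.** Exacerbations — acute worsenings of
   respiratory symptoms — are the clinically meaningful events, and the
   trial community uses a composite case definition combining treated
   health-care episodes, symptom criteria, and sustained reliever-inhaler
   use.
3. **Trial analysis.** The intervention's effect is judged in a
   randomized comparison on disease-specific quality of life (SGRQ-C),
   generic health status (EQ-5D), admissions, exacerbation rates and
   health-care use.

Because no patient-level data from such trials are publicly deposited, the
package pairs the analysis machinery with a synthetic cohort generator
whose defaults encode the design and published summary statistics of a
12-month, 2:1-randomized telemonitoring trial (166 patients; baseline age
69.8 (SD 9.1) years, SGRQ-C 56.4 (SD 19.7); SGRQ-C difference −1.7 points
at 12 months; EQ-5D change difference 0.076; admission relative risk
0.83). These published estimates serve as *simulator truths*: the test
suite checks that the analysis functions recover them, with correct
confidence-interval coverage and type-I error, from cohorts generated at
the trial's own size.

## The alerting engine

For each patient the run-in (default 42 days) supplies empirical
distributions of daily heart rate, composite symptom score, and SpO2.
Thresholds are the **97th centile** for heart rate and symptom score and
the **3rd centile** for SpO2.

Numerical choices, made once and pinned by oracle tests:

* **Centile estimator.** Nearest-rank: the `ceiling(p·n)`-th smallest of
  the `n` completed run-in values, no interpolation. With daily ordinal
  symptom scores and 42-point samples, interpolated quantiles would
  produce thresholds that no observable value can equal; nearest rank
  keeps thresholds on the observable grid. The convention is configurable
  through the centile arguments.
* **Strict crossing.** An alert requires the observation to be strictly
  above (below for SpO2) the threshold. A value *equal* to the 97th
  centile was, by construction, seen during the run-in and is not evidence
  of change.
* **Minimum data.** Thresholds are undefined below 14 completed run-in
  days (configurable). A centile estimated from a handful of days is
  dominated by noise; an undefined-threshold outcome (never an exception)
  lets the caller decide between waiting and a manual override.
* **Persistence.** A *clinically important change* is the same parameter
  alerting on ≥ 2 **consecutive observed** days. A missing day breaks the
  run: persistence cannot be asserted across days with no data.
* **Review queue.** Patients are ranked by the number of alerts in the
  trailing 14 days. A patient transmitting no data in the window is itself
  a review trigger; such patients rank immediately above transmitting
  patients with the same alert count, and ties break by ascending patient
  id so the queue is reproducible.
* **Overrides.** Threshold revisions (e.g. after an admission) produce a
  new threshold set with provenance `manual_override` and an
  `effective_from` day; alert generation applies whichever set is in force
  each day.

## The exacerbation case definition

An exacerbation is recorded when a treated care event (antibiotics or oral
steroids prescribed, A&E attendance, or admission) occurs together with an
acute symptom change — **at least two symptoms, at least one major**
(major: change in sputum, more breathlessness, chest tightness; minor:
feeling unwell, tiredness, raised temperature, a cold) — or when reliever
(salbutamol) use exceeds the patient's baseline for **at least 48 hours**.

Operationalizations where the definition is silent:

* The qualifying symptom report may fall within ±7 days of the care event
  (`symptom_window`); treated episodes and diary reports are rarely
  same-day in practice.
* 48 h maps to ≥ 2 consecutive completed diary days; "more salbutamol"
  means strictly above the patient's completed run-in **median** daily use.
* Distinct events must start ≥ 14 days apart (`washout`); candidate
  triggers inside the washout of an accepted event are absorbed into it,
  with a care-event trigger preferred at equal start days. This also
  answers whether an A&E visit followed by an admission is one episode:
  within the washout, it is.

One behavior worth knowing: with integer puffs and day-to-day reliever
noise, the strictly-above-median rule fires readily — two consecutive
noisy days above the median suffice. Event counts from the rule are
therefore sensitive to the simulator's `salbutamol_noise_sd`, which is a
faithful property of the rule rather than an artifact.

## The synthetic cohort generator

The generator's defaults are the study conditions, not tuning knobs:
2:1 allocation (166 patients split exactly 110/56 — the intervention arm
takes `floor(2n/3)`, the control arm the remainder), 365-day follow-up,
42-day run-in, covariate distributions matching the published baseline
table, and outcome effects equal to the published estimates. Variance
parameters for follow-up SGRQ-C (patient random intercept SD 10, residual
SD 11, baseline slope 0.7) were chosen so that the 12-month contrast's
confidence interval at n = 166 has a half-width of about 5 points,
consistent with the reported interval. Mean daily missingness of 0.15
corresponds to system use on about 5.95 days/week, matching the reported
compliance of 5.9 days/week; a Beta-distributed per-patient missingness
probability (SD 0.12) reproduces its between-patient spread.

Exacerbation episodes follow a linear onset ramp (3 days), a full-depth
plateau (7 days), and a linear recovery (7 days); at full depth the
deviations are +4 symptom-score points, +12 bpm, −4 SpO2 points and +2
puffs/day. Episodes arise from a Poisson process (1.5/patient-year in
control, rate ratio 1.2 in the intervention arm, where closer monitoring
detects more treated episodes) thinned to enforce separation. Deaths
(5.5%) and withdrawals (7%) censor daily and outcome data from a uniform
event day.

Reproducibility: every patient draws from a substream seeded
deterministically by `(seed, patient_id, purpose)`, so cohorts are
byte-identical across runs and a patient's data are invariant to cohort
size and to skipping the daily series (`include_daily = FALSE`).

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: informative missingness (sicker patients
skipping entries), autocorrelated physiology beyond episode ramps,
seasonal structure, measurement artifacts from the oximeter, admissions
causally linked to the latent episode process (the admission indicator is
an arm-specific Bernoulli with the configured relative risk, independent
of the episode draws), and learning effects in diary completion.

## The trial analysis

* **Primary outcome.** A linear mixed-effects model for SGRQ-C at 6 and
  12 months: fixed effects for randomized group, time point, baseline
  SGRQ-C, age (continuous), sex, current smoking, severity (moderate vs
  severe/very severe) and site; a group-by-time interaction; a
  patient-specific random intercept. The 12-month contrast is the sum of
  the group main effect and the interaction; inference uses Satterthwaite
  degrees of freedom (via `lmerTest`). Missing follow-up scores are
  handled by the likelihood, with no imputation. Covariates that are
  constant in the supplied data (a single site, a single-severity
  stratum) are dropped automatically, which also makes the single-stratum
  subgroup fit reduce exactly to the primary model.
* **Binary outcomes.** Log-binomial regression with the same adjustment
  set, reporting an adjusted relative risk with a Wald interval. The
  p-value for the treatment term is a likelihood-ratio test: with eight
  nuisance parameters against roughly sixty events, the Wald test is
  measurably anticonservative at this sample size while the
  likelihood-ratio test stays close to nominal. The log link is fragile
  when fitted risks approach 1; on non-convergence the function falls back
  to a modified Poisson model with robust (HC0 sandwich) variance and
  flags the result. With no covariates the log-binomial MLE equals the
  contingency-table risk ratio, which the suite checks to 1e-10.
* **Count outcomes.** Negative-binomial regression (log link) with
  `log(follow-up/365)` as offset, so the treatment coefficient is an
  incidence rate ratio; Poisson is available and is the automatic fallback
  when the negative-binomial fit degenerates.
* **Contacts.** Per-arm medians and IQRs with a two-sample Wilcoxon
  rank-sum test (normal approximation, appropriate under heavy ties).
* **Subgroups.** Stratum-specific refits of the primary model plus a
  1-df likelihood-ratio test for a group-by-subgroup interaction added to
  the ML-refitted model. Empty or unfittable strata are skipped with a
  warning.
* **No multiplicity adjustment** is applied across secondary outcomes,
  matching the analysis plan the models come from.

### Sample size

The calculator solves the two-sample comparison of means with unequal
allocation `r:1`. With `method = "t"` it takes the smallest integer
control-arm size whose noncentral-t power reaches the target (intervention
arm = `ceiling(r · n_c)`), then inflates for loss to follow-up by dividing
the **control** arm by `1 − loss` (rounding up) and setting the
intervention arm to `r` times the inflated control arm. Inflating the
control arm and rescaling keeps the allocation ratio exact in the
recruited total, which is how recruitment targets are actually set for a
ratio-randomized trial; inflating each arm separately can produce totals
(e.g. 164 here) that no 2:1 randomization can realize. Under the design
inputs (δ = 7.3 SGRQ-C points, σ = 12.7, 90% power, α = 0.05 two-sided,
2:1, 10% loss) this gives 49 + 98 analysed, 55 + 110 = **165** recruited.
The normal-approximation method exists to compare against the closed form
`n_c = (1 + 1/r)σ²(z₁₋α/₂ + z₁₋β)²/δ²`.

### Compliance and costs

Compliance is `7 × (completed days) / (days in study)` per patient, with
the engagement flag requiring ≥ 30 days in study and an average of ≥ 3
use-days per week. Costs apply fixed unit prices: tablet £319 and oximeter
£399 (intervention arm only), £2900 per admission, £36 per GP visit, £11
per practice-nurse visit.

## Problem sizes used in the checks

The simulation-based checks run at the trial's own scale, n = 166 per
cohort: 200 replicate cohorts for parameter recovery and CI coverage
(Monte-Carlo standard errors of about 0.2 SGRQ-C points, 0.002 EQ-5D
units, and 1.5 coverage points), 500 replicates for type-I error (99%
binomial band 2.5–7.5% around the nominal 5%), 1000 random series of up
to 400 days for the brute-force oracle equivalences, and a 10,000-patient
cohort for the covariate-calibration check. The acceptance script uses
150 recovery and 300 null replicates, reporting the same quantities.

## Known limitations

* The admission indicator is not mechanistically coupled to the latent
  episode process; joint modelling of admissions within exacerbations is
  out of scope.
* EQ-5D is treated as a generic index change in [−0.6, 1]; no value-set
  tariff mapping is implemented.
* Time-to-first-exacerbation is summarized descriptively (earliest event
  or censoring), not modelled with a hazard regression.
* The review queue models a single review stream; clinic-level batching
  across multiple nurses is not represented.
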