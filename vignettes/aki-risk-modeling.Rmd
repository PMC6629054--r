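---
title: "Methods: real-time AKI risk modeling on inpatient time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: real-time AKI risk modeling on inpatient time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`akiward` implements a complete, testable pipeline for predicting
hospital-acquired acute kidney injury (AKI) in real time from ordinary EHR
event streams. This vignette is the package's own account of the methods:
the clinical definitions it operationalizes, the statistical model, the
synthetic data generator used to validate everything, and the numerical and
design decisions a maintainer should know about.

## 1. Clinical definitions and their operationalization

AKI is detected from the inpatient serum-creatinine series alone, using the
KDIGO creatinine criteria: an absolute rise of at least 0.3 mg/dL within 48
hours, or a value at least 1.5 times the rolling baseline, defined as the
lowest measured creatinine over the preceding 7 days. Urine-output criteria
are deliberately out of scope (they are unreliable outside the ICU), as is
any baseline imputed from prior admissions or outpatient values.

Several points the clinical definition leaves open had to be fixed:

* **Windows are half-open and exclude the current measurement**: the
  baseline at time *t* is the minimum over `[t − 168h, t)` and the 48-hour
  reference is the minimum over `[t − 48h, t)`. Including the current value
  would compare a measurement against itself whenever it is the running
  minimum; exclusion matches the natural reading of "preceding".
* **The absolute criterion compares against the window minimum**, so any
  rise of ≥ 0.3 mg/dL from any value in the last 48 hours triggers —
  equivalent to "an increase within 48 hours".
* **No onset at the first measurement, ever.** AKI requires at least two
  measured creatinine values; a patient is unlabelable before that.
* **Only the first event per admission is used**; all later time points are
  censored from modeling, because once AKI is manifest the prediction
  problem is over.
* **Simultaneous duplicate timestamps collapse to their maximum** —
  conservative toward detection and deterministic.
* **Staging** uses the guideline thresholds (ratio ≥ 2 → stage 2, ratio ≥ 3
  or creatinine ≥ 4.0 mg/dL at onset → stage 3, RRT initiation → stage 3),
  exposed as arguments rather than hard-coded. The package reports the
  stage at onset; a per-admission maximum stage is a trivial summary of the
  events table.
* **Sustained AKI** means the onset measurement and the next measurement
  each independently satisfy a KDIGO trigger (two consecutive qualifying
  values); an onset with no later measurement is not sustained.
* All threshold comparisons carry a 1e-9 mg/dL tolerance so that exact
  boundary cases (a rise of exactly 0.3, a ratio of exactly 1.5) do not
  flip on floating-point representation.

Cohort rules mirror a standard inpatient study flow: patients are excluded,
in order, for a missing discharge time, fewer than two inpatient creatinine
values, an end-stage kidney disease code (consumed as a boolean input — code
lists are institution-specific), or an admission creatinine ≥ 4 mg/dL.
"Admission creatinine" is the chronologically first inpatient value, the
only definition computable from the data described. Attribution is
first-rule-wins so the flow-diagram counts add up to the input count.

## 2. The discrete-time hazard model

The unit of analysis is the *observation row*: one row per covariate update
(lab panel or exposure onset) per patient, emulating an EHR that re-scores
the patient every time new information arrives. Time-varying covariates are
carried forward until remeasured; exposures (medications, procedures) are
absorbing within the admission, matching "requirement during
hospitalization" semantics. Three creatinine features are derived per row:
the last value, the 7-day rolling baseline, and the 48-hour delta (last
value minus the 48-hour window minimum, 0 when the window is empty — the
same reference convention as the detection criterion).

A row is labeled positive when AKI onset falls in the half-open window
`(t, t + 24h]`. The row exactly at onset is censored — by definition it
already shows the diagnostic rise and would leak outcome into features —
while a row exactly 24 hours ahead is positive. The same lookahead labels
sustained AKI, renal replacement therapy, and inpatient death;
admission-level ("any during admission") indicators are emitted alongside
for cohort summaries, and the 24-hour variant is the modeling default.

The model itself is intentionally plain: maximum-likelihood logistic
regression of the row label on the covariate vector, untransformed (no
splines, no standardization by default, no regularization). The value of
the approach lies in the data construction, not in the learner. Fitting is
IRLS with convergence declared at a relative log-likelihood change below
1e-8 and a cap of 100 iterations. Complete separation is an explicit error
naming the offending covariate, never a silently penalized fit; singular
designs name the collinear columns. An optional `standardize` flag centres
and scales continuous covariates internally for numerical conditioning and
maps the coefficients back to the original scale.

Because one patient contributes many rows, naive binomial variances are
wrong. Inference uses the cluster-robust sandwich estimator with patients
as clusters: score contributions are summed within patient before the outer
product. No small-sample cluster adjustment is applied — with thousands of
patient clusters the G/(G−1) factor is negligible, and omitting it makes
the estimator coincide exactly with the ordinary heteroskedasticity-robust
variance when every cluster has one row (a useful degenerate check).
Covariate importance is reported as |Wald z| (coefficient over
cluster-robust standard error), in descending order with alphabetical
tie-break for determinism.

Covariates enter in classes — demographics and comorbidities (time
invariant), laboratory values, the 48-hour creatinine delta on its own
(because of its outsized strength), medications, and procedures — plus the
full model with everything. Missing data are never imputed: each class only
scores rows where every covariate it requires has been observed, matching
what a live EHR deployment could actually do. By default a separate model
is refit per outcome; re-scoring the 24-hour-AKI model against the other
outcomes' labels is available behind `refit_per_outcome = FALSE` since the
choice is defensible either way.

The patient-level split is two-thirds training / one-third internal
validation within the internal hospital, with other hospitals passing
through as external strata. Splits are always by patient, never by row.

## 3. Evaluation

Discrimination is the midrank (Mann–Whitney) AUC: the probability that a
random positive row outscores a random negative row, ties at half credit,
equal by construction to the trapezoidal area over all unique thresholds.
Confidence intervals come from a percentile bootstrap that resamples
*patients* with replacement, moving each patient's rows together (B = 2000
by default, seeded). The paper-of-record for this kind of analysis states
patient-level clustering without naming a mechanism; the patient bootstrap
is the assumption-light choice, and in the independent-rows limit the test
suite checks its interval width against a DeLong-style analytic interval
from an independent implementation. Resamples with a single label class are
redrawn and counted; when the exact probability of a single-class resample
reaches one half the data are declared too sparse to bootstrap.

Operating points are chosen from the ROC by nearest achieved value on the
feasible side of a sensitivity or specificity target, tie-broken toward
higher specificity. The PPV of an operating point follows Bayes' rule,
PPV = se·π / (se·π + (1 − sp)(1 − π)); at 15% prevalence an 80%/50%
(sensitivity/specificity) alert carries a PPV of 22% and a 37.5%/87.5%
alert 35% — the two worked values the test suite pins down.

## 4. The synthetic EHR generator

No real EHR extract ships with the package, so validation rests on a
generator that emulates the *structure* the analysis assumes while keeping
the data-generating truth known:

* **Admissions**: gamma-distributed length of stay (mean 120 h, truncated
  24–480 h), three hospitals with configurable membership and hazard
  intercept shifts; a small share of patients is deliberately generated
  exclusion-eligible under each of the four rules so the cohort filter is
  exercised.
* **Laboratories**: panel draws at Poisson times (1.5/day by default; every
  panel measures all nine analytes), values = patient-level latent mean +
  measurement noise; baseline creatinine is lognormal
  (log-mean log 0.9 mg/dL, log-sd 0.25).
* **Exposures**: absorbing onsets at uniform times, with prevalences set to
  plausible inpatient values.
* **Hazard**: a discrete-time logistic hazard evaluated on a 6-hour grid —
  the real observation process is measurement-driven, but a generator needs
  a clock, and 6 hours is fine enough that a 24-hour window spans several
  ticks. The true covariate state at a tick is exactly the
  carried-forward value (the patient latent mean before the first draw), so
  the generative truth and the modeling representation agree by
  construction. The default coefficients act through age, comorbidity,
  nephrotoxic/supportive exposures, BUN and bicarbonate, with the intercept
  set so close to one in five patients develops AKI during the admission —
  the incidence regime of general inpatient populations.
* **Post-onset course**: creatinine climbs linearly at 0.8 mg/dL per 24 h
  for 72 h then plateaus — the simplest shape that lets both KDIGO criteria
  trigger — with a follow-up creatinine drawn 6–24 h after onset, mimicking
  clinical rechecking. Death and RRT times are drawn with AKI-dependent
  probabilities (2% / 10% death without / with AKI; 8% RRT after AKI).
* **Missingness**: an optional thinning stage removes each non-creatinine
  lab row with a configurable probability (the ~10%-of-observations regime
  is typical); creatinine is never removed because the outcome must remain
  ascertainable.

Everything is driven by a single seed through an RNG-preserving wrapper, so
identical configurations are bit-identical, and `ground_truth` carries the
per-patient onset times, per-row true probabilities, and the generative
coefficients.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: real lab panels are not exchangeable Poisson draws
(ordering intensifies when patients deteriorate, which induces informative
observation times); true creatinine trajectories are not
piecewise-linear-then-plateau; comorbidities are not independent Bernoulli
draws; and no attempt is made to reproduce any published cohort's
demographics table. Published AUCs from six-figure real cohorts are not
reproducible from desk-scale synthetic data and are not claimed.

## 5. Validation strategy and problem sizes

The test suite validates each stage against an independent oracle rather
than against itself: a literal O(n²) brute-force KDIGO scanner on 10,000
fuzzed creatinine series (onset time, criterion, stage and sustained flag
must match exactly); a brute-force latest-value scan for every
carried-forward cell; pairwise enumeration for the AUC; `glm` plus an
external sandwich implementation for the fitted model; a DeLong-style
interval for the bootstrap; and the generator's own coefficients for
parameter recovery — 200 replicates of 5,000-patient cohorts, in which each
cluster-robust 95% Wald interval must cover its true coefficient in at
least 92% of replicates. The duplicated-rows experiment checks that the
patient bootstrap is invariant to perfect within-patient dependence while a
row bootstrap incorrectly shrinks by √2. A lab-driven-hazard simulation
reproduces, under its enabling condition, the qualitative headline that a
laboratory-only model performs on par with the full model. These problem
sizes (2,000–5,000 patients per cohort, 10,000 fuzz series, B = 500–2,000
bootstrap replicates) were chosen as the smallest at which the asymptotic
claims under test are expected to hold cleanly.

## 6. Known limitations

* The KDIGO engine sees only inpatient creatinine: community-acquired AKI
  and pre-admission baselines are invisible by design.
* Detection timing is sampling-limited: the detected onset is the first
  measurement showing the rise, which lags the true (generative) onset by
  up to one inter-draw interval; parameter-recovery tests therefore fit on
  the generative rows, while model-evaluation tests accept the lag as part
  of the problem.
* The bootstrap CI method is a defensible choice, not the only one;
  cross-package numeric agreement with other clustered-AUC procedures is
  not claimed.
* `evaluation_grid` refuses cells whose stratum has single-class labels
  rather than silently dropping them; restrict `eval_strata` when small
  external strata carry no events of a rare outcome.
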