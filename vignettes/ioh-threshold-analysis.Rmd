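---
title: "Hypotension exposure metrics and harm-threshold discovery"
author: "iohmace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hypotension exposure metrics and harm-threshold discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iohmace)
library(data.table)
```

## The scientific problem

Intraoperative hypotension (IOH) — mean arterial pressure (MAP) falling
below a harm threshold during surgery — is a modifiable risk factor for
30-day major adverse cardiac events (MACE: myocardial infarction, unstable
angina, heart failure, new severe arrhythmia, nonfatal cardiac arrest or
cardiac death). The clinically contested question for patients aged 65 and
over is *where* that threshold lies: the commonly used 65 mm Hg derives
from younger mixed populations, while older patients' reduced
cardiovascular reserve argues for a higher limit.

`iohmace` implements the complete analysis chain used to answer this
question from routinely collected vital-sign streams:

1. **Vitals cleaning** — artifact removal from 30-second blood-pressure
   records by four published invalidity rules, invasive-over-noninvasive
   source selection, baseline (preoperative mean) MAP.
2. **Exposure metrics** — per patient and threshold: minutes with
   MAP below the threshold, area under the threshold–time curve
   (min × mm Hg), and time-weighted-average (TWA) MAP deficit, plus the
   categorical encodings used in reporting (duration bins
   `0.5–5 / 5–10 / 10–15 / >15` min, area and TWA quartiles).
3. **Threshold discovery** — MACE-probability curves against a MAP grid,
   stratified by cumulative hypotension duration, with a quantitative
   convergence detector; restricted-cubic-spline logistic models for the
   adjusted analogue.
4. **Association models** — unadjusted and confounder-adjusted logistic
   regressions of MACE on each exposure encoding, an age-stratified
   analysis (cut at 80 years), and a standardized-mean-difference (SMD)
   baseline table.
5. **Synthetic cohort generator** — a seedable simulator of covariates,
   blood-pressure traces and outcomes, so that every stage is testable
   without access to hospital data, and so that recovery of a *known*
   threshold and effect size can be demonstrated end to end.

## Data model

Vitals are long-format records: `patient_id`, `phase`
(`preop`/`intraop`), `t` (seconds from anesthesia start; negative
preoperatively), `sbp`, `dbp`, `map` (mm Hg), `source`
(`invasive`/`noninvasive`). Patients are one row each with demographics,
comorbidities, labs, medications, surgical factors, the MACE flag and
subtype flags.

### Cleaning rules

A record is invalid when (1) SBP ≥ 300 or ≤ 20 mm Hg, (2) SBP ≤ DBP + 5,
(3) DBP ≤ 5 or ≥ 225, or (4) MAP > 155 or < 25. Boundaries are inclusive
exactly as written; a record violating several rules is attributed to the
lowest-numbered one. Records with a missing MAP but valid SBP/DBP are
repaired with `map = dbp + (sbp − dbp)/3` before the rules are applied —
this maximizes data retention and keeps the repair consistent with the
MAP identity. If any invasive intraoperative record exists for a patient,
that patient's noninvasive intraoperative records are discarded.

### Time credits and gaps

Sampling is nominally every 30 s, but cleaned traces have holes. Each
record is credited with the time span to the next record, capped at a
`gap_cap` of 120 s (so a single reading never stands in for a long
unmonitored stretch); the final record carries the nominal interval.
Moving-average windows for the lowest-MAP statistics are *trailing*,
advance one record at a time, and never span a gap wider than `gap_cap`.
Whether the source analyses used trailing or centred windows, and how they
treated gaps, is not documented anywhere we know of; these are this
package's declared conventions, and the tests pin them down.

## Exposure metrics

With per-record credits $c_i$ (minutes) and readings $m_i$, for a
threshold $h$:

* minutes below: $\sum_i c_i \, 1[m_i < h]$ — strictly below, matching
  the "MAP < 70 mm Hg" convention;
* area below: $\sum_i c_i \,(h - m_i)_+$ (rectangle rule — the natural
  integral for step-wise 30-second data; a trapezoid rule would
  interpolate across measurement noise);
* TWA deficit: area divided by monitored duration ($\sum_i c_i$) — the
  monitored time, not the scheduled case length, is the denominator.

Duration bins use half-open intervals with the first exposed bin closed on
the right (5.0 min is `0.5–5`); patients under 0.5 min form the `none`
reference. Area and TWA quartiles are computed among exposed patients
only, as equal-frequency rank quartiles with ties broken by patient id, so
the assignment is reproducible run to run.

## Threshold discovery

For each grid value $m$ (40–100 mm Hg in 1 mm Hg steps) and each
cumulative-duration stratum $s \in \{1, 3, 5, 10\}$ minutes, the
univariate curve is the MACE rate among patients whose time below $m$ is
at least $s$, smoothed along the grid with a centred 5-point moving
average. Empty cells are missing, never zero. The adjusted analogue
rescales each cell's observed rate by the ratio of the marginal incidence
to the cell's mean confounder-only model risk (indirect standardization),
so curves that stay separated after adjustment indicate an exposure
effect not explained by the confounders. A second adjusted view fits a
logistic model with a restricted cubic spline of the lowest MAP
(Harrell's 3-knot form, knots at the 10th/50th/90th percentiles; the
restricted term is identically zero below the first knot and the fitted
spline is linear beyond the outer knots) plus confounders, and predicts
risk along the grid with confounders at their means/modes.

### Convergence detection

The harm threshold is read off the curves as the point where the strata
stop separating. We operationalize this with a *knee* estimator. Let
$\mathrm{sep}(m)$ be the largest pairwise distance between strata curves
at grid value $m$ (cells whose smallest stratum holds fewer than 10% of
the largest cell are masked — the max–min spread of small noisy cells is
biased upward and would otherwise distort the profile's left edge).
From the separation peak upward we fit, by weighted least squares (cell
size as weight), a continuous three-segment shape: a flat plateau, a
linear decay, and a floor. The threshold estimate is the first grid value
past the fitted end of the plateau. The estimate is scale-free: it does
not depend on the absolute height of the separation profile, only on
where the profile starts to collapse.

An earlier candidate design — "the largest grid value at which separation
still exceeds a fixed tolerance $\tau = 0.25 \times$ marginal incidence"
— was abandoned after measurement: with a 2.5% incidence and a true
odds ratio of 1.5, the typical separation plateau (0.4–0.6 percentage
points at $n = 20{,}000$) is of the same order as that $\tau$, so
detection degenerated to a coin flip on ordinary replicates. The fixed
tolerance survives in the `converged` flag, which asks a different
question: the median separation over the last 5 grid points must lie
within $\tau$ (the curves really do collapse) and the fitted plateau must
exceed $\tau/2$ (they were separated to begin with). Identical curves
therefore report "no threshold" rather than a spurious estimate.

## Association models

Logistic regressions are maximum-likelihood `glm` fits with Wald 95%
intervals (chosen over profile likelihood for determinism and speed;
at the cohort sizes involved the difference is negligible). Runaway
coefficients (|log-odds| > 15) raise an explicit separation error rather
than returning garbage. The adjusted models carry the standard confounder
list (age, cardiovascular and renal history, labs, medications, ASA,
surgery type and duration, emergency status, blood loss, urine volume,
crystalloid rate). ASA grade enters as a numeric score 1–4 — the grade-IV
prevalence (0.7%) makes indicator coding quasi-separable in moderate
samples, and the confounder is described as a score in the source
analyses. Continuous confounders enter linearly; no multiplicity
correction is applied, matching the reporting style being emulated.
The age-stratified analysis refits the duration-bin model below and at/
above 80 years among exposed patients, with `0.5–5` min as the reference
bin. Baseline tables use the binary SMD
$|p_1-p_2| / \sqrt{(p_1(1-p_1)+p_2(1-p_2))/2}$, its continuous analogue
with pooled SDs, and a chi-square test without continuity correction.

## The synthetic cohort generator

The generator emulates the *structure* of a large retrospective cohort of
older noncardiac-surgery patients, not any real patient stream:

* **Covariates** are drawn independently with prevalences matching the
  published non-MACE baseline column (e.g. hypertension 44.3%, arrhythmia
  9.4%, ASA II 78.4%); labs and intraoperative volumes are lognormal
  matched to printed medians and IQRs; surgery duration is a mixture over
  the printed duration bands.
* **Traces**: preoperative MAP is normal (mean 96, SD 10.4 mm Hg,
  truncated 70–130). The intraoperative trajectory is a discrete-time
  mean-reverting AR(1) process (coefficient 0.90 per 30-s step,
  innovation SD 3 mm Hg) around an age-adjusted level about 10 mm Hg
  below baseline, plus an induction dip over the first 10 minutes and
  Poisson-placed triangular hypotensive dips (≈1.2/hour, mean depth
  14 mm Hg, mean duration 6 min). These settings were fixed once so that
  cumulative time below 70 mm Hg covers all reporting bins (roughly a
  quarter of patients unexposed and a third above 15 minutes) — the
  source cohort's exposure distribution is not published, so coverage,
  not fidelity, is the design goal.
* **Pressures**: a per-patient pulse pressure (normal, mean 45, SD 8)
  gives `dbp = map − pp/3`, `sbp = dbp + pp`, keeping the MAP identity
  exact on clean records.
* **Outcome**: `logit P(MACE) = α + log(1.5)·1[T > 15] + 0.002·min(T, 60)
  + γ'Z`, where `T` is the true minutes below the configured threshold
  (70 mm Hg by default) and `γ` are plausible covariate effects
  (positive for arrhythmia, heart failure, ASA, age, ...). The intercept
  α is calibrated by root finding on the realized cohort so the marginal
  incidence matches the 2.5% target. The small linear term produces the
  graded dose–response seen across area/TWA quartiles; its default is a
  compromise — large enough that quartile odds ratios climb to ≈1.7,
  small enough that the fitted ">15 min" adjusted odds ratio stays
  compatible with its nominal 1.5 (a linear term strong enough to push
  the top quartile to 1.8 provably inflates the >15-min contrast past
  recovery).
* **Artifacts**: exactly ⌈rate·N⌉ records (0.5% by default) are corrupted
  so each violates exactly one randomly chosen validity rule, and the
  violated rule is retained in an internal truth column so tests can
  verify that cleaning removes precisely the injected set.
* **Subtypes**: each MACE patient receives one subtype drawn with weights
  matching the published subtype counts, plus a 4.2% chance of a second
  (subtypes may overlap).

What the generator does *not* emulate: covariate correlation structure
(beyond age's effect on intraoperative level and duration's effect on
exposure opportunity), waveform-level physiology, treatment responses to
hypotension, or informative missingness. Passing the recovery tests
therefore shows that the *pipeline* is correct and well calibrated under
a known truth — not that any particular clinical threshold is right.

## Problem sizes and reproducibility

All randomness flows from a single seed, fanned out deterministically per
stage; the pipeline writes a manifest (config echo, seed, package
version) sufficient to reproduce a run bit for bit. The package's own
verification uses: 10 replicates of $n = 20{,}000$ cohorts for threshold
recovery (median estimate within ±2.5 mm Hg of the configured truth, for
both 70 and 60 mm Hg generators) and for the adjusted ">15 min" odds
ratio; 20 replicates of $n = 4{,}000$ null cohorts for CI coverage; 200
random traces against brute-force oracles for the exposure metrics and
moving-average minima. These sizes were chosen as the smallest at which
the Monte-Carlo error of each check is comfortably below its tolerance.

## Known limitations

* The convergence detector assumes a single plateau-then-decay shape; a
  cohort with two distinct harm thresholds would be summarized by one.
* Wald intervals undercover slightly in strata with very few events; the
  stratified analysis reports `estimable = FALSE` rather than forcing a
  fit when a stratum degenerates.
* The TWA denominator is monitored time; if monitoring gaps are
  informative (e.g. crises), all exposure metrics inherit that bias.
* Relative (percent-below-baseline) thresholds require a preoperative
  baseline; patients without one are excluded from relative analyses
  only.
* Because the generator's harm mechanism is purely absolute, the relative
  analysis sees a genuine image of the absolute effect (convergence near
  100 × (1 − 70/96) ≈ 30% below baseline) rather than an independent
  relative threshold; scenarios in which relative convergence vanishes
  after adjustment would need a baseline-dependent outcome mechanism the
  generator does not model.
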