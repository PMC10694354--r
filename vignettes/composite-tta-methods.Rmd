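---
title: "Composite time-to-alteration analysis: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite time-to-alteration analysis: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttalt)
```

## Why a composite time-to-alteration endpoint

Late lung and heart toxicity after breast radiotherapy is multi-dimensional:
pulmonary function tests, echocardiographic ejection fraction, clinician
morbidity grades and patient-reported symptoms each tell part of the story,
are measured on different scales, and can point in different directions.
Tabulating ordinal grades per indicator, period and arm is useful
descriptively but practically unmanageable for inference. `ttalt` instead
reduces each patient's whole longitudinal record to a single time-to-event
quantity — the first time *any* indicator class shows a deterioration of at
least d% relative to that patient's own baseline — and then applies standard
survival inference to it.

## The estimator

For one patient and one continuous indicator with measurements
\((t_i, y_i)\), \(t_1 = 0\) at randomization:

1. Fit ordinary least squares \(\hat y(t) = a + b t\) over all available
   visits (no imputation; irregular and missing visits are simply absent
   points). At least two distinct time points are required.
2. Test \(H_0: b = 0\) with the usual t-test on the slope. A *significant
   decline* means \(b < 0\) and two-sided \(p < \alpha_{slope}\).
3. If there is a significant decline, the candidate alteration time solves
   \(a + b t^* = (1 - d)\, y_0\), where \(y_0\) is the observed baseline
   value. The patient has an event at \(t^*\) if \(t^* \le\) follow-up,
   is censored at follow-up if \(t^* >\) follow-up, and otherwise
   (no significant decline) is censored at follow-up.

Ordinal series (RTOG lung/heart grades; fatigue and dyspnea categories)
contribute the first visit time whose grade exceeds the baseline grade,
else censoring at follow-up.

The composite event is the minimum over the component event times: lung TTA
on {FEV1/FVC, DLCO/VA, TLC}, heart TTA on LVEF, RTOG grade increase,
fatigue-dyspnea increase. Ties are labelled (not timed) by the fixed
precedence lung, heart, RTOG, fatigue-dyspnea. The lung ratios are built by
pairing the member series visit-by-visit; visits missing either member (or
with a zero denominator) are dropped.

Inference on the composite is by randomized arm, intention-to-treat:
Kaplan–Meier curves with Greenwood standard errors, the log-rank test, the
restricted mean survival time (RMST) difference, and a Cox model with the
Efron tie correction — ties are common because ordinal events land on the
yearly visit grid.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `d` | 0.10 | deterioration fraction defining the threshold \((1-d) y_0\) |
| `alpha_slope` | 0.05 | two-sided level of the per-patient slope test |
| `tau` | auto | RMST horizon (years); auto = largest horizon observable in both arms |
| `age_cut` | 50 | dichotomization of age (years) for subgroup interactions |
| `qlq_rule` | "category" | PRO event = category increase; `"raw"` uses any raw-score increase |
| `d_sweep` | 0.10, 0.20, 0.40, 0.60 | thresholds of the sensitivity sweep |

Grading cutoffs are fixed by the adapted CTCAE convention: percent decline
from baseline in (10, 25] → grade 1, (25, 50] → 2, (50, 75] → 3, > 75 → 4
for pulmonary tests; absolute percentage-point LVEF drops in (10, 20],
(20, 30], (30, 50], > 50 → grades 1–4; QLQ symptom scores (linear 0–100
transform of the 1–4 raw mean) categorized as [0, 20] mild, (20, 40]
moderate, > 40 severe. All intervals are left-open, right-closed exactly as
printed, so a 10% decline is still grade 0 and a score of 40 is still
moderate. Improvements always map to grade 0: only deterioration is graded.

## Design choices where the method is genuinely open

* **Slope significance level.** The TTA definition requires a "significant
  decline" without fixing a level; `ttalt` uses a two-sided slope t-test at
  `alpha_slope = 0.05`, exposed as a parameter. Two-point series, whose
  slope p-value is undefined, are treated as not significant (censored) —
  the conservative reading.
* **Baseline anchor.** The threshold is anchored at the observed t = 0
  value, matching the grading convention "relative to baseline"; when the
  baseline visit is missing, the fitted intercept is the fallback.
* **Negative crossing times.** With a noisy baseline the fitted line can sit
  below the threshold already at t = 0 (t* < 0). Such patients get an event
  at time 0, the earliest admissible time for "time to reach" a state they
  are already in.
* **PRO increase rule.** "Fatigue-dyspnea increase" is read as an increase
  of the mild/moderate/severe *category* over the baseline category; a raw
  score increase rule is available via `qlq_rule = "raw"`. The category rule
  avoids flagging clinically irrelevant one-point item fluctuations.
* **Residual volume.** RV rises when function declines, so it enters
  descriptive grading through its inverse (percent decline of 1/RV), and the
  `rv_invert()` transform log(1/RV) is provided for display consistency. RV
  is *not* in the default composite set, which follows the lung-ratio +
  TLC + LVEF + RTOG + PRO composite; users can override the indicator set.
* **LVEF change scale.** Absolute percentage-point drop by default (the
  CTCAE convention for resting ejection fraction); relative change is a
  switch for sensitivity analyses.
* **Sample size correction.** The continuity-corrected (Fleiss) two-
  proportion formula is the default because a 25% → 5% design at α = 0.05,
  power 0.80 then requires 59/arm (118 total), the figure a conventional
  corrected chi-square design yields; the uncorrected formula (49/arm) is
  exposed as an option.
* **Randomization.** Efron's biased coin with the classical p = 2/3,
  applied independently within each stratum combination (nodal status ×
  surgery × chemotherapy sequence) — the simplest reading of "balanced by".
* **RMST inference.** The RMST is the rectangle integral of the KM step
  function up to τ; its variance is the standard asymptotic sum over event
  times \(\sum_j A_j^2\, d_j / (n_j (n_j - d_j))\) with
  \(A_j = \int_{t_j}^{\tau} \hat S\), and the between-arm difference uses a
  normal two-sided test. The default τ is the largest horizon at which both
  arms are still observable; requesting a larger τ is an error because the
  estimand is not identified there.

## The synthetic cohort generator

`simulate_cohort()` exists so the entire pipeline — grading, trajectory
fits, composite construction, survival inference, threshold sweep — is
exercisable and testable without patient data. It emulates the measurement
design of a long-running two-arm trial:

* visits at baseline, 0.25 years (the 1–3 months post-therapy assessment,
  fixed at a single deterministic time to keep fixtures reproducible), then
  yearly to an administrative cutoff of 13 years;
* baseline values drawn per patient from the control-arm baseline
  distribution of an operated stage I–II breast cancer population
  (FEV1 2.44 ± 0.56 L, FVC 3.26 ± 0.67 L, DLCO 18.74 ± 3.98 mL/mmHg/min,
  VA 4.46 ± 0.68 L, RV 1.90 ± 0.51 L, TLC 5.20 ± 0.70 L,
  LVEF 62.6 ± 4.5%, fatigue raw 1.90 ± 0.62, dyspnea raw 1.33 ± 0.67);
* linear arm-specific decline plus Gaussian measurement noise (3% of the
  baseline mean for pulmonary tests, 2 LVEF points), truncated below at 1%
  of the baseline mean to respect positivity. The trajectories are linear
  because the TTA estimator itself assumes a linear fit, which makes the
  generator's truth model the right one for parameter-recovery tests. The
  default decline rates are free parameters chosen once as realistic —
  conventional arm ≈ 1–3.5% of baseline per year depending on the
  indicator, experimental arm half of that, with FEV1 declining faster than
  FVC and DLCO faster than VA so the ratio indicators carry signal;
* RTOG grades as monotone step processes with an arm-specific yearly
  one-grade transition probability (0.05 vs 0.025); QLQ raw scores drifting
  upward (+0.06 vs +0.03 per year), clamped to [1, 4];
* independent exponential dropout (0.03/y), death (0.012/y) and recurrence
  (0.02/y) — the simplest censoring model that exercises every censoring
  branch; follow-up is min(cutoff, dropout, death);
* arm allocation by the same Efron biased coin the package exposes, over
  strata drawn as independent Bernoulli/multinomial variables with
  frequencies typical of such a cohort (30% node-positive, 37% mastectomy,
  55/11/34% chemotherapy none/before/concomitant).

What it deliberately does **not** emulate: radiotherapy dose or any
dose–toxicity mechanism, non-linear or step-change trajectories,
informative censoring, correlated indicators within a patient, or
measurement batch effects. Passing tests on synthetic cohorts therefore
demonstrate that the *pipeline computes its estimands correctly under its
own assumptions*, not that real trajectories are linear or that real
censoring is ignorable.

## Numerical choices and degenerate inputs

* An exact (zero-residual) fitted line is detected at relative tolerance
  1e-8; its slope p-value is 0 for a non-zero slope and 1 for a flat line,
  so noiseless fixtures behave as the closed forms say.
* `findInterval(..., left.open = TRUE)` implements the left-open,
  right-closed grade intervals so boundary values land exactly as printed.
* Empty ordinal series censor at follow-up; series with < 2 distinct time
  points are censored as "no significant decline"; rows failing type
  invariants at CSV ingestion are rejected with logged line numbers, never
  silently repaired.
* The pipeline is a pure function of its inputs: identical tables and
  configuration produce byte-identical output files, and no patient is ever
  excluded (the composite table always has one row per patient record).

## Problem sizes used in the test suite

Unit tests run on cohorts of 8–60 patients per arm; oracle-equivalence
checks use ≤ 200-subject tables against hand-rolled product-limit, O−E/V,
rectangle-integration and 1-D partial-likelihood computations; the
operating-characteristic checks use 1000 replicates of a 1000-subject null
for the log-rank type-I error, 200 replicates of 1000 subjects for Cox null
coverage, and a single 2000-subject cohort for planted hazard-ratio
recovery — sizes at which the asymptotics under test are expected to hold
while the whole suite runs in about a minute.

## Known limitations

* The per-patient regression ignores within-patient correlation structure
  and measurement-error heteroscedasticity; the slope test is exact only
  under i.i.d. Gaussian noise.
* No joint longitudinal–survival model and no competing-risks treatment:
  death censors the composite endpoint rather than competing with it.
* Components are unweighted; whether differential weighting of PRO,
  clinician, echo and PFT components is warranted is an open research
  question.
* The RMST difference test is asymptotic; very small arms or very few
  events will make its normal approximation optimistic.
* Subgroup interaction tests are post-hoc screening tools: a trial sized
  for a main effect is not sized for interactions.
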