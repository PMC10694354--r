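# ttalt — composite time-to-alteration analysis of lung–heart toxicity

`ttalt` is an R package for analysing late cardio-pulmonary toxicity in
two-arm randomized radiotherapy trials through a single composite
**time-to-alteration (TTA)** endpoint, instead of dozens of separate
per-indicator comparisons. It is aimed at trial statisticians and
radiation-oncology researchers who follow patients longitudinally with
pulmonary function tests (FEV1, FVC, DLCO, VA, RV, TLC), echocardiographic
LVEF, clinician-assigned RTOG late morbidity grades, and EORTC QLQ-C30
fatigue/dyspnea scores.

## The endpoint

For each patient and each continuous indicator whose decline signals
deterioration, the observed series (y(t_1), …, y(t_k)) is summarized by an
ordinary least-squares line ŷ(t) = a + bt. The *time to d% alteration* is
the crossing time

  t\* = ((1 − d)·y₀ − a) / b,

where y₀ is the patient's baseline (t = 0) value and d is the deterioration
fraction (default d = 0.10). If the regression shows no significant decline
(b ≥ 0, or the two-sided slope p-value ≥ α_slope = 0.05), or t\* exceeds the
patient's follow-up, the patient is censored at their actual follow-up
time. Ordinal indicators (RTOG grades; fatigue/dyspnea categorized
mild/moderate/severe from the 0–100 scale) contribute the first visit time
whose grade exceeds the baseline grade.

The **composite toxicity event** is the first occurrence of any of: lung
TTA (on FEV1/FVC, DLCO/VA, TLC), heart TTA (LVEF), RTOG grade increase, or
fatigue-dyspnea increase. The composite is analysed by randomized arm
(intention-to-treat) with Kaplan–Meier curves, the log-rank test, the
restricted mean survival time (RMST) difference Δ at a horizon τ, and Cox
proportional hazards (Efron ties), with subgroup arm×covariate
interactions and a sensitivity sweep over d ∈ {10%, 20%, 40%, 60%}.

Trial-design helpers are included: the continuity-corrected two-proportion
sample size (25% vs 5% any-grade toxicity at α = 0.05, power 0.80 gives
59/arm, 118 total) and Efron's biased-coin stratified randomization.

## Worked example

```r
library(ttalt)

# a synthetic 120-patient two-arm cohort with arm-specific decline
cohort <- simulate_cohort(sim_config(n_per_arm = 60, seed = 1))

fit <- tta_analysis(cohort$patients, cohort$measurements, d = 0.10)
fit
#> Composite time-to-alteration analysis (d = 10%)
#>   120 patients; 110 composite events
#>   median time free from alteration, CRT: 2 years
#>   median time free from alteration, H-IGRT: 3.69 years
#>   log-rank chi-square = 21.527, p = 3.4897e-06
#>   RMST difference at tau = 5.38 y: 1.20 years, p = 3.6808e-05
#>   arm hazard ratio: 0.38 (95% CI 0.25-0.58), p = 8.3988e-06
```

Patients in the image-guided hypofractionated arm (H-IGRT) of this
synthetic cohort — generated with half the decline rate of the
conventional arm (CRT) — stay free from 10% lung–heart alteration a median
1.7 years longer; the RMST difference says they gain on average 1.20
deterioration-free years up to the 5.4-year horizon at which both arms are
still observable, and the hazard of a composite event is reduced by 62%.
`summary(fit)` breaks events down by triggering component, `plot(fit)`
draws the per-arm Kaplan–Meier curves, and

```r
sensitivity_sweep(cohort$patients, cohort$measurements,
                  d_list = c(0.10, 0.20, 0.40, 0.60))
```

re-runs the whole analysis at more lenient deterioration thresholds (event
counts can only decrease as d grows).

Individual building blocks are exported: `fit_trajectory()`,
`time_to_alteration()`, `ordinal_event_time()`, `composite_tta()`,
`pft_grade()`, `lvef_grade()`, `qlq_scale()`, `qlq_category()`,
`tabulate_grades()`, `km_estimate()`, `logrank_test()`, `rmst_diff()`,
`cox_fit()`, `subgroup_interactions()`, `os_dfs_endpoints()`,
`required_sample_size()`, `efron_coin()`/`efron_assign()`, and the
CSV pipeline `read_patients()`/`read_measurements()`/`run_pipeline()`.

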