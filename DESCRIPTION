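Package: ttalt
Title: Composite Time-to-Alteration Analysis of Lung-Heart Toxicity in
    Two-Arm Radiotherapy Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing longitudinal lung and heart toxicity in
    randomized radiotherapy trials through a composite time-to-alteration
    (TTA) endpoint. Raw pulmonary function tests, echocardiographic left
    ventricular ejection fraction, clinician-assigned RTOG late morbidity
    grades and EORTC QLQ-C30 fatigue/dyspnea scores are mapped to ordinal
    deterioration grades relative to baseline; per-patient least-squares
    trajectories yield the time at which each indicator crosses a d%
    deterioration threshold; the earliest component event defines a
    composite toxicity time analysed by Kaplan-Meier curves, the log-rank
    test, restricted mean survival time differences and Cox proportional
    hazards models with subgroup interactions. Includes trial-design
    helpers (continuity-corrected two-proportion sample size, Efron's
    biased-coin stratified randomization), a deterioration-threshold
    sensitivity sweep, CSV input/output with validation, and a synthetic
    two-arm cohort generator so the full pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
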