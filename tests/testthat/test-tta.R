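test_that("trajectory fit recovers exact lines and matches the normal equations", {
  f <- fit_trajectory(0:3, c(100, 95, 90, 85))
  expect_equal(f$slope, -5)
  expect_equal(f$intercept, 100)
  expect_equal(f$residual_sd, 0, tolerance = 1e-10)
  expect_lt(f$slope_p, 1e-10)   # exact decline: slope known without error

  fc <- fit_trajectory(0:4, rep(3.2, 5))
  expect_equal(fc$slope, 0)
  expect_equal(fc$slope_p, 1)

  set.seed(3)
  t10 <- sort(runif(10, 0, 12)); y10 <- 2.5 - 0.05 * t10 + rnorm(10, 0, 0.1)
  f10 <- fit_trajectory(t10, y10)
  ref <- ols_oracle(t10, y10)
  expect_equal(f10$intercept, ref[1], tolerance = 1e-10)
  expect_equal(f10$slope, ref[2], tolerance = 1e-10)
  # the t-test on the slope agrees with lm's summary
  sm <- summary(lm(y10 ~ t10))$coefficients
  expect_equal(f10$slope_p, sm["t10", "Pr(>|t|)"], tolerance = 1e-12)

  expect_error(fit_trajectory(1, 2), "at least 2")
  expect_error(fit_trajectory(c(1, 1), c(2, 3)), "times are equal")
  # two points: slope p undefined
  expect_true(is.na(fit_trajectory(c(0, 1), c(2, 1))$slope_p))
})

test_that("time to alteration crosses the threshold or censors per the rules", {
  f <- fit_trajectory(0:3, c(100, 95, 90, 85))
  r <- time_to_alteration(f, baseline = 100, d = 0.10, follow_up = 12)
  expect_true(r$event)
  expect_equal(r$time_years, 2, tolerance = 1e-9)
  expect_equal(r$threshold_value, 90)

  # crossing beyond follow-up: censored at follow-up
  r2 <- time_to_alteration(f, baseline = 100, d = 0.10, follow_up = 1.5)
  expect_false(r2$event)
  expect_equal(r2$time_years, 1.5)
  expect_identical(r2$censor_reason, "beyond_follow_up")

  # increasing trajectory: censored, no significant decline
  fup <- fit_trajectory(0:3, c(100, 101.1, 101.9, 103.2))
  r3 <- time_to_alteration(fup, baseline = 100, d = 0.10, follow_up = 12)
  expect_false(r3$event)
  expect_identical(r3$censor_reason, "no_significant_decline")

  # declining but non-significant slope (noisy, alpha_slope small): censored
  set.seed(8)
  fns <- fit_trajectory(0:5, 10 - 0.01 * (0:5) + rnorm(6, 0, 2))
  r4 <- time_to_alteration(fns, baseline = 10, d = 0.10, follow_up = 12,
                           alpha_slope = 1e-6)
  expect_false(r4$event)

  # two-point series: p undefined, treated as not significant
  f2 <- fit_trajectory(c(0, 1), c(100, 50))
  expect_false(time_to_alteration(f2, 100, 0.10, 12)$event)

  # fitted line already below threshold at t = 0: event at time 0
  flow <- fit_trajectory(0:3, c(85, 80, 75, 70))
  r5 <- time_to_alteration(flow, baseline = 100, d = 0.10, follow_up = 12)
  expect_true(r5$event)
  expect_equal(r5$time_years, 0)

  expect_error(time_to_alteration(f, 100, d = 1.2, follow_up = 12), "\\(0, 1\\)")
  expect_error(time_to_alteration(f, 100, d = 0.1, follow_up = -1), "positive")
})

test_that("TTA is invariant under unit rescaling and scales inversely with d", {
  f <- fit_trajectory(0:3, c(100, 95, 90, 85))
  fs <- fit_trajectory(0:3, c(100, 95, 90, 85) / 1000)  # liters -> mL
  r <- time_to_alteration(f, 100, 0.10, 12)
  rs <- time_to_alteration(fs, 0.1, 0.10, 12)
  expect_equal(r$time_years, rs$time_years, tolerance = 1e-9)
  # d = 20% on the same line: crossing at 4 years
  expect_equal(time_to_alteration(f, 100, 0.20, 12)$time_years, 4,
               tolerance = 1e-9)
})

test_that("ordinal event time is the first visit above the baseline grade", {
  r <- ordinal_event_time(0:3, c(0, 0, 1, 1), follow_up = 12)
  expect_true(r$event); expect_equal(r$time_years, 2)
  r2 <- ordinal_event_time(0:3, c(0, 0, 0, 0), follow_up = 12)
  expect_false(r2$event); expect_equal(r2$time_years, 12)
  # ordered categories
  cats <- factor(c("mild", "mild", "moderate"),
                 levels = c("mild", "moderate", "severe"), ordered = TRUE)
  r3 <- ordinal_event_time(0:2, cats, follow_up = 12)
  expect_true(r3$event); expect_equal(r3$time_years, 2)
  # non-zero baseline grade: only increases above it count
  r4 <- ordinal_event_time(0:3, c(2, 2, 1, 2), follow_up = 10)
  expect_false(r4$event)
  # empty series: censored at follow-up
  r5 <- ordinal_event_time(numeric(0), numeric(0), follow_up = 7)
  expect_false(r5$event); expect_equal(r5$time_years, 7)
})

test_that("ratio series pairs visits by time and handles degenerate cases", {
  r <- derive_ratio_series(0, 2.44, 0, 3.26)
  expect_equal(r$values, 2.44 / 3.26)
  expect_equal(round(r$values, 2), 0.75)   # as conventionally reported
  ident <- derive_ratio_series(0:3, c(2, 2.1, 2.2, 2.3), 0:3, c(2, 2.1, 2.2, 2.3))
  expect_true(all(ident$values == 1))
  mis <- derive_ratio_series(c(0, 1, 2), c(2, 2, 2), c(1, 2, 3), c(4, 4, 4))
  expect_equal(mis$times, c(1, 2))
  expect_warning(z <- derive_ratio_series(0:1, c(1, 1), 0:1, c(1, 0)),
                 "zero denominator")
  expect_equal(z$times, 0)
})

test_that("composite event is the earliest component with fixed tie precedence", {
  comps <- list(lung_tta = list(event = TRUE, time_years = 3.0),
                heart_tta = list(event = FALSE, time_years = 12),
                rtog_increase = list(event = TRUE, time_years = 2.5),
                fatigue_dyspnea_increase = list(event = FALSE, time_years = 12))
  ce <- composite_tta(comps, follow_up = 12)
  expect_true(ce$event)
  expect_equal(ce$time_years, 2.5)
  expect_identical(ce$component, "rtog_increase")

  none <- lapply(comps, function(x) list(event = FALSE, time_years = 12))
  ce2 <- composite_tta(none, follow_up = 12)
  expect_false(ce2$event)
  expect_equal(ce2$time_years, 12)
  expect_identical(ce2$component, "censored")

  tie <- list(rtog_increase = list(event = TRUE, time_years = 3.0),
              lung_tta = list(event = TRUE, time_years = 3.0))
  ce3 <- composite_tta(tie, follow_up = 12)
  expect_equal(ce3$time_years, 3.0)
  expect_identical(ce3$component, "lung_tta")  # precedence labels, time unaffected
  expect_error(composite_tta(list(bogus = list(event = TRUE, time_years = 1)), 12),
               "unknown component")
})

test_that("cohort-level composite construction honors ITT and component minima", {
  cohort <- simulate_cohort(sim_config(n_per_arm = 20, seed = 14))
  res <- compute_composite_tta(cohort$patients, cohort$measurements)
  expect_identical(nrow(res$composite), nrow(cohort$patients))
  expect_setequal(res$composite$patient_id, cohort$patients$patient_id)
  # composite time <= every component event time; censored exactly at follow-up
  fu <- cohort$patients$follow_up_years[
    match(res$composite$patient_id, cohort$patients$patient_id)]
  cens <- res$composite$event == 0
  expect_equal(res$composite$time_years[cens], fu[cens])
  per <- res$per_indicator
  for (i in which(res$composite$event == 1)) {
    pid <- res$composite$patient_id[i]
    ev_times <- per$time_years[per$patient_id == pid & per$event]
    expect_true(res$composite$time_years[i] <= min(ev_times) + 1e-12)
  }
})

test_that("sensitivity sweep is consistent at the default and monotone in d", {
  cohort <- simulate_cohort(sim_config(n_per_arm = 20, seed = 21))
  single <- tta_analysis(cohort$patients, cohort$measurements, d = 0.10)
  sw <- sensitivity_sweep(cohort$patients, cohort$measurements,
                          d_list = c(0.10, 0.20, 0.40, 0.60))
  expect_identical(nrow(sw), 4L)
  expect_equal(sw$events[1], sum(single$composite$event))
  expect_equal(sw$hr[1], single$cox$table$hr[1])
  expect_true(all(diff(sw$events) <= 0))
  expect_error(sensitivity_sweep(cohort$patients, cohort$measurements,
                                 d_list = c(0.1, 0.1)), "anyDuplicated|distinct")
})

test_that("steeper decline yields stochastically earlier composite events", {
  # parameter recovery: the arm with twice the decline rate loses freedom
  # from alteration sooner; log-rank detects it on a moderate cohort
  cohort <- simulate_cohort(sim_config(n_per_arm = 60, seed = 17))
  fit <- tta_analysis(cohort$patients, cohort$measurements)
  r <- fit$rmst
  crt <- r$by_group$rmst[r$by_group$group == "CRT"]
  hig <- r$by_group$rmst[r$by_group$group == "H-IGRT"]
  expect_gt(hig, crt)
  expect_lt(fit$logrank$p_value, 0.05)
  expect_lt(fit$cox$table$hr[1], 1)  # H-IGRT vs CRT reference
})
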