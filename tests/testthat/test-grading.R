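test_that("pulmonary grades follow the half-open percent-decline cutoffs", {
  expect_identical(pft_grade(2.0, 1.4), 2L)   # 30% decline
  expect_identical(pft_grade(2.0, 1.8), 0L)   # exactly 10%: interval open at 10
  expect_identical(pft_grade(2.0, 1.5), 1L)   # exactly 25%: closed at 25
  expect_identical(pft_grade(2.0, 2.0), 0L)   # no change
  expect_identical(pft_grade(2.0, 2.4), 0L)   # improvement maps to grade 0
  expect_identical(pft_grade(2.0, 0.4), 4L)   # 80% decline
  # vectorized and monotone in the magnitude of decline
  declines <- seq(0, 0.9, by = 0.05)
  g <- pft_grade(rep(1, length(declines)), 1 - declines)
  expect_true(all(diff(g) >= 0))
  expect_error(pft_grade(0, 1), "positive")
  expect_error(pft_grade(2, -1), "positive")
})

test_that("LVEF grades use the absolute percentage-point drop by default", {
  expect_identical(lvef_grade(65, 50), 1L)    # 15-point drop
  expect_identical(lvef_grade(60, 35), 2L)    # 25-point drop
  expect_identical(lvef_grade(65, 65), 0L)
  expect_identical(lvef_grade(65, 70), 0L)    # improvement
  expect_identical(lvef_grade(90, 30), 4L)    # 60-point drop
  # relative option: 15/65 = 23% relative decline -> grade 2
  expect_identical(lvef_grade(65, 50, relative = TRUE), 2L)
  expect_error(lvef_grade(120, 60), "\\(0, 100]")
})

test_that("QLQ scaling and categorization match the printed boundaries", {
  expect_equal(qlq_scale(1), 0)
  expect_equal(qlq_scale(4), 100)
  expect_equal(qlq_scale(2.2), 40)
  expect_error(qlq_scale(0.5), "outside")
  expect_identical(as.character(qlq_category(c(0, 20, 20.5, 40, 40.1, 100))),
                   c("mild", "mild", "moderate", "moderate", "severe", "severe"))
  expect_true(is.ordered(qlq_category(10)))
  expect_error(qlq_category(101), "outside")
})

test_that("residual volume inversion is the negative log and strictly decreasing", {
  expect_equal(rv_invert(1), 0)
  expect_equal(rv_invert(exp(1)), -1)
  rv <- sort(runif(20, 0.5, 4))
  expect_true(all(diff(rv_invert(rv)) < 0))
  expect_error(rv_invert(0), "positive")
})

test_that("category odds reproduce the worked tabulation arithmetic", {
  expect_equal(category_odds(55.4, 32.6, 11.9), 0.803)
  expect_equal(category_odds(62.4, 24.1, 13.5), 0.603)
  expect_equal(category_odds(50, 25, 25), 1.000)
  expect_error(category_odds(0, 50, 50), "undefined")
})

test_that("grade tabulation conserves counts and normalizes percentages", {
  grades <- data.frame(
    patient_id = sprintf("P%02d", 1:10), arm = "CRT", indicator = "FEV1",
    time_years = 1, grade = "0", stringsAsFactors = FALSE)
  tab <- tabulate_grades(grades)
  expect_identical(tab$count, 10L)
  expect_equal(tab$percent, 100)

  # randomized fixture: percentages sum to 100 within each block,
  # counts sum to the number of records
  set.seed(7)
  g2 <- data.frame(
    patient_id = sample(sprintf("P%02d", 1:30), 400, replace = TRUE),
    arm = sample(c("CRT", "H-IGRT"), 400, replace = TRUE),
    indicator = sample(c("FEV1", "LVEF", "RTOG_LUNG"), 400, replace = TRUE),
    time_years = runif(400, 0, 12),
    grade = as.character(sample(0:3, 400, replace = TRUE)),
    stringsAsFactors = FALSE)
  tab2 <- tabulate_grades(g2, split = 5)
  expect_identical(sum(tab2$count), 400L)
  sums <- tapply(tab2$percent,
                 interaction(tab2$indicator, tab2$period, tab2$arm, drop = TRUE),
                 sum)
  expect_true(all(abs(sums - 100) < 0.1))
  expect_identical(nrow(tabulate_grades(grades[0, ])), 0L)
})

test_that("cohort grading anchors to baseline and drops series without one", {
  meas <- data.frame(
    patient_id = rep("P1", 8),
    indicator = c(rep("FEV1", 3), rep("LVEF", 2), rep("FATIGUE_RAW", 2), "RTOG_LUNG"),
    time_years = c(0, 1, 2, 0, 1, 0, 1, 1),
    value = c(2.0, 1.7, 1.4, 65, 50, 1.0, 2.5, 2),
    stringsAsFactors = FALSE)
  g <- grade_measurements(meas)
  fe <- g[g$indicator == "FEV1", ]
  expect_identical(fe$grade, c("0", "1", "2"))  # 0%, 15%, 30% declines
  lv <- g[g$indicator == "LVEF", ]
  expect_identical(lv$grade, c("0", "1"))
  fa <- g[g$indicator == "FATIGUE_RAW", ]
  expect_identical(fa$grade, c("mild", "severe"))  # scores 0 and 50
  expect_identical(g$grade[g$indicator == "RTOG_LUNG"], "2")  # used as-is
  # total measurements conserved
  expect_identical(nrow(g), nrow(meas))
  # no baseline record -> dropped with a warning
  nob <- data.frame(patient_id = "P2", indicator = "FVC",
                    time_years = c(1, 2), value = c(3, 2.8),
                    stringsAsFactors = FALSE)
  expect_warning(g2 <- grade_measurements(nob), "no baseline")
  expect_identical(nrow(g2), 0L)
})

test_that("grading is idempotent in (baseline, value) and RV deterioration registers", {
  # RV rising (worse) must produce a positive grade through the inverse
  meas <- data.frame(patient_id = "P1", indicator = "RV",
                     time_years = c(0, 1), value = c(1.5, 2.5),
                     stringsAsFactors = FALSE)
  g <- grade_measurements(meas)
  expect_true(as.integer(g$grade[2]) >= 1)
  expect_identical(pft_grade(2, 1.4), pft_grade(2, 1.4))
})
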