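test_that("Kaplan-Meier estimate matches the hand product-limit computation", {
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  ev <- km[km$n_event > 0, ]
  expect_equal(ev$survival, c(2 / 3, 0))   # (1 - 1/3), then (1 - 1/1)
  expect_equal(ev$time, c(1, 3))

  # all censored: S stays at 1
  km2 <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km2$survival == 1))

  # agreement with the brute-force oracle on a 200-subject table
  set.seed(12)
  tt <- rexp(200, 0.2); cc <- rexp(200, 0.1)
  time <- pmin(tt, cc); event <- as.integer(tt <= cc)
  km3 <- km_estimate(time, event)
  ora <- km_oracle(time, event)
  got <- km3$survival[match(ora$time, km3$time)]
  expect_equal(got, ora$surv, tolerance = 1e-10)
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("log-rank test equals direct O-E/V accumulation and is null on identical groups", {
  time <- c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5)
  event <- rep(c(1, 1, 0, 1, 0), 2)
  group <- rep(c("a", "b"), each = 5)
  lr <- logrank_test(time, event, group)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)

  set.seed(4)
  t2 <- c(rexp(40, 0.3), rexp(40, 0.6))
  c2 <- rexp(80, 0.15)
  time2 <- pmin(t2, c2); event2 <- as.integer(t2 <= c2)
  group2 <- rep(c("a", "b"), each = 40)
  lr2 <- logrank_test(time2, event2, group2)
  expect_equal(lr2$statistic, logrank_oracle(time2, event2, group2),
               tolerance = 1e-12)
  expect_equal(lr2$p_value, pchisq(lr2$statistic, 1, lower.tail = FALSE))
  expect_error(logrank_test(c(1, 2), c(0, 0), c("a", "b")), "no events")
})

test_that("log-rank statistic is invariant under monotone time transformations", {
  set.seed(9)
  t2 <- c(rexp(30, 0.3), rexp(30, 0.5)); c2 <- rexp(60, 0.2)
  time <- pmin(t2, c2); event <- as.integer(t2 <= c2)
  group <- rep(c("a", "b"), each = 30)
  a <- logrank_test(time, event, group)
  b <- logrank_test(time^1.7, event, group)
  d <- logrank_test(exp(time), event, group)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_equal(a$statistic, d$statistic, tolerance = 1e-12)
})

test_that("RMST integrates the survival step function with the standard variance", {
  # no events: RMST equals the horizon
  expect_equal(rmst(rep(10, 5), rep(0, 5), tau = 10)$rmst, 10)
  # S = 1 on [0,2), 0.5 on [2,4): area 2*1 + 2*0.5 = 3
  expect_equal(rmst(c(2, 4), c(1, 0), tau = 4)$rmst, 3)
  set.seed(5)
  tt <- rexp(100, 0.25); cc <- rexp(100, 0.1)
  time <- pmin(tt, cc); event <- as.integer(tt <= cc)
  tau <- quantile(time, 0.8)
  expect_equal(rmst(time, event, tau)$rmst, rmst_oracle(time, event, tau),
               tolerance = 1e-10)
  expect_error(rmst(c(1, 2), c(1, 1), tau = 5), "not identified")
})

test_that("RMST difference is zero for identical groups and respects the horizon rule", {
  time <- c(1, 3, 5, 7, 1, 3, 5, 7)
  event <- rep(c(1, 0, 1, 0), 2)
  group <- rep(c("a", "b"), each = 4)
  rd <- rmst_diff(time, event, group)
  expect_equal(rd$diff, 0)
  expect_equal(rd$tau, 7)   # min across groups of the max observed time
  expect_error(rmst_diff(time, event, group, tau = 8), "maximal observed")
  # reference group selection flips the sign
  set.seed(6)
  t2 <- c(rexp(50, 0.4), rexp(50, 0.2)); c2 <- rexp(100, 0.1)
  time2 <- pmin(t2, c2); event2 <- as.integer(t2 <= c2)
  group2 <- rep(c("a", "b"), each = 50)
  r1 <- rmst_diff(time2, event2, group2, ref = "a")
  r2 <- rmst_diff(time2, event2, group2, ref = "b")
  expect_equal(r1$diff, -r2$diff, tolerance = 1e-12)
})

test_that("Cox fit maximizes the partial likelihood (brute-force 1-D oracle)", {
  # 6-subject table, one binary covariate, no ties
  time <- c(1.1, 2.3, 3.1, 4.7, 5.2, 6.9)
  event <- c(1, 1, 0, 1, 1, 0)
  x <- c(1, 0, 1, 0, 1, 0)
  fit <- cox_fit(time, event, data.frame(x = x))
  beta_ref <- cox_oracle_beta(time, event, x)
  expect_equal(fit$table$coef[1], beta_ref, tolerance = 1e-6)
  expect_equal(fit$table$hr[1], exp(fit$table$coef[1]))
  expect_lte(fit$table$lower[1], fit$table$hr[1])
  expect_lte(fit$table$hr[1], fit$table$upper[1])
  expect_error(cox_fit(c(1, 2), c(0, 0), data.frame(x = c(0, 1))), "no events")
})

test_that("Cox score test at beta = 0 equals the log-rank statistic (no ties)", {
  set.seed(10)
  t2 <- c(rexp(30, 0.3), rexp(30, 0.5))
  time <- t2; event <- rep(1L, 60)
  group <- rep(c(0, 1), each = 30)
  fit <- cox_fit(time, event, data.frame(g = group))
  sc <- summary(fit$fit)$sctest[["test"]]
  lr <- logrank_test(time, event, group)
  expect_equal(sc, lr$statistic, tolerance = 1e-8)
})

test_that("Cox null recovery: independent covariate gives HR near 1 with calibrated CIs", {
  set.seed(13)
  reps <- 200
  hrs <- numeric(reps); covered <- logical(reps)
  for (r in seq_len(reps)) {
    n <- 1000
    x <- rbinom(n, 1, 0.5)
    tt <- rexp(n, 0.5); cc <- rexp(n, 0.2)
    fit <- cox_fit(pmin(tt, cc), as.integer(tt <= cc), data.frame(x = x))
    hrs[r] <- fit$table$hr[1]
    covered[r] <- fit$table$lower[1] <= 1 && 1 <= fit$table$upper[1]
  }
  expect_true(median(hrs) > 0.85 && median(hrs) < 1.18)
  expect_gte(mean(covered), 0.90)
})

test_that("subgroup interactions report per-level HRs and skip degenerate levels", {
  set.seed(15)
  n <- 400
  arm <- rep(c("CRT", "H-IGRT"), each = n / 2)
  age <- rnorm(n, 56, 11)
  # planted interaction: the arm effect exists only in older patients
  older <- age >= 50
  rate <- ifelse(arm == "H-IGRT" & older, 0.25, 0.5)
  tt <- rexp(n, rate); cc <- rexp(n, 0.1)
  time <- pmin(tt, cc); event <- as.integer(tt <= cc)
  expect_warning(
    sg <- subgroup_interactions(time, event, arm,
                                data.frame(age = age, site = "breast"),
                                dichotomize = c(age = 50)),
    "single level")
  expect_true(all(c("covariate", "level", "hr", "interaction_p") %in% names(sg)))
  age_rows <- sg[sg$covariate == "age", ]
  expect_identical(nrow(age_rows), 2L)
  hr_old <- age_rows$hr[age_rows$level == ">=50"]
  hr_young <- age_rows$hr[age_rows$level == "<50"]
  expect_lt(hr_old, hr_young)
  expect_true(all(age_rows$interaction_p == age_rows$interaction_p[1]))
  # single-level covariate skipped with warning
  expect_false("site" %in% sg$covariate)
})

test_that("OS and DFS endpoints follow the first-event definitions", {
  p <- data.frame(
    patient_id = c("A", "B", "C"), arm = "CRT",
    follow_up_years = c(12, 5, 5),
    death_time = c(NA, 5, 5), recurrence_time = c(NA, 3, NA),
    stringsAsFactors = FALSE)
  ep <- os_dfs_endpoints(p)
  expect_equal(ep$os$time, c(12, 5, 5))
  expect_equal(ep$os$event, c(0L, 1L, 1L))
  expect_equal(ep$dfs$time, c(12, 3, 5))
  expect_equal(ep$dfs$event, c(0L, 1L, 1L))  # death alone is a DFS event
})
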