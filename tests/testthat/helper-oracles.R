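# Independent brute-force oracles, kept deliberately naive and separate from
# the package implementation paths.

# Product-limit estimator by hand: events precede censorings at equal times.
km_oracle <- function(time, event) {
  o <- order(time, -event)
  time <- time[o]; event <- as.integer(event[o])
  ut <- sort(unique(time[event == 1]))
  n <- length(time)
  surv <- numeric(length(ut))
  s <- 1
  for (k in seq_along(ut)) {
    at_risk <- sum(time >= ut[k])
    d <- sum(time == ut[k] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  list(time = ut, surv = surv)
}

# Two-group log-rank by direct O - E / V accumulation over event times.
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group)) - 1L  # 0/1
  ut <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ut) {
    n1 <- sum(time >= t & g == 1)
    n0 <- sum(time >= t & g == 0)
    n <- n1 + n0
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n0 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# RMST by rectangle integration of the hand product-limit curve.
rmst_oracle <- function(time, event, tau) {
  km <- km_oracle(time, event)
  keep <- km$time <= tau
  t_grid <- c(0, km$time[keep], tau)
  s_grid <- c(1, km$surv[keep])
  sum(diff(t_grid) * s_grid)
}

# Cox partial log-likelihood for one binary covariate, no ties assumed;
# maximized by golden-section search.
cox_oracle_beta <- function(time, event, x, lower = -5, upper = 5) {
  loglik <- function(beta) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    ll
  }
  stats::optimize(loglik, c(lower, upper), maximum = TRUE, tol = 1e-9)$maximum
}

# Closed-form OLS via the normal equations.
ols_oracle <- function(t, y) {
  X <- cbind(1, t)
  unname(solve(t(X) %*% X, t(X) %*% y)[, 1])
}
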