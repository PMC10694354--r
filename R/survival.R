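#' Kaplan-Meier curve(s)
#'
#' Product-limit estimate of the survival function, per group when a group
#' label is supplied, with Greenwood standard errors and log-scale
#' confidence intervals (the `survival` package defaults). Ties are handled
#' in the standard way: events precede censorings at equal times.
#'
#' @param time Event/censoring times in years (non-negative).
#' @param event Event indicator: 1/TRUE event, 0/FALSE censored.
#' @param group Optional group labels.
#' @param conf_level Confidence level for the pointwise CI (default 0.95).
#' @return Data frame of class `km_curve` with columns `group`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`, `std_err`, `lower`,
#'   `upper`.
#' @export
km_estimate <- function(time, event, group = NULL, conf_level = 0.95) {
  if (length(time) == 0) stop("empty event table")
  stopifnot(length(event) == length(time), all(time >= 0))
  event <- as.integer(as.logical(event))
  if (is.null(group)) group <- rep("all", length(time))
  sf <- survival::survfit(survival::Surv(time, event) ~ grp,
                          data = data.frame(time = time, event = event,
                                            grp = group),
                          conf.int = conf_level)
  s <- summary(sf, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(unique(group)[1], length(s$time))
         else sub("^grp=", "", as.character(s$strata))
  out <- data.frame(group = grp, time = s$time, n_risk = s$n.risk,
                    n_event = s$n.event, n_censor = s$n.censor,
                    survival = s$surv, std_err = s$std.err,
                    lower = s$lower, upper = s$upper,
                    stringsAsFactors = FALSE)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank test with the hypergeometric variance, p-value from a
#' chi-square distribution with `k - 1` degrees of freedom.
#'
#' @param time,event As in [km_estimate()].
#' @param group Group labels; at least two groups with at least one event
#'   overall.
#' @return A list with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(time, event, group) {
  event <- as.integer(as.logical(event))
  if (length(unique(group)) < 2) stop("need at least 2 groups")
  if (sum(event) == 0) stop("no events: log-rank test undefined")
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp,
                           data = data.frame(time = time, event = event,
                                             grp = group))
  df <- length(sd$n) - 1
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

## KM curve of one sample as (times, survival, n_risk, n_event) for RMST.
.km_steps <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  list(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
       n_event = sf$n.event)
}

#' Restricted mean survival time
#'
#' Area under the Kaplan-Meier curve up to the horizon `tau`, with the
#' standard asymptotic variance
#' \deqn{\widehat{Var} = \sum_{t_j \le \tau} A_j^2 \frac{d_j}{n_j (n_j - d_j)},
#'   \qquad A_j = \int_{t_j}^{\tau} \hat S(u)\,du,}
#' summing over distinct event times.
#'
#' @param time,event As in [km_estimate()].
#' @param tau Horizon in years; must not exceed the largest observed time.
#' @return A list with `rmst`, `se`, `tau`.
#' @examples
#' rmst(c(2, 4, 6), c(1, 1, 0), tau = 4)
#' @export
rmst <- function(time, event, tau) {
  event <- as.integer(as.logical(event))
  stopifnot(length(time) >= 1, tau > 0)
  if (tau > max(time) + 1e-12)
    stop("tau exceeds the largest observed time; the RMST is not identified")
  km <- .km_steps(time, event)
  keep <- km$time <= tau
  t_grid <- c(0, km$time[keep], tau)
  s_grid <- c(1, km$surv[keep])  # S on [t_grid[k], t_grid[k+1])
  area <- sum(diff(t_grid) * s_grid)
  # variance over event times <= tau
  ev <- keep & km$n_event > 0
  v <- 0
  if (any(ev)) {
    t_ev <- km$time[ev]; d <- km$n_event[ev]; n <- km$n_risk[ev]
    A <- vapply(t_ev, function(tj) {
      lo <- pmax(t_grid[-length(t_grid)], tj)
      hi <- t_grid[-1]
      sum(pmax(hi - lo, 0) * s_grid)
    }, numeric(1))
    denom <- n * (n - d)
    term <- ifelse(denom > 0, d / denom, 0)
    v <- sum(A^2 * term)
  }
  list(rmst = area, se = sqrt(v), tau = tau)
}

#' Between-group difference in restricted mean survival time
#'
#' Computes per-group RMST at a common horizon and the difference
#' (group 1 minus group 0, in the sorted order of labels unless `ref` is
#' given), with an asymptotic normal two-sided p-value.
#'
#' @param time,event,group As in [logrank_test()].
#' @param tau Horizon; defaults to the largest horizon at which every group
#'   is still observable (the minimum across groups of the maximal observed
#'   time).
#' @param ref Label of the reference group (default: first sorted label).
#' @return A list of class `rmst_diff` with `tau`, `by_group` (data frame
#'   of group, rmst, se), `diff`, `se_diff`, `p_value`, `conf_int` (95%).
#' @export
rmst_diff <- function(time, event, group, tau = NULL, ref = NULL) {
  event <- as.integer(as.logical(event))
  groups <- sort(unique(as.character(group)))
  if (length(groups) != 2) stop("rmst_diff compares exactly two groups")
  if (!is.null(ref)) {
    stopifnot(ref %in% groups)
    groups <- c(ref, setdiff(groups, ref))
  }
  max_by_group <- vapply(groups, function(g) max(time[group == g]), numeric(1))
  if (is.null(tau)) tau <- min(max_by_group)
  if (tau > min(max_by_group) + 1e-12)
    stop("tau exceeds the maximal observed time of at least one group")
  per <- lapply(groups, function(g)
    rmst(time[group == g], event[group == g], tau = tau))
  r <- vapply(per, `[[`, numeric(1), "rmst")
  se <- vapply(per, `[[`, numeric(1), "se")
  diff <- r[2] - r[1]
  se_diff <- sqrt(sum(se^2))
  z <- if (se_diff > 0) diff / se_diff else 0
  structure(list(
    tau = tau,
    by_group = data.frame(group = groups, rmst = r, se = se,
                          stringsAsFactors = FALSE),
    diff = diff, se_diff = se_diff,
    p_value = 2 * stats::pnorm(-abs(z)),
    conf_int = diff + c(-1, 1) * stats::qnorm(0.975) * se_diff),
    class = "rmst_diff")
}

#' @export
print.rmst_diff <- function(x, ...) {
  cat(sprintf("RMST at tau = %.3g years:\n", x$tau))
  for (i in seq_len(nrow(x$by_group)))
    cat(sprintf("  %-12s %.3f (se %.3f)\n", x$by_group$group[i],
                x$by_group$rmst[i], x$by_group$se[i]))
  cat(sprintf("  difference = %.3f years (95%% CI %.3f to %.3f), p = %s\n",
              x$diff, x$conf_int[1], x$conf_int[2], format.pval(x$p_value)))
  invisible(x)
}

#' Cox proportional hazards fit
#'
#' Partial-likelihood Cox regression with the Efron approximation for tied
#' event times (ties are common on a yearly visit grid), returning per
#' covariate the coefficient, hazard ratio, Wald 95% CI and p-value.
#'
#' @param time,event As in [km_estimate()].
#' @param covariates Data frame of covariates (one column per term;
#'   character/factor columns are treated as factors).
#' @return A list of class `cox_result` with `table` (data frame:
#'   `term`, `coef`, `hr`, `lower`, `upper`, `p_value`), `n_events`, and
#'   the underlying `coxph` fit.
#' @export
cox_fit <- function(time, event, covariates) {
  event <- as.integer(as.logical(event))
  if (sum(event) == 0) stop("no events: Cox model undefined")
  covariates <- as.data.frame(covariates)
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(names(covariates), collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = dat, ties = "efron"),
    error = function(e) stop("Cox fit failed: ", conditionMessage(e)),
    warning = function(w) {
      if (grepl("infinite|did not converge", conditionMessage(w)))
        stop("Cox fit did not converge (possible separation): ",
             conditionMessage(w))
      suppressWarnings(survival::coxph(fml, data = dat, ties = "efron"))
    })
  sm <- summary(fit)
  tab <- data.frame(term = rownames(sm$coefficients),
                    coef = sm$coefficients[, "coef"],
                    hr = sm$coefficients[, "exp(coef)"],
                    lower = sm$conf.int[, "lower .95"],
                    upper = sm$conf.int[, "upper .95"],
                    p_value = sm$coefficients[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, n_events = sum(event), fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox proportional hazards (Efron ties), %d events:\n", x$n_events))
  tb <- x$table
  for (i in seq_len(nrow(tb)))
    cat(sprintf("  %-24s HR %.3f (95%% CI %.3f-%.3f), p = %s\n",
                tb$term[i], tb$hr[i], tb$lower[i], tb$upper[i],
                format.pval(tb$p_value[i])))
  invisible(x)
}

#' Subgroup hazard ratios and arm-by-covariate interactions
#'
#' For each candidate covariate, fits a Cox model with the arm, the
#' covariate and their interaction, reports the arm hazard ratio within
#' each covariate level (with Wald CI), and the Wald p-value of the
#' interaction. Continuous covariates named in `dichotomize` are split at
#' the supplied cut points (default: age at 50 years). Covariate levels
#' with no subjects or no events are skipped with a warning.
#'
#' @param time,event As in [km_estimate()].
#' @param arm Two-level arm labels; the first sorted level is the reference.
#' @param covariates Data frame of subgroup covariates.
#' @param dichotomize Named numeric vector of cut points for continuous
#'   covariates, e.g. `c(age = 50, weight = 70)`; values >= cut form the
#'   upper level.
#' @return Data frame of class `subgroup_table` with columns `covariate`,
#'   `level`, `n`, `n_events`, `hr`, `lower`, `upper`, `interaction_p`
#'   (repeated within covariate), shaped for a forest plot.
#' @export
subgroup_interactions <- function(time, event, arm, covariates,
                                  dichotomize = c(age = 50)) {
  event <- as.integer(as.logical(event))
  arm <- factor(arm)
  if (nlevels(arm) != 2) stop("arm must have exactly two levels")
  covariates <- as.data.frame(covariates)
  rows <- list()
  for (cv in names(covariates)) {
    x <- covariates[[cv]]
    if (is.numeric(x) && cv %in% names(dichotomize)) {
      cut <- dichotomize[[cv]]
      x <- factor(ifelse(x >= cut, sprintf(">=%g", cut), sprintf("<%g", cut)))
    } else x <- factor(x)
    x <- droplevels(x)
    if (nlevels(x) < 2) {
      warning(sprintf("covariate '%s' has a single level: interaction undefined, skipped", cv))
      next
    }
    dat <- data.frame(.time = time, .event = event, .arm = arm, .x = x)
    int_fit <- tryCatch(
      survival::coxph(survival::Surv(.time, .event) ~ .arm * .x, data = dat,
                      ties = "efron"),
      error = function(e) NULL)
    int_p <- NA_real_
    if (!is.null(int_fit)) {
      sm <- summary(int_fit)$coefficients
      int_terms <- grep(":", rownames(sm))
      if (length(int_terms) == 1) int_p <- sm[int_terms, "Pr(>|z|)"]
      else if (length(int_terms) > 1) {
        # multi-df Wald test of all interaction terms
        b <- stats::coef(int_fit)[int_terms]
        V <- stats::vcov(int_fit)[int_terms, int_terms, drop = FALSE]
        w <- tryCatch(drop(t(b) %*% solve(V) %*% b), error = function(e) NA_real_)
        int_p <- stats::pchisq(w, df = length(int_terms), lower.tail = FALSE)
      }
    }
    for (lv in levels(x)) {
      sel <- x == lv
      n <- sum(sel); ne <- sum(event[sel])
      hr <- lo <- up <- NA_real_
      if (ne > 0 && length(unique(arm[sel])) == 2) {
        lf <- tryCatch(cox_fit(time[sel], event[sel],
                               data.frame(arm = arm[sel])),
                       error = function(e) NULL)
        if (!is.null(lf)) {
          hr <- lf$table$hr[1]; lo <- lf$table$lower[1]; up <- lf$table$upper[1]
        }
      } else {
        warning(sprintf("level '%s' of '%s' has no events or a single arm: HR skipped", lv, cv))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cv, level = lv, n = n, n_events = ne,
        hr = hr, lower = lo, upper = up, interaction_p = int_p,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(covariate = character(), level = character(), n = integer(),
               n_events = integer(), hr = numeric(), lower = numeric(),
               upper = numeric(), interaction_p = numeric())
  class(out) <- c("subgroup_table", "data.frame")
  out
}

#' Overall and disease-free survival endpoints
#'
#' Builds the OS and DFS event tables from patient records. OS: event is
#' death from any cause, time is the death time or else the follow-up time.
#' DFS: event is the first of death or any recurrence-type event
#' (local/regional recurrence, metastasis, new primary), time is the
#' earliest such time or else follow-up.
#'
#' @param patients Patient table with `patient_id`, `arm`,
#'   `follow_up_years`, and optional `death_time`, `recurrence_time`
#'   columns (`NA` when the event did not occur).
#' @return A list with `os` and `dfs`, each a data frame `patient_id`,
#'   `arm`, `time`, `event`.
#' @export
os_dfs_endpoints <- function(patients) {
  p <- patients
  stopifnot(all(c("patient_id", "arm", "follow_up_years") %in% names(p)))
  death <- if ("death_time" %in% names(p)) p$death_time else rep(NA_real_, nrow(p))
  recur <- if ("recurrence_time" %in% names(p)) p$recurrence_time else rep(NA_real_, nrow(p))
  os_time <- ifelse(is.na(death), p$follow_up_years, death)
  os_event <- as.integer(!is.na(death))
  dfs_first <- pmin(ifelse(is.na(death), Inf, death),
                    ifelse(is.na(recur), Inf, recur))
  dfs_event <- as.integer(is.finite(dfs_first))
  dfs_time <- ifelse(is.finite(dfs_first), dfs_first, p$follow_up_years)
  list(os = data.frame(patient_id = p$patient_id, arm = p$arm,
                       time = os_time, event = os_event,
                       stringsAsFactors = FALSE),
       dfs = data.frame(patient_id = p$patient_id, arm = p$arm,
                        time = dfs_time, event = dfs_event,
                        stringsAsFactors = FALSE))
}
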