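#' Fit the composite time-to-alteration analysis of a two-arm trial
#'
#' The package's main entry point. From a patient table and a long
#' measurement table it (1) constructs the per-patient composite
#' time-to-alteration endpoint at deterioration fraction `d` (see
#' [compute_composite_tta()]), then (2) analyses it by randomized arm —
#' intention-to-treat, never by treatment received — with Kaplan-Meier
#' curves, the log-rank test, the restricted mean survival time difference
#' at horizon `tau`, and a Cox proportional hazards model of the arm
#' effect; (3) optionally adds subgroup arm-by-covariate interactions and
#' the overall/disease-free survival endpoints.
#'
#' @param patients Patient table (see [read_patients()]).
#' @param measurements Long measurement table (see [read_measurements()]).
#' @param d Deterioration fraction defining the alteration threshold
#'   (default 0.10, i.e. "time to 10% alteration").
#' @param alpha_slope Significance level of the per-patient slope test
#'   (default 0.05).
#' @param tau RMST horizon in years; `NULL` (default) uses the largest
#'   horizon observable in both arms.
#' @param subgroups Character vector of patient-table columns for subgroup
#'   interaction analysis, or `NULL` to skip. Defaults to the standard
#'   covariate list when those columns are present.
#' @param age_cut Dichotomization cut for age in the subgroup analysis
#'   (default 50 years).
#' @param qlq_rule Passed to [compute_composite_tta()].
#' @return An object of class `tta_analysis`: a list with elements `d`,
#'   `tau`, `composite`, `per_indicator`, `km`, `logrank`, `rmst`, `cox`,
#'   `subgroups`, `os`, `dfs`, `n`, `call`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_per_arm = 30, seed = 3))
#' fit <- tta_analysis(cohort$patients, cohort$measurements, d = 0.10)
#' fit
#' @export
tta_analysis <- function(patients, measurements, d = 0.10,
                         alpha_slope = 0.05, tau = NULL,
                         subgroups = NULL, age_cut = 50,
                         qlq_rule = c("category", "raw")) {
  qlq_rule <- match.arg(qlq_rule)
  cl <- match.call()
  res <- compute_composite_tta(patients, measurements, d = d,
                               alpha_slope = alpha_slope, qlq_rule = qlq_rule)
  comp <- res$composite
  stopifnot(nrow(comp) == nrow(patients))  # intention-to-treat contract
  km <- km_estimate(comp$time_years, comp$event, comp$arm)
  lr <- if (sum(comp$event) > 0 && length(unique(comp$arm)) == 2)
    logrank_test(comp$time_years, comp$event, comp$arm) else NULL
  rm <- if (length(unique(comp$arm)) == 2)
    rmst_diff(comp$time_years, comp$event, comp$arm, tau = tau) else NULL
  cox <- if (sum(comp$event) > 0 && length(unique(comp$arm)) == 2)
    tryCatch(cox_fit(comp$time_years, comp$event,
                     data.frame(arm = factor(comp$arm))),
             error = function(e) NULL) else NULL
  if (is.null(subgroups)) {
    std <- c("age", "weight", "laterality", "surgery", "nodal_irradiation",
             "chemo", "trastuzumab", "histological_grade")
    subgroups <- intersect(std, names(patients))
  }
  sg <- NULL
  if (length(subgroups) > 0 && !is.null(cox)) {
    covs <- patients[match(comp$patient_id, patients$patient_id),
                     subgroups, drop = FALSE]
    sg <- suppressWarnings(
      subgroup_interactions(comp$time_years, comp$event, comp$arm, covs,
                            dichotomize = c(age = age_cut, weight = 70)))
  }
  ep <- os_dfs_endpoints(patients)
  structure(list(d = d, alpha_slope = alpha_slope,
                 tau = if (!is.null(rm)) rm$tau else tau,
                 composite = comp, per_indicator = res$per_indicator,
                 km = km, logrank = lr, rmst = rm, cox = cox,
                 subgroups = sg, os = ep$os, dfs = ep$dfs,
                 n = nrow(patients), call = cl),
            class = "tta_analysis")
}

#' Median time free from alteration per arm
#' @param comp Composite event data frame.
#' @return Named numeric vector of KM median times (NA when not reached).
#' @keywords internal
.km_median <- function(comp) {
  sf <- survival::survfit(survival::Surv(time_years, event) ~ arm, data = comp)
  tb <- summary(sf)$table
  if (is.null(dim(tb))) stats::setNames(tb[["median"]], "all")
  else stats::setNames(tb[, "median"], sub("^arm=", "", rownames(tb)))
}

#' @export
print.tta_analysis <- function(x, ...) {
  cat(sprintf("Composite time-to-alteration analysis (d = %g%%)\n", 100 * x$d))
  cat(sprintf("  %d patients; %d composite events\n",
              x$n, sum(x$composite$event)))
  med <- .km_median(x$composite)
  for (g in names(med))
    cat(sprintf("  median time free from alteration, %s: %s years\n", g,
                ifelse(is.na(med[g]), "not reached", format(round(med[g], 2)))))
  if (!is.null(x$logrank))
    cat(sprintf("  log-rank chi-square = %.3f, p = %s\n",
                x$logrank$statistic, format.pval(x$logrank$p_value)))
  if (!is.null(x$rmst))
    cat(sprintf("  RMST difference at tau = %.3g y: %.2f years, p = %s\n",
                x$rmst$tau, x$rmst$diff, format.pval(x$rmst$p_value)))
  if (!is.null(x$cox))
    cat(sprintf("  arm hazard ratio: %.2f (95%% CI %.2f-%.2f), p = %s\n",
                x$cox$table$hr[1], x$cox$table$lower[1], x$cox$table$upper[1],
                format.pval(x$cox$table$p_value[1])))
  invisible(x)
}

#' @export
summary.tta_analysis <- function(object, ...) {
  comp <- object$composite
  by_arm <- split(comp, comp$arm)
  counts <- data.frame(
    arm = names(by_arm),
    n = vapply(by_arm, nrow, integer(1)),
    events = vapply(by_arm, function(d) sum(d$event), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  comp_tab <- table(comp$component[comp$event == 1])
  out <- list(d = object$d, counts = counts,
              components = comp_tab,
              median = .km_median(comp),
              logrank = object$logrank, rmst = object$rmst,
              cox = object$cox, subgroups = object$subgroups)
  class(out) <- "summary.tta_analysis"
  out
}

#' @export
print.summary.tta_analysis <- function(x, ...) {
  cat(sprintf("Composite time-to-alteration, d = %g%%\n\n", 100 * x$d))
  print(x$counts, row.names = FALSE)
  cat("\nTriggering components among events:\n")
  print(x$components)
  cat("\nMedian time free from alteration (years):\n")
  print(round(x$median, 2))
  if (!is.null(x$logrank))
    cat(sprintf("\nLog-rank: chi-square = %.3f, p = %s\n",
                x$logrank$statistic, format.pval(x$logrank$p_value)))
  if (!is.null(x$rmst)) { cat("\n"); print(x$rmst) }
  if (!is.null(x$cox)) { cat("\n"); print(x$cox) }
  if (!is.null(x$subgroups) && nrow(x$subgroups) > 0) {
    cat("\nSubgroup arm hazard ratios (interaction p per covariate):\n")
    print(format(x$subgroups, digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.tta_analysis <- function(object, ...) {
  if (is.null(object$cox)) return(numeric(0))
  stats::setNames(object$cox$table$coef, object$cox$table$term)
}

#' Plot the Kaplan-Meier curves of the composite endpoint
#'
#' Step curves of the probability of remaining free from the composite
#' lung-heart alteration, one line per arm.
#'
#' @param x A [tta_analysis()] object.
#' @param main Plot title.
#' @param col Colors, one per arm.
#' @param ... Passed to [plot()].
#' @export
plot.tta_analysis <- function(x, main = sprintf(
                                "Freedom from %g%% lung-heart alteration",
                                100 * x$d),
                              col = c("firebrick", "navy"), ...) {
  comp <- x$composite
  sf <- survival::survfit(survival::Surv(time_years, event) ~ arm, data = comp)
  graphics::plot(sf, col = col, lwd = 2, xlab = "Years from randomization",
                 ylab = "Probability free from alteration", main = main, ...)
  graphics::legend("topright", legend = sub("^arm=", "", names(sf$strata)),
                   col = col, lwd = 2, bty = "n")
  invisible(x)
}

#' Residuals of the per-patient trajectory construction
#'
#' Returns, per patient and continuous indicator, the difference between the
#' observed measurements and the fitted per-patient line — a diagnostic for
#' the linearity assumption behind the threshold-crossing estimator.
#'
#' @param object A [tta_analysis()] object (must have been fitted with the
#'   default indicator set).
#' @param patients,measurements The tables the object was fitted on.
#' @param ... Unused.
#' @return Data frame `patient_id`, `indicator`, `time_years`, `residual`.
#' @export
residuals.tta_analysis <- function(object, patients, measurements, ...) {
  inds <- .default_indicators()
  out <- list()
  for (pid in patients$patient_id) {
    pm <- measurements[measurements$patient_id == pid, , drop = FALSE]
    series <- function(ind) {
      s <- pm[pm$indicator == ind, , drop = FALSE]
      s <- s[order(s$time_years), , drop = FALSE]
      list(times = s$time_years, values = s$value)
    }
    blocks <- c(
      lapply(inds$lung_ratio, function(pair) {
        a <- series(pair[1]); b <- series(pair[2])
        suppressWarnings(derive_ratio_series(a$times, a$values,
                                             b$times, b$values))
      }),
      stats::setNames(lapply(c(inds$lung_direct, inds$heart), series),
                      c(inds$lung_direct, inds$heart)))
    for (nm in names(blocks)) {
      s <- blocks[[nm]]
      if (length(s$times) < 2 || length(unique(s$times)) < 2) next
      f <- fit_trajectory(s$times, s$values)
      out[[length(out) + 1L]] <- data.frame(
        patient_id = pid, indicator = nm, time_years = s$times,
        residual = s$values - (f$intercept + f$slope * s$times),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(patient_id = character(), indicator = character(),
               time_years = numeric(), residual = numeric())
}

#' Deterioration-threshold sensitivity sweep
#'
#' Re-runs the composite time-to-alteration analysis over a grid of
#' deterioration fractions `d` and summarizes, per threshold, the event
#' counts, median times, RMST difference and arm hazard ratio. A more
#' lenient threshold (larger `d`) can only lose events, so event counts are
#' non-increasing in `d`.
#'
#' @param patients,measurements As in [tta_analysis()].
#' @param d_list Thresholds in (0, 1); default `c(0.10, 0.20, 0.40, 0.60)`.
#' @param ... Passed to [tta_analysis()].
#' @return Data frame of class `tta_sweep`: one row per `d` with columns
#'   `d`, `events`, `events_by_arm` columns, `median_*`, `rmst_diff`,
#'   `rmst_p`, `hr`, `hr_lower`, `hr_upper`, `logrank_p`.
#' @export
sensitivity_sweep <- function(patients, measurements,
                              d_list = c(0.10, 0.20, 0.40, 0.60), ...) {
  stopifnot(all(d_list > 0 & d_list < 1), !anyDuplicated(d_list))
  rows <- lapply(d_list, function(d) {
    fit <- tta_analysis(patients, measurements, d = d, ...)
    comp <- fit$composite
    arms <- sort(unique(comp$arm))
    ev_by <- unname(vapply(arms, function(a) sum(comp$event[comp$arm == a]),
                           numeric(1)))
    med <- unname(.km_median(comp))
    data.frame(
      d = d, events = sum(comp$event),
      events_arm1 = ev_by[1],
      events_arm2 = if (length(ev_by) > 1) ev_by[2] else NA_real_,
      median_arm1 = med[1],
      median_arm2 = if (length(med) > 1) med[2] else NA_real_,
      rmst_diff = if (!is.null(fit$rmst)) fit$rmst$diff else NA_real_,
      rmst_p = if (!is.null(fit$rmst)) fit$rmst$p_value else NA_real_,
      hr = if (!is.null(fit$cox)) fit$cox$table$hr[1] else NA_real_,
      hr_lower = if (!is.null(fit$cox)) fit$cox$table$lower[1] else NA_real_,
      hr_upper = if (!is.null(fit$cox)) fit$cox$table$upper[1] else NA_real_,
      logrank_p = if (!is.null(fit$logrank)) fit$logrank$p_value else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "arms") <- sort(unique(patients$arm))
  class(out) <- c("tta_sweep", "data.frame")
  out
}
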