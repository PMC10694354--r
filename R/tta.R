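#' Per-patient least-squares trajectory fit
#'
#' Fits an ordinary least-squares line of an indicator's values on time for
#' a single patient and reports the slope, intercept, the two-sided t-test
#' p-value for slope = 0, the number of points and the residual standard
#' deviation. With exactly two points the slope p-value is undefined
#' (`NA`), which downstream is treated as "no significant decline".
#'
#' @param times Measurement times in years; at least two distinct values.
#' @param values Measurements aligned with `times`.
#' @return A list of class `trajectory_fit` with `slope`, `intercept`,
#'   `slope_p`, `n_points`, `residual_sd`.
#' @examples
#' fit_trajectory(0:3, c(100, 95, 90, 85))  # slope -5, intercept 100
#' @export
fit_trajectory <- function(times, values) {
  stopifnot(length(times) == length(values))
  ok <- is.finite(times) & is.finite(values)
  times <- times[ok]; values <- values[ok]
  if (length(times) < 2) stop("need at least 2 measurement points")
  if (length(unique(times)) < 2) stop("all measurement times are equal")
  fit <- stats::lm(values ~ times)
  cf <- stats::coef(fit)
  n <- length(times)
  rsd <- if (n > 2) sqrt(sum(stats::residuals(fit)^2) / (n - 2)) else 0
  slope_p <- NA_real_
  if (n > 2) {
    sxx <- sum((times - mean(times))^2)
    se <- rsd / sqrt(sxx)
    scale <- max(abs(values), 1)
    slope_p <- if (rsd <= 1e-8 * scale) {
      # numerically exact line: the slope is known without error
      if (abs(cf[2]) <= 1e-8 * scale) 1 else 0
    } else {
      2 * stats::pt(abs(cf[2] / se), df = n - 2, lower.tail = FALSE)
    }
  }
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 slope_p = unname(slope_p), n_points = n, residual_sd = rsd),
            class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("Trajectory fit: slope %.4g /year, intercept %.4g, p(slope) = %s, n = %d\n",
              x$slope, x$intercept,
              if (is.na(x$slope_p)) "NA" else format.pval(x$slope_p), x$n_points))
  invisible(x)
}

#' Time to d% alteration for one fitted trajectory
#'
#' Given a patient's fitted linear trajectory for an indicator whose decline
#' signals deterioration, computes the time at which the fitted line crosses
#' the threshold `(1 - d) * baseline`. The patient is censored at their
#' actual follow-up time when the regression shows no significant decline
#' (non-negative slope, or slope p-value at or above `alpha_slope`, or an
#' undefined p-value), or when the crossing time exceeds follow-up. A
#' negative crossing time (fitted line already below threshold at t = 0,
#' possible with noisy baselines) is recorded as an event at time 0.
#'
#' @param fit A [fit_trajectory()] result.
#' @param baseline Baseline value anchoring the threshold; must be positive.
#' @param d Deterioration fraction in (0, 1); default 0.10.
#' @param follow_up The patient's follow-up time in years; must be positive.
#' @param alpha_slope Significance level for the slope test (default 0.05).
#' @return A list of class `tta_result` with `event` (logical),
#'   `time_years`, `censor_reason` (`"event"`, `"no_significant_decline"`,
#'   or `"beyond_follow_up"`), `baseline_value`, `threshold_value`.
#' @examples
#' f <- fit_trajectory(0:3, c(100, 95, 90, 85))
#' time_to_alteration(f, baseline = 100, d = 0.10, follow_up = 12)  # event at 2
#' @export
time_to_alteration <- function(fit, baseline, d = 0.10, follow_up,
                               alpha_slope = 0.05) {
  stopifnot(inherits(fit, "trajectory_fit"))
  if (!(d > 0 && d < 1)) stop("d must be in (0, 1)")
  if (!(follow_up > 0)) stop("follow_up must be positive")
  if (!(baseline > 0)) stop("baseline must be positive")
  threshold <- (1 - d) * baseline
  significant_decline <- fit$slope < 0 &&
    !is.na(fit$slope_p) && fit$slope_p < alpha_slope
  if (!significant_decline) {
    res <- list(event = FALSE, time_years = follow_up,
                censor_reason = "no_significant_decline")
  } else {
    t_star <- (threshold - fit$intercept) / fit$slope
    if (t_star > follow_up) {
      res <- list(event = FALSE, time_years = follow_up,
                  censor_reason = "beyond_follow_up")
    } else {
      res <- list(event = TRUE, time_years = max(t_star, 0),
                  censor_reason = "event")
    }
  }
  res$baseline_value <- baseline
  res$threshold_value <- threshold
  structure(res, class = "tta_result")
}

#' First ordinal deterioration above baseline
#'
#' For an ordinal series (RTOG grades, or symptom categories), returns the
#' first visit time whose grade exceeds the baseline grade; if none does,
#' the patient is censored at follow-up. Grades may be integers or ordered
#' factors.
#'
#' @param times Visit times in years, aligned with `grades`.
#' @param grades Ordinal values (numeric or ordered factor).
#' @param baseline_grade Reference grade; defaults to the grade at the
#'   earliest visit.
#' @param follow_up Censoring time in years.
#' @return A list with `event` (logical) and `time_years`.
#' @examples
#' ordinal_event_time(0:3, c(0, 0, 1, 1), follow_up = 12)  # event at 2
#' @export
ordinal_event_time <- function(times, grades, baseline_grade = NULL,
                               follow_up) {
  stopifnot(length(times) == length(grades), follow_up > 0)
  if (length(times) == 0)
    return(list(event = FALSE, time_years = follow_up))
  o <- order(times)
  times <- times[o]
  g <- if (is.ordered(grades)) as.integer(grades[o]) else as.numeric(grades[o])
  b <- if (is.null(baseline_grade)) g[1]
       else if (is.ordered(baseline_grade) || is.factor(baseline_grade))
         as.integer(baseline_grade) else as.numeric(baseline_grade)
  hit <- which(g > b)
  if (length(hit) == 0) list(event = FALSE, time_years = follow_up)
  else list(event = TRUE, time_years = times[hit[1]])
}

#' Per-visit ratio of two indicator series
#'
#' Pairs two indicator series by visit time and returns the per-visit
#' ratio (e.g. FEV1/FVC, DLCO/VA). Visits missing either member are
#' dropped; visits with a zero denominator are dropped with a warning.
#'
#' @param times_num,values_num Times and values of the numerator series.
#' @param times_den,values_den Times and values of the denominator series.
#' @return A list with `times` and `values` of the ratio series.
#' @examples
#' derive_ratio_series(0, 2.44, 0, 3.26)$values  # 0.749
#' @export
derive_ratio_series <- function(times_num, values_num, times_den, values_den) {
  stopifnot(length(times_num) == length(values_num),
            length(times_den) == length(values_den))
  common <- intersect(times_num, times_den)
  if (length(common) == 0) return(list(times = numeric(0), values = numeric(0)))
  common <- sort(common)
  num <- values_num[match(common, times_num)]
  den <- values_den[match(common, times_den)]
  zero <- den == 0
  if (any(zero)) {
    warning(sprintf("%d visit(s) dropped: zero denominator", sum(zero)))
    common <- common[!zero]; num <- num[!zero]; den <- den[!zero]
  }
  list(times = common, values = num / den)
}

#' Composite first-event from per-component results
#'
#' Combines the per-component event results of one patient (lung TTA, heart
#' TTA, RTOG grade increase, fatigue-dyspnea increase) into the composite
#' toxicity event: the earliest component event time, or censoring at
#' follow-up when no component fires. Ties are labelled by the fixed
#' precedence lung_tta > heart_tta > rtog_increase >
#' fatigue_dyspnea_increase; precedence affects the label only, never the
#' time.
#'
#' @param components Named list of lists, each with `event` and
#'   `time_years`; names drawn from `lung_tta`, `heart_tta`,
#'   `rtog_increase`, `fatigue_dyspnea_increase`. Missing components are
#'   treated as censored.
#' @param follow_up Censoring time in years.
#' @return A list of class `composite_event` with `event`, `time_years`,
#'   and `component` (the triggering component, or `"censored"`).
#' @export
composite_tta <- function(components, follow_up) {
  stopifnot(follow_up > 0)
  precedence <- c("lung_tta", "heart_tta", "rtog_increase",
                  "fatigue_dyspnea_increase")
  unknown <- setdiff(names(components), precedence)
  if (length(unknown))
    stop("unknown component(s): ", paste(unknown, collapse = ", "))
  times <- rep(Inf, length(precedence))
  names(times) <- precedence
  for (nm in names(components)) {
    cmp <- components[[nm]]
    if (isTRUE(cmp$event)) times[nm] <- cmp$time_years
  }
  if (all(!is.finite(times))) {
    res <- list(event = FALSE, time_years = follow_up, component = "censored")
  } else {
    tmin <- min(times)
    winner <- precedence[which(times == tmin)[1]]
    res <- list(event = TRUE, time_years = tmin, component = winner)
  }
  structure(res, class = "composite_event")
}

## Default composite indicator sets: lung ratios + TLC, LVEF for the heart,
## RTOG clinician grades and the two QLQ symptom categories.
.default_indicators <- function() {
  list(lung_ratio = list(FEV1_FVC = c("FEV1", "FVC"),
                         DLCO_VA  = c("DLCO", "VA")),
       lung_direct = "TLC",
       heart = "LVEF",
       rtog = c("RTOG_LUNG", "RTOG_HEART"),
       qlq = c("FATIGUE_RAW", "DYSPNEA_RAW"))
}

.continuous_component <- function(times, values, d, follow_up, alpha_slope) {
  if (length(times) < 2 || length(unique(times)) < 2)
    return(list(event = FALSE, time_years = follow_up,
                censor_reason = "no_significant_decline",
                baseline_value = NA_real_, threshold_value = NA_real_,
                slope = NA_real_, intercept = NA_real_, slope_p = NA_real_,
                n_points = length(times)))
  fit <- fit_trajectory(times, values)
  base <- values[times == 0]
  base <- if (length(base)) base[1] else fit$intercept
  if (!is.finite(base) || base <= 0)
    return(list(event = FALSE, time_years = follow_up,
                censor_reason = "no_significant_decline",
                baseline_value = base, threshold_value = NA_real_,
                slope = fit$slope, intercept = fit$intercept,
                slope_p = fit$slope_p, n_points = fit$n_points))
  res <- time_to_alteration(fit, base, d = d, follow_up = follow_up,
                            alpha_slope = alpha_slope)
  c(unclass(res), list(slope = fit$slope, intercept = fit$intercept,
                       slope_p = fit$slope_p, n_points = fit$n_points))
}

#' Composite time-to-alteration for every patient of a cohort
#'
#' Runs the full per-patient endpoint construction: least-squares
#' trajectories of the continuous indicators (the lung ratios FEV1/FVC and
#' DLCO/VA, TLC, and LVEF for the heart), threshold-crossing times at
#' deterioration fraction `d`, ordinal first-increase times for the RTOG
#' lung/heart grades and for the QLQ fatigue/dyspnea categories, and the
#' composite first event per patient. Every patient contributes a row
#' (intention-to-treat): patients with no usable series are censored at
#' follow-up.
#'
#' @param patients Patient table with `patient_id`, `arm`,
#'   `follow_up_years` (see [read_patients()]).
#' @param measurements Long measurement table (see [read_measurements()]).
#' @param d Deterioration fraction in (0, 1); default 0.10.
#' @param alpha_slope Significance level for the per-patient slope test.
#' @param qlq_rule `"category"` (default) flags a fatigue/dyspnea event at
#'   the first visit whose mild/moderate/severe category exceeds the
#'   baseline category; `"raw"` uses any raw-score increase above baseline.
#' @param indicators Indicator set specification as returned by the internal
#'   default; override to add or remove components.
#' @return A list with `composite` (data frame: `patient_id`, `arm`,
#'   `time_years`, `event` (0/1), `component`) and `per_indicator` (data
#'   frame of per-patient, per-indicator TTA results including fitted slope,
#'   intercept, slope p-value, event flag, time, and censor reason).
#' @export
compute_composite_tta <- function(patients, measurements, d = 0.10,
                                  alpha_slope = 0.05,
                                  qlq_rule = c("category", "raw"),
                                  indicators = .default_indicators()) {
  qlq_rule <- match.arg(qlq_rule)
  stopifnot(all(c("patient_id", "arm", "follow_up_years") %in% names(patients)))
  meas_split <- split(measurements,
                      factor(measurements$patient_id,
                             levels = patients$patient_id))
  comp_rows <- vector("list", nrow(patients))
  ind_rows <- vector("list", nrow(patients))
  for (i in seq_len(nrow(patients))) {
    pid <- patients$patient_id[i]
    fu <- patients$follow_up_years[i]
    pm <- meas_split[[i]]
    series <- function(ind) {
      s <- pm[pm$indicator == ind, , drop = FALSE]
      s <- s[order(s$time_years), , drop = FALSE]
      list(times = s$time_years, values = s$value)
    }
    per_ind <- list()
    # lung: ratio indicators then direct indicators
    lung <- list()
    for (nm in names(indicators$lung_ratio)) {
      pair <- indicators$lung_ratio[[nm]]
      a <- series(pair[1]); b <- series(pair[2])
      r <- suppressWarnings(derive_ratio_series(a$times, a$values, b$times, b$values))
      lung[[nm]] <- .continuous_component(r$times, r$values, d, fu, alpha_slope)
    }
    for (nm in indicators$lung_direct) {
      s <- series(nm)
      lung[[nm]] <- .continuous_component(s$times, s$values, d, fu, alpha_slope)
    }
    heart <- list()
    for (nm in indicators$heart) {
      s <- series(nm)
      heart[[nm]] <- .continuous_component(s$times, s$values, d, fu, alpha_slope)
    }
    ords <- list()
    for (nm in indicators$rtog) {
      s <- series(nm)
      ords[[nm]] <- ordinal_event_time(s$times, s$values, follow_up = fu)
    }
    for (nm in indicators$qlq) {
      s <- series(nm)
      if (length(s$times) == 0) {
        ords[[nm]] <- list(event = FALSE, time_years = fu)
      } else if (qlq_rule == "category") {
        g <- qlq_category(qlq_scale(s$values))
        ords[[nm]] <- ordinal_event_time(s$times, g, follow_up = fu)
      } else {
        ords[[nm]] <- ordinal_event_time(s$times, s$values, follow_up = fu)
      }
    }
    first_of <- function(lst) {
      ev <- vapply(lst, function(x) isTRUE(x$event), logical(1))
      if (!any(ev)) return(list(event = FALSE, time_years = fu))
      list(event = TRUE,
           time_years = min(vapply(lst[ev], `[[`, numeric(1), "time_years")))
    }
    comps <- list(
      lung_tta = first_of(lung),
      heart_tta = first_of(heart),
      rtog_increase = first_of(ords[indicators$rtog]),
      fatigue_dyspnea_increase = first_of(ords[indicators$qlq]))
    ce <- composite_tta(comps, follow_up = fu)
    comp_rows[[i]] <- data.frame(
      patient_id = pid, arm = patients$arm[i],
      time_years = ce$time_years, event = as.integer(ce$event),
      component = ce$component, stringsAsFactors = FALSE)
    all_ind <- c(lung, heart, ords)
    ind_rows[[i]] <- data.frame(
      patient_id = pid, indicator = names(all_ind),
      event = vapply(all_ind, function(x) isTRUE(x$event), logical(1)),
      time_years = vapply(all_ind, `[[`, numeric(1), "time_years"),
      censor_reason = vapply(all_ind, function(x) {
        if (!is.null(x$censor_reason)) x$censor_reason
        else if (isTRUE(x$event)) "event" else "no_event_observed"
      }, character(1)),
      slope = vapply(all_ind, function(x)
        if (!is.null(x$slope)) x$slope else NA_real_, numeric(1)),
      slope_p = vapply(all_ind, function(x)
        if (!is.null(x$slope_p)) x$slope_p else NA_real_, numeric(1)),
      baseline_value = vapply(all_ind, function(x)
        if (!is.null(x$baseline_value)) x$baseline_value else NA_real_, numeric(1)),
      stringsAsFactors = FALSE)
  }
  list(composite = do.call(rbind, comp_rows),
       per_indicator = do.call(rbind, ind_rows))
}
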