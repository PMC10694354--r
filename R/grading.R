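#' Ordinal deterioration grade for a pulmonary function measurement
#'
#' Maps the percent decline from baseline of a raw pulmonary function value
#' onto CTCAE-adapted grades: declines in (10%, 25%] are grade 1,
#' (25%, 50%] grade 2, (50%, 75%] grade 3, and > 75% grade 4. Declines of
#' 10% or less — including improvements — are grade 0. Intervals are
#' left-open, right-closed, so a decline of exactly 10% is grade 0 and
#' exactly 25% is grade 1.
#'
#' @param baseline Baseline (pre-therapy) value; must be positive.
#' @param value Follow-up value on the same scale; must be positive.
#' @return Integer grade 0-4, vectorized over inputs.
#' @examples
#' pft_grade(2.0, 1.4)  # 30% decline -> grade 2
#' pft_grade(2.0, 1.8)  # exactly 10% -> grade 0
#' @export
pft_grade <- function(baseline, value) {
  if (any(baseline <= 0)) stop("baseline must be positive")
  if (any(value <= 0)) stop("value must be positive")
  decline <- 100 * (baseline - value) / baseline
  .interval_grade(decline, c(10, 25, 50, 75))
}

#' Ordinal deterioration grade for LVEF
#'
#' Grades left ventricular ejection fraction by its change from baseline:
#' drops in (10, 20] map to grade 1, (20, 30] to grade 2, (30, 50] to
#' grade 3, and > 50 to grade 4. By default the change is the absolute drop
#' in percentage points (`baseline - value`), the CTCAE convention for
#' resting ejection fraction; `relative = TRUE` switches to the percent
#' change from baseline for sensitivity analyses.
#'
#' @param baseline Baseline LVEF in percent, in (0, 100].
#' @param value Follow-up LVEF in percent, in (0, 100].
#' @param relative Use relative percent change instead of the absolute
#'   percentage-point drop (default `FALSE`).
#' @return Integer grade 0-4, vectorized.
#' @examples
#' lvef_grade(65, 50)  # 15-point drop -> grade 1
#' lvef_grade(60, 35)  # 25-point drop -> grade 2
#' @export
lvef_grade <- function(baseline, value, relative = FALSE) {
  if (any(baseline <= 0 | baseline > 100)) stop("baseline LVEF must be in (0, 100]")
  if (any(value <= 0 | value > 100)) stop("value LVEF must be in (0, 100]")
  change <- if (relative) 100 * (baseline - value) / baseline else baseline - value
  .interval_grade(change, c(10, 20, 30, 50))
}

## shared half-open interval grading: x <= cuts[1] -> 0, (cuts[k], cuts[k+1]] -> k
.interval_grade <- function(x, cuts) {
  as.integer(findInterval(x, cuts, left.open = TRUE))
}

#' Linear 0-100 scaling of QLQ-C30 raw symptom scores
#'
#' Transforms the raw mean of 4-level QLQ-C30 symptom items to the standard
#' 0-100 scale: `100 * (raw_mean - 1) / item_range`, higher meaning worse
#' symptoms.
#'
#' @param raw_mean Raw item mean, between 1 and `1 + item_range`.
#' @param item_range Range of the item scale (3 for the usual 1-4 items).
#' @return Score on 0-100, vectorized.
#' @examples
#' qlq_scale(1)    # 0
#' qlq_scale(4)    # 100
#' qlq_scale(2.2)  # 40
#' @export
qlq_scale <- function(raw_mean, item_range = 3) {
  stopifnot(item_range > 0)
  if (any(raw_mean < 1 | raw_mean > 1 + item_range))
    stop("raw_mean outside [1, 1 + item_range]")
  100 * (raw_mean - 1) / item_range
}

#' Symptom category from a 0-100 QLQ score
#'
#' Categorizes a scaled fatigue or dyspnea score: \[0, 20\] mild,
#' (20, 40\] moderate, > 40 severe.
#'
#' @param score Scaled score in \[0, 100\].
#' @return Ordered factor with levels `mild < moderate < severe`, vectorized.
#' @examples
#' qlq_category(c(20, 40, 40.1))
#' @export
qlq_category <- function(score) {
  if (any(score < 0 | score > 100)) stop("score outside [0, 100]")
  cat <- ifelse(score <= 20, "mild", ifelse(score <= 40, "moderate", "severe"))
  factor(cat, levels = c("mild", "moderate", "severe"), ordered = TRUE)
}

#' Inverted residual volume
#'
#' Residual volume increases when lung function deteriorates, unlike the
#' other pulmonary indicators. `rv_invert` returns `log(1/rv) = -log(rv)`,
#' a strictly decreasing transform, so that declining values consistently
#' indicate deterioration.
#'
#' @param rv Residual volume in liters; must be positive.
#' @return The transformed value, vectorized.
#' @examples
#' rv_invert(1)      # 0
#' rv_invert(exp(1)) # -1
#' @export
rv_invert <- function(rv) {
  if (any(rv <= 0)) stop("rv must be positive")
  -log(rv)
}

#' Odds of moderate-to-severe versus mild symptom categories
#'
#' Computes `(moderate + severe) / mild` from tabulated category
#' percentages (or counts), rounded to three decimals as conventionally
#' reported.
#'
#' @param percent_mild,percent_moderate,percent_severe Column percentages
#'   (or counts) of the three categories; `percent_mild` must be positive.
#' @return The odds, a numeric scalar.
#' @examples
#' category_odds(55.4, 32.6, 11.9)  # 0.803
#' category_odds(62.4, 24.1, 13.5)  # 0.603
#' @export
category_odds <- function(percent_mild, percent_moderate, percent_severe) {
  stopifnot(percent_mild >= 0, percent_moderate >= 0, percent_severe >= 0)
  if (percent_mild == 0) stop("odds undefined: mild percentage is zero")
  round((percent_moderate + percent_severe) / percent_mild, 3)
}

#' Grade all measurements of a cohort relative to baseline
#'
#' Converts a long measurement table into ordinal grade records, anchored
#' to each patient's baseline (t = 0) value per indicator:
#' \itemize{
#'   \item FEV1, FVC, DLCO, VA, TLC: [pft_grade()] on the raw values;
#'   \item RV: graded through its inverse (percent decline of `1/RV`), so
#'     that rising residual volume registers as deterioration;
#'   \item LVEF: [lvef_grade()] (absolute percentage-point drop by default);
#'   \item RTOG_LUNG, RTOG_HEART: grades used as-is;
#'   \item FATIGUE_RAW, DYSPNEA_RAW: scaled to 0-100 with [qlq_scale()] and
#'     categorized with [qlq_category()].
#' }
#' Measurements of an indicator with no baseline record are dropped with a
#' warning.
#'
#' @param measurements Measurement data frame with columns `patient_id`,
#'   `indicator`, `time_years`, `value` (see [read_measurements()]).
#' @param patients Optional patient data frame supplying the `arm` column
#'   to carry along.
#' @param lvef_relative Passed to [lvef_grade()].
#' @return Data frame with columns `patient_id`, `arm` (if patients given),
#'   `indicator`, `time_years`, `grade` (character: `"0"`-`"4"` or
#'   `"mild"/"moderate"/"severe"`).
#' @export
grade_measurements <- function(measurements, patients = NULL,
                               lvef_relative = FALSE) {
  m <- measurements
  stopifnot(all(c("patient_id", "indicator", "time_years", "value") %in% names(m)))
  pieces <- split(m, interaction(m$patient_id, m$indicator, drop = TRUE))
  out <- vector("list", 0L)
  dropped <- 0L
  for (sub in pieces) {
    sub <- sub[order(sub$time_years), , drop = FALSE]
    ind <- sub$indicator[1]
    if (ind %in% c("RTOG_LUNG", "RTOG_HEART")) {
      grade <- as.character(as.integer(sub$value))
    } else if (ind %in% c("FATIGUE_RAW", "DYSPNEA_RAW")) {
      grade <- as.character(qlq_category(qlq_scale(sub$value)))
    } else {
      b <- sub$value[sub$time_years == 0]
      if (length(b) == 0) { dropped <- dropped + nrow(sub); next }
      b <- b[1]
      grade <- as.character(switch(ind,
        LVEF = lvef_grade(b, sub$value, relative = lvef_relative),
        RV   = pft_grade(1 / b, 1 / sub$value),
        pft_grade(b, sub$value)))
    }
    out[[length(out) + 1L]] <- data.frame(
      patient_id = sub$patient_id, indicator = ind,
      time_years = sub$time_years, grade = grade,
      stringsAsFactors = FALSE)
  }
  if (dropped > 0)
    warning(sprintf("%d measurements dropped: no baseline record for the indicator", dropped))
  g <- if (length(out)) do.call(rbind, out) else
    data.frame(patient_id = character(), indicator = character(),
               time_years = numeric(), grade = character())
  if (!is.null(patients)) {
    g$arm <- patients$arm[match(g$patient_id, patients$patient_id)]
    g <- g[, c("patient_id", "arm", "indicator", "time_years", "grade")]
  }
  g
}

#' Tabulate grades by indicator, period and arm
#'
#' Summarizes grade records as counts and column-wise percentages per
#' indicator x grade x follow-up period x arm, the layout used to report
#' ordinal deterioration and toxicity grades relative to baseline. The
#' period splits measurement times at `split` years (<= split vs > split).
#'
#' @param grades Grade records from [grade_measurements()] (columns
#'   `patient_id`, `arm`, `indicator`, `time_years`, `grade`).
#' @param split Period cut in years (default 5).
#' @return Data frame of class `grade_table` with columns `indicator`,
#'   `period`, `arm`, `grade`, `count`, `percent`; percentages sum to 100
#'   within each indicator x period x arm block.
#' @export
tabulate_grades <- function(grades, split = 5) {
  stopifnot(all(c("arm", "indicator", "time_years", "grade") %in% names(grades)))
  if (nrow(grades) == 0) {
    out <- data.frame(indicator = character(), period = character(),
                      arm = character(), grade = character(),
                      count = integer(), percent = numeric())
    class(out) <- c("grade_table", "data.frame")
    return(out)
  }
  g <- grades
  g$period <- ifelse(g$time_years <= split,
                     sprintf("<=%gy", split), sprintf(">%gy", split))
  tab <- as.data.frame(table(indicator = g$indicator, period = g$period,
                             arm = g$arm, grade = g$grade),
                       stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "count"
  block <- interaction(tab$indicator, tab$period, tab$arm, drop = FALSE)
  totals <- stats::ave(tab$count, block, FUN = sum)
  tab$percent <- ifelse(totals > 0, 100 * tab$count / totals, NA_real_)
  tab <- tab[totals > 0, c("indicator", "period", "arm", "grade", "count", "percent")]
  tab <- tab[order(tab$indicator, tab$period, tab$arm, tab$grade), ]
  rownames(tab) <- NULL
  class(tab) <- c("grade_table", "data.frame")
  tab
}
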