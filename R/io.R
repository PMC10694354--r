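.known_indicators <- c("FEV1", "FVC", "DLCO", "VA", "RV", "TLC", "LVEF",
                       "RTOG_LUNG", "RTOG_HEART", "FATIGUE_RAW", "DYSPNEA_RAW")

#' Read and validate a long measurement CSV
#'
#' Expects a UTF-8 CSV with a header row and columns `patient_id`,
#' `indicator`, `time_years`, `value`. Rows violating the type invariants —
#' unknown indicator code, negative time, non-positive continuous value,
#' RTOG grade outside 0-5 or non-integer, QLQ raw score outside \[1, 4\] —
#' are rejected with a warning naming the offending line numbers.
#'
#' @param path Path to the CSV file.
#' @return Validated measurement data frame.
#' @export
read_measurements <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("patient_id", "indicator", "time_years", "value")
  missing <- setdiff(need, names(m))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  m$patient_id <- as.character(m$patient_id)
  m$indicator <- as.character(m$indicator)
  m$time_years <- as.numeric(m$time_years)
  m$value <- as.numeric(m$value)
  bad <- !(m$indicator %in% .known_indicators)
  bad <- bad | !is.finite(m$time_years) | m$time_years < 0 | !is.finite(m$value)
  cont <- m$indicator %in% c("FEV1", "FVC", "DLCO", "VA", "RV", "TLC", "LVEF")
  bad <- bad | (cont & m$value <= 0)
  rtog <- m$indicator %in% c("RTOG_LUNG", "RTOG_HEART")
  bad <- bad | (rtog & (m$value < 0 | m$value > 5 | m$value != round(m$value)))
  qlq <- m$indicator %in% c("FATIGUE_RAW", "DYSPNEA_RAW")
  bad <- bad | (qlq & (m$value < 1 | m$value > 4))
  bad[is.na(bad)] <- TRUE
  if (any(bad))
    warning(sprintf("rejected %d invalid measurement row(s) at line(s): %s",
                    sum(bad),
                    paste(utils::head(which(bad) + 1L, 20), collapse = ", ")))
  m <- m[!bad, , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Read and validate a patient CSV
#'
#' Expects columns `patient_id`, `arm`, `follow_up_years`; the strata
#' (`nodal_status`, `surgery`, `chemo`), subgroup covariates, `death_time`
#' and `recurrence_time` are carried through when present. Rows with
#' non-positive follow-up or duplicate patient ids are rejected with a
#' warning.
#'
#' @param path Path to the CSV file.
#' @return Validated patient data frame.
#' @export
read_patients <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("patient_id", "arm", "follow_up_years")
  missing <- setdiff(need, names(p))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  p$patient_id <- as.character(p$patient_id)
  p$follow_up_years <- as.numeric(p$follow_up_years)
  bad <- !is.finite(p$follow_up_years) | p$follow_up_years <= 0
  bad <- bad | duplicated(p$patient_id)
  if (any(bad))
    warning(sprintf("rejected %d invalid patient row(s) at line(s): %s",
                    sum(bad),
                    paste(utils::head(which(bad) + 1L, 20), collapse = ", ")))
  p <- p[!bad, , drop = FALSE]
  rownames(p) <- NULL
  p
}

#' Write cohort tables to CSV
#'
#' Writes the patient and measurement tables in the schemas
#' [read_patients()] and [read_measurements()] expect, so that a simulated
#' cohort round-trips identically.
#'
#' @param cohort List with `patients` and `measurements` (as returned by
#'   [simulate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pp <- file.path(dir, "patients.csv")
  mp <- file.path(dir, "measurements.csv")
  utils::write.csv(cohort$patients, pp, row.names = FALSE, na = "")
  utils::write.csv(cohort$measurements, mp, row.names = FALSE, na = "")
  invisible(c(patients = pp, measurements = mp))
}

#' Analysis configuration
#'
#' Collects the user-tunable parameters of [run_pipeline()].
#'
#' @param d Deterioration fraction (default 0.10).
#' @param d_sweep Thresholds of the sensitivity sweep
#'   (default 0.10, 0.20, 0.40, 0.60); must be distinct fractions in (0,1).
#' @param alpha_slope Per-patient slope significance level (default 0.05).
#' @param rmst_tau RMST horizon in years, or `NULL` for the largest horizon
#'   observable in both arms.
#' @param age_cut Age dichotomization for subgroups (default 50 years).
#' @param qlq_rule Patient-reported-outcome event rule (see
#'   [compute_composite_tta()]).
#' @param seed Optional integer seed echoed into the run log.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(d = 0.10, d_sweep = c(0.10, 0.20, 0.40, 0.60),
                            alpha_slope = 0.05, rmst_tau = NULL,
                            age_cut = 50, qlq_rule = "category",
                            seed = NULL) {
  stopifnot(d > 0, d < 1, all(d_sweep > 0 & d_sweep < 1),
            !anyDuplicated(d_sweep), alpha_slope > 0, alpha_slope < 1)
  structure(list(d = d, d_sweep = d_sweep, alpha_slope = alpha_slope,
                 rmst_tau = rmst_tau, age_cut = age_cut,
                 qlq_rule = qlq_rule, seed = seed),
            class = "analysis_config")
}

#' Run the full analysis pipeline and write the report bundle
#'
#' Executes grading (tabulated grade counts by indicator, period and arm),
#' the composite time-to-alteration construction, the survival analyses of
#' the composite endpoint and of OS/DFS, the subgroup interactions, and the
#' threshold sensitivity sweep, writing every table as TSV plus a run log
#' to `output_dir`. The pipeline is a pure function of its inputs: the same
#' tables and config produce byte-identical outputs. No patient is ever
#' excluded (intention-to-treat).
#'
#' @param patients,measurements Input tables (from [read_patients()] /
#'   [read_measurements()] or [simulate_cohort()]).
#' @param config An [analysis_config()].
#' @param output_dir Directory for the report bundle; created if needed.
#' @return Invisibly, a list with the fitted [tta_analysis()] object, the
#'   grade table, the sweep table, and the paths written.
#' @export
run_pipeline <- function(patients, measurements, config = analysis_config(),
                         output_dir) {
  stopifnot(inherits(config, "analysis_config"))
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  log <- character(0)
  log <- c(log, sprintf("config: d=%g sweep=%s alpha_slope=%g tau=%s age_cut=%g qlq_rule=%s seed=%s",
                        config$d, paste(config$d_sweep, collapse = ","),
                        config$alpha_slope,
                        ifelse(is.null(config$rmst_tau), "auto",
                               as.character(config$rmst_tau)),
                        config$age_cut, config$qlq_rule,
                        ifelse(is.null(config$seed), "none",
                               as.character(config$seed))))
  log <- c(log, sprintf("inputs: %d patients, %d measurements",
                        nrow(patients), nrow(measurements)))

  grades <- withCallingHandlers(
    grade_measurements(measurements, patients),
    warning = function(w) {
      log <<- c(log, paste("grading warning:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  grade_tab <- tabulate_grades(grades)
  fit <- tta_analysis(patients, measurements, d = config$d,
                      alpha_slope = config$alpha_slope,
                      tau = config$rmst_tau, age_cut = config$age_cut,
                      qlq_rule = config$qlq_rule)
  if (nrow(fit$composite) != nrow(patients))
    stop("intention-to-treat violation: composite table lost patients")
  log <- c(log, sprintf("composite events: %d of %d patients",
                        sum(fit$composite$event), fit$n))
  sweep <- sensitivity_sweep(patients, measurements,
                             d_list = config$d_sweep,
                             alpha_slope = config$alpha_slope,
                             tau = config$rmst_tau,
                             age_cut = config$age_cut,
                             qlq_rule = config$qlq_rule)

  tsv <- function(x, name) {
    path <- file.path(output_dir, name)
    utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                       quote = FALSE, na = "")
    path
  }
  paths <- c(
    grade_table = tsv(grade_tab, "grade_table.tsv"),
    per_indicator = tsv(fit$per_indicator, "tta_per_indicator.tsv"),
    composite = tsv(fit$composite, "composite_events.tsv"),
    km = tsv(fit$km, "km_curves.tsv"),
    sweep = tsv(sweep, "sweep_summary.tsv"))
  if (!is.null(fit$rmst)) {
    rmst_tab <- data.frame(tau = fit$rmst$tau,
                           group = fit$rmst$by_group$group,
                           rmst = fit$rmst$by_group$rmst,
                           se = fit$rmst$by_group$se,
                           diff = fit$rmst$diff, p = fit$rmst$p_value)
    paths <- c(paths, rmst = tsv(rmst_tab, "rmst_summary.tsv"))
  }
  if (!is.null(fit$cox)) paths <- c(paths, cox = tsv(fit$cox$table, "cox_arm.tsv"))
  if (!is.null(fit$subgroups))
    paths <- c(paths, forest = tsv(fit$subgroups, "forest_subgroups.tsv"))
  ep_os <- fit$os; ep_dfs <- fit$dfs
  paths <- c(paths, os = tsv(ep_os, "os_events.tsv"),
             dfs = tsv(ep_dfs, "dfs_events.tsv"))
  log <- c(log, sprintf("wrote %d tables", length(paths)))
  writeLines(log, file.path(output_dir, "run_log.txt"))
  invisible(list(fit = fit, grade_table = grade_tab, sweep = sweep,
                 paths = paths, log = log))
}
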