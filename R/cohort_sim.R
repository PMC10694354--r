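#' Visit schedule of the toxicity follow-up
#'
#' Lung and heart are assessed at baseline (t = 0), once 1-3 months after
#' therapy (encoded as 0.25 years), and then once yearly. The schedule is
#' truncated at the patient's follow-up time.
#'
#' @param follow_up_years Follow-up duration in years; must be positive.
#' @return Numeric vector of visit times: `c(0, 0.25, 1, 2, ...)` up to
#'   `follow_up_years`.
#' @examples
#' visit_schedule(3.5)  # 0, 0.25, 1, 2, 3
#' @export
visit_schedule <- function(follow_up_years) {
  if (!is.numeric(follow_up_years) || length(follow_up_years) != 1 ||
      !is.finite(follow_up_years) || follow_up_years <= 0)
    stop("follow_up_years must be a positive number")
  v <- c(0, 0.25, seq_len(max(floor(follow_up_years), 0)))
  v[v <= follow_up_years]
}

#' Simulation configuration for a synthetic two-arm trial
#'
#' Bundles the parameters of the synthetic cohort generator. Baseline means
#' and SDs default to the control-arm baseline distribution of a breast
#' radiotherapy trial (e.g. FEV1 2.44 L, SD 0.56); decline dynamics,
#' transition probabilities and censoring hazards are free parameters with
#' defaults chosen to produce a realistic mix of events over a 13-year
#' horizon (see the methods vignette).
#'
#' Continuous trajectories are linear plus Gaussian measurement noise,
#' truncated below at 1% of the indicator's baseline mean; RTOG grades
#' follow a monotone step process with an arm-specific yearly one-grade
#' increase probability; QLQ raw scores drift upwards linearly; dropout,
#' death and recurrence are independent exponentials.
#'
#' @param n_per_arm Patients per arm (>= 2).
#' @param seed Integer seed; identical seed and config give bit-identical
#'   cohorts.
#' @param baseline_mean,baseline_sd Named vectors over the continuous
#'   indicators `FEV1, FVC, DLCO, VA, RV, TLC, LVEF, FATIGUE_RAW,
#'   DYSPNEA_RAW`.
#' @param decline_slope Named list with one numeric vector per arm
#'   (`CRT`, `H-IGRT`), units per year, negative = deterioration (for RV a
#'   positive slope is deterioration; LVEF in percentage points per year).
#' @param noise_sd Named vector of measurement-error SDs per indicator.
#' @param rtog_transition_prob Named per-arm yearly probability of a
#'   one-grade RTOG increase (applies to lung and heart grades).
#' @param qlq_drift Named per-arm yearly mean shift of the raw fatigue and
#'   dyspnea scores.
#' @param max_follow_up Administrative follow-up horizon in years.
#' @param dropout_rate,death_rate,recurrence_rate Exponential hazards per
#'   year.
#' @param p_bias Efron biased-coin parameter used for arm allocation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_arm = 60,
                       seed = 1L,
                       baseline_mean = c(FEV1 = 2.44, FVC = 3.26,
                                         DLCO = 18.74, VA = 4.46, RV = 1.90,
                                         TLC = 5.20, LVEF = 62.62,
                                         FATIGUE_RAW = 1.90,
                                         DYSPNEA_RAW = 1.33),
                       baseline_sd = c(FEV1 = 0.56, FVC = 0.67, DLCO = 3.98,
                                       VA = 0.68, RV = 0.51, TLC = 0.70,
                                       LVEF = 4.54, FATIGUE_RAW = 0.62,
                                       DYSPNEA_RAW = 0.67),
                       decline_slope = list(
                         "CRT" = c(FEV1 = -0.035 * 2.44, FVC = -0.015 * 3.26,
                                   DLCO = -0.035 * 18.74, VA = -0.010 * 4.46,
                                   RV = +0.010 * 1.90, TLC = -0.020 * 5.20,
                                   LVEF = -0.8),
                         "H-IGRT" = c(FEV1 = -0.0175 * 2.44, FVC = -0.0075 * 3.26,
                                      DLCO = -0.0175 * 18.74, VA = -0.005 * 4.46,
                                      RV = +0.005 * 1.90, TLC = -0.010 * 5.20,
                                      LVEF = -0.4)),
                       noise_sd = c(FEV1 = 0.03 * 2.44, FVC = 0.03 * 3.26,
                                    DLCO = 0.03 * 18.74, VA = 0.03 * 4.46,
                                    RV = 0.03 * 1.90, TLC = 0.03 * 5.20,
                                    LVEF = 2.0, FATIGUE_RAW = 0.20,
                                    DYSPNEA_RAW = 0.20),
                       rtog_transition_prob = c("CRT" = 0.05, "H-IGRT" = 0.025),
                       qlq_drift = c("CRT" = 0.06, "H-IGRT" = 0.03),
                       max_follow_up = 13,
                       dropout_rate = 0.03,
                       death_rate = 0.012,
                       recurrence_rate = 0.02,
                       p_bias = 2 / 3) {
  cfg <- list(n_per_arm = as.integer(n_per_arm), seed = as.integer(seed),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              decline_slope = decline_slope, noise_sd = noise_sd,
              rtog_transition_prob = rtog_transition_prob,
              qlq_drift = qlq_drift, max_follow_up = max_follow_up,
              dropout_rate = dropout_rate, death_rate = death_rate,
              recurrence_rate = recurrence_rate, p_bias = p_bias)
  .validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.sim_continuous <- c("FEV1", "FVC", "DLCO", "VA", "RV", "TLC", "LVEF")
.sim_qlq <- c("FATIGUE_RAW", "DYSPNEA_RAW")
.sim_arms <- c("CRT", "H-IGRT")

.validate_sim_config <- function(cfg) {
  if (cfg$n_per_arm < 2) stop("n_per_arm must be >= 2")
  need <- c(.sim_continuous, .sim_qlq)
  for (nm in c("baseline_mean", "baseline_sd", "noise_sd"))
    if (!all(need %in% names(cfg[[nm]])))
      stop(sprintf("%s must name all of: %s", nm, paste(need, collapse = ", ")))
  if (any(cfg$baseline_sd < 0) || any(cfg$noise_sd < 0))
    stop("all SDs must be >= 0")
  if (!all(.sim_arms %in% names(cfg$decline_slope)))
    stop("decline_slope must have components 'CRT' and 'H-IGRT'")
  for (a in .sim_arms)
    if (!all(c(.sim_continuous) %in% names(cfg$decline_slope[[a]])))
      stop("decline_slope per arm must name all continuous indicators")
  rates <- c(cfg$dropout_rate, cfg$death_rate, cfg$recurrence_rate,
             cfg$rtog_transition_prob)
  if (any(rates < 0)) stop("all rates must be >= 0")
  if (any(cfg$rtog_transition_prob > 1)) stop("rtog_transition_prob must be <= 1")
  if (cfg$max_follow_up <= 0) stop("max_follow_up must be positive")
  invisible(cfg)
}

## Stratum label from the three balancing factors.
.stratum_label <- function(nodal, surgery, chemo) {
  paste(nodal, surgery, chemo, sep = "/")
}

#' Simulate a synthetic two-arm trial cohort
#'
#' Generates patient and measurement tables with the longitudinal structure
#' the composite time-to-alteration analysis expects: stratified
#' biased-coin arm allocation, baseline values drawn per patient, linear
#' arm-specific decline plus measurement noise on the continuous
#' indicators, monotone RTOG grade step processes, drifting QLQ raw scores,
#' and exponential dropout/death/recurrence censoring. Strata and subgroup
#' covariates are drawn with frequencies typical of an operated stage I-II
#' breast cancer population.
#'
#' @param config A [sim_config()] object.
#' @return A list with `patients` (one row per patient: `patient_id`,
#'   `arm`, `nodal_status`, `surgery`, `chemo`, `age`, `weight`,
#'   `laterality`, `nodal_irradiation`, `trastuzumab`, `histological_grade`,
#'   `follow_up_years`, `death_time`, `recurrence_time`) and `measurements`
#'   (long table: `patient_id`, `indicator`, `time_years`, `value`).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_per_arm = 5, seed = 7,
#'                                      max_follow_up = 3))
#' head(cohort$measurements)
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  .validate_sim_config(config)
  set.seed(config$seed)
  n <- 2L * config$n_per_arm
  pid <- sprintf("P%04d", seq_len(n))

  # balancing strata (frequencies from a typical operated stage I-II cohort)
  nodal <- ifelse(stats::runif(n) < 0.30, "N+", "N0")
  surgery <- ifelse(stats::runif(n) < 0.37, "mastectomy", "lumpectomy")
  chemo_u <- stats::runif(n)
  chemo <- ifelse(chemo_u < 0.55, "none",
                  ifelse(chemo_u < 0.66, "before RT", "concomitant"))

  # sequential Efron biased-coin allocation over the simulated strata;
  # arm totals are near (not exactly) n_per_arm, as in an actual accrual
  arm <- character(n)
  coin <- efron_coin(arms = .sim_arms, p_bias = config$p_bias)
  for (i in seq_len(n)) {
    drawn <- efron_assign(coin, .stratum_label(nodal[i], surgery[i], chemo[i]))
    coin <- drawn$state
    arm[i] <- drawn$arm
  }

  # subgroup covariates
  age <- pmin(pmax(stats::rnorm(n, 56.5, 11.5), 30), 85)
  weight <- pmin(pmax(stats::rnorm(n, 68, 14), 40), 120)
  laterality <- ifelse(stats::runif(n) < 0.55, "left", "right")
  nodal_irr <- nodal == "N+" | stats::runif(n) < 0.05
  trastuzumab <- stats::runif(n) < 0.10
  hist_grade <- sample(1:3, n, replace = TRUE, prob = c(0.29, 0.46, 0.25))

  # censoring processes
  rexp_or_inf <- function(rate) if (rate > 0) stats::rexp(n, rate) else rep(Inf, n)
  dropout <- rexp_or_inf(config$dropout_rate)
  death <- rexp_or_inf(config$death_rate)
  recurrence <- rexp_or_inf(config$recurrence_rate)
  follow_up <- pmin(config$max_follow_up, dropout, death)
  death_time <- ifelse(death <= pmin(config$max_follow_up, dropout),
                       death, NA_real_)
  recurrence_time <- ifelse(recurrence <= follow_up, recurrence, NA_real_)

  patients <- data.frame(
    patient_id = pid, arm = arm, nodal_status = nodal, surgery = surgery,
    chemo = chemo, age = age, weight = weight, laterality = laterality,
    nodal_irradiation = nodal_irr, trastuzumab = trastuzumab,
    histological_grade = hist_grade, follow_up_years = follow_up,
    death_time = death_time, recurrence_time = recurrence_time,
    stringsAsFactors = FALSE)

  # visit grid (long): all patients on the master schedule, truncated per patient
  master <- visit_schedule(config$max_follow_up)
  grid_pid <- rep(pid, each = length(master))
  grid_t <- rep(master, times = n)
  keep <- grid_t <= rep(follow_up, each = length(master))
  grid_pid <- grid_pid[keep]; grid_t <- grid_t[keep]
  grid_i <- match(grid_pid, pid)
  N <- length(grid_t)

  meas <- vector("list", length(c(.sim_continuous, .sim_qlq)) + 2L)
  k <- 0L

  # continuous indicators: baseline_i + slope_arm * t + noise, floored
  b0 <- sapply(c(.sim_continuous, .sim_qlq), function(ind)
    stats::rnorm(n, config$baseline_mean[[ind]], config$baseline_sd[[ind]]))
  for (ind in .sim_continuous) {
    base_i <- pmax(b0[, ind], 0.01 * config$baseline_mean[[ind]])
    slope_i <- vapply(arm, function(a) config$decline_slope[[a]][[ind]],
                      numeric(1))
    val <- base_i[grid_i] + slope_i[grid_i] * grid_t +
      stats::rnorm(N, 0, config$noise_sd[[ind]])
    val <- pmax(val, 0.01 * config$baseline_mean[[ind]])
    if (ind == "LVEF") val <- pmin(val, 100)
    k <- k + 1L
    meas[[k]] <- data.frame(patient_id = grid_pid, indicator = ind,
                            time_years = grid_t, value = val,
                            stringsAsFactors = FALSE)
  }

  # QLQ raw scores: baseline + drift * t + noise, clamped to [1, 4]
  for (ind in .sim_qlq) {
    base_i <- pmin(pmax(b0[, ind], 1), 4)
    drift_i <- config$qlq_drift[arm]
    val <- base_i[grid_i] + drift_i[grid_i] * grid_t +
      stats::rnorm(N, 0, config$noise_sd[[ind]])
    val <- pmin(pmax(val, 1), 4)
    k <- k + 1L
    meas[[k]] <- data.frame(patient_id = grid_pid, indicator = ind,
                            time_years = grid_t, value = val,
                            stringsAsFactors = FALSE)
  }

  # RTOG grades: monotone step process, one-grade increase per year w.p. p_arm
  y_max <- max(floor(config$max_follow_up), 1)
  for (ind in c("RTOG_LUNG", "RTOG_HEART")) {
    p_i <- config$rtog_transition_prob[arm]
    inc <- matrix(stats::rbinom(n * y_max, 1, rep(p_i, times = y_max)),
                  nrow = n, ncol = y_max)
    cum <- if (y_max == 1L) inc else t(apply(inc, 1, cumsum))
    yr <- floor(grid_t)
    grade <- ifelse(yr >= 1, cum[cbind(grid_i, pmax(yr, 1))], 0)
    grade <- pmin(grade, 5)
    k <- k + 1L
    meas[[k]] <- data.frame(patient_id = grid_pid, indicator = ind,
                            time_years = grid_t, value = as.numeric(grade),
                            stringsAsFactors = FALSE)
  }

  measurements <- do.call(rbind, meas)
  measurements <- measurements[order(measurements$patient_id,
                                     measurements$indicator,
                                     measurements$time_years), ]
  rownames(measurements) <- NULL
  list(patients = patients, measurements = measurements)
}
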