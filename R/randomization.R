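#' Two-proportion sample size with continuity correction
#'
#' Computes the number of patients per arm needed to detect a difference
#' between two proportions with a two-sided normal-approximation test. The
#' default applies the Fleiss continuity correction to the pooled-variance
#' uncorrected sample size, the convention under which a 25% vs 5% toxicity
#' hypothesis at alpha = 0.05 and power 0.80 requires 59 patients per arm
#' (118 in total).
#'
#' The uncorrected per-arm size is
#' \deqn{n = \frac{\left(z_{\alpha/2}\sqrt{2\bar p \bar q} +
#'   z_\beta\sqrt{p_1 q_1 + p_2 q_2}\right)^2}{(p_1-p_2)^2}}
#' with \eqn{\bar p = (p_1+p_2)/2}, and the continuity-corrected size is
#' \deqn{n' = \frac{n}{4}\left(1 + \sqrt{1 + \frac{4}{n\,|p_1-p_2|}}\right)^2.}
#'
#' @param p_control Anticipated event proportion in the control arm.
#' @param p_experimental Anticipated event proportion in the experimental arm.
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Desired power, 1 - beta (default 0.80).
#' @param continuity_correction Apply the Fleiss correction (default `TRUE`).
#'   Without it the same hypothesis gives 49 per arm; the corrected size is
#'   the one that matches standard trial-design practice for chi-square
#'   tests with continuity correction.
#' @return A list of class `sample_size` with elements `n_per_arm`,
#'   `n_total`, and the inputs.
#' @examples
#' required_sample_size(0.25, 0.05)            # 59 per arm, 118 total
#' required_sample_size(0.25, 0.05, continuity_correction = FALSE)
#' @export
required_sample_size <- function(p_control, p_experimental,
                                 alpha = 0.05, power = 0.80,
                                 continuity_correction = TRUE) {
  stopifnot(length(p_control) == 1, length(p_experimental) == 1,
            p_control > 0, p_control < 1,
            p_experimental > 0, p_experimental < 1,
            alpha > 0, alpha < 1, power > 0, power < 1)
  if (p_control == p_experimental)
    stop("p_control and p_experimental are equal: no detectable effect")
  p1 <- p_control; p2 <- p_experimental
  pbar <- (p1 + p2) / 2
  delta <- abs(p1 - p2)
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  n <- (za * sqrt(2 * pbar * (1 - pbar)) +
        zb * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2 / delta^2
  if (continuity_correction)
    n <- (n / 4) * (1 + sqrt(1 + 4 / (n * delta)))^2
  n_per_arm <- as.integer(ceiling(n))
  structure(list(n_per_arm = n_per_arm, n_total = 2L * n_per_arm,
                 n_exact = n, p_control = p1, p_experimental = p2,
                 alpha = alpha, power = power,
                 continuity_correction = continuity_correction),
            class = "sample_size")
}

#' @export
print.sample_size <- function(x, ...) {
  cat(sprintf(
    "Two-proportion sample size (%s):\n  p1 = %.3f vs p2 = %.3f, alpha = %.3f (two-sided), power = %.2f\n  n per arm = %d, total = %d\n",
    if (x$continuity_correction) "continuity-corrected" else "uncorrected",
    x$p_control, x$p_experimental, x$alpha, x$power, x$n_per_arm, x$n_total))
  invisible(x)
}

#' Efron's biased-coin state
#'
#' Creates the bookkeeping object for stratified biased-coin randomization:
#' per-stratum counts of assignments to each of two arms plus the bias
#' parameter. With balanced within-stratum counts the next patient is
#' assigned by a fair coin; otherwise the under-represented arm is chosen
#' with probability `p_bias` (Efron's classical value 2/3 by default).
#'
#' @param arms Character vector of the two arm labels.
#' @param p_bias Probability of assigning the under-represented arm when the
#'   stratum is imbalanced; must lie in \[0.5, 1\]. 0.5 reduces to simple
#'   randomization.
#' @return A list of class `efron_coin` with `arms`, `p_bias`, and `counts`
#'   (an environment-free named list, one two-vector per stratum seen).
#' @seealso [efron_assign()]
#' @export
efron_coin <- function(arms = c("CRT", "H-IGRT"), p_bias = 2 / 3) {
  stopifnot(length(arms) == 2, !anyDuplicated(arms),
            p_bias >= 0.5, p_bias <= 1)
  structure(list(arms = arms, p_bias = p_bias, counts = list()),
            class = "efron_coin")
}

#' Assign one patient with Efron's biased coin
#'
#' Draws the arm for the next patient in a given stratum and returns the
#' updated coin state. Uses R's global random number stream, so seed the
#' session for reproducible allocation sequences.
#'
#' @param state An [efron_coin()] object.
#' @param stratum A character scalar identifying the stratum combination
#'   (e.g. `"N+/mastectomy/concomitant"`); each distinct value is balanced
#'   independently.
#' @return A list with `arm` (the assigned label) and `state` (the updated
#'   coin).
#' @examples
#' set.seed(1)
#' coin <- efron_coin()
#' a <- efron_assign(coin, "N0/lumpectomy/none")
#' a$arm
#' @export
efron_assign <- function(state, stratum) {
  stopifnot(inherits(state, "efron_coin"), is.character(stratum),
            length(stratum) == 1)
  cnt <- state$counts[[stratum]]
  if (is.null(cnt)) cnt <- c(0L, 0L)
  p_first <- if (cnt[1] == cnt[2]) 0.5
             else if (cnt[1] < cnt[2]) state$p_bias
             else 1 - state$p_bias
  idx <- if (stats::runif(1) < p_first) 1L else 2L
  cnt[idx] <- cnt[idx] + 1L
  state$counts[[stratum]] <- cnt
  list(arm = state$arms[idx], state = state)
}
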