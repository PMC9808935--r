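#' Beta distribution parameters from a mean and standard deviation
#'
#' Method-of-moments parameterization used for utility weights in the
#' probabilistic sensitivity analysis. Given a mean `m` and standard
#' deviation `s` with `s^2 < m (1 - m)`, the matched Beta distribution has
#' `alpha = m * c` and `beta = (1 - m) * c` where `c = m (1 - m) / s^2 - 1`.
#'
#' @param mean Mean on (0, 1).
#' @param sd Standard deviation; its square must be strictly less than
#'   `mean * (1 - mean)`, otherwise no Beta distribution has these moments.
#' @return A list of class `"beta_spec"` with elements `alpha` and `beta`.
#' @seealso [gamma_from_moments()] for cost parameters.
#' @export
#' @examples
#' beta_from_moments(0.72, 0.25)
beta_from_moments <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd), length(mean) == 1L, length(sd) == 1L)
  if (!(mean > 0 && mean < 1))
    stop("beta_from_moments: mean must lie strictly inside (0, 1), got ", mean)
  if (sd <= 0)
    stop("beta_from_moments: sd must be positive, got ", sd)
  v <- sd^2
  if (v >= mean * (1 - mean))
    stop(sprintf(
      "beta_from_moments: variance %.6g is not feasible for mean %.4g (needs < %.6g)",
      v, mean, mean * (1 - mean)))
  c0 <- mean * (1 - mean) / v - 1
  structure(list(alpha = mean * c0, beta = (1 - mean) * c0), class = "beta_spec")
}

#' Gamma distribution parameters from a mean and standard deviation
#'
#' Method-of-moments parameterization used for cost items in the
#' probabilistic sensitivity analysis: `shape = (mean/sd)^2`,
#' `scale = sd^2/mean` (so `shape * scale == mean` and
#' `sqrt(shape) * scale == sd`).
#'
#' @param mean Positive mean (money units).
#' @param sd Positive standard deviation (same units).
#' @return A list of class `"gamma_spec"` with elements `shape` and `scale`.
#' @export
#' @examples
#' gamma_from_moments(43200000, 4032654)
gamma_from_moments <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd), length(mean) == 1L, length(sd) == 1L)
  if (mean <= 0 || sd <= 0)
    stop("gamma_from_moments: mean and sd must be positive, got mean = ",
         mean, ", sd = ", sd)
  structure(list(shape = (mean / sd)^2, scale = sd^2 / mean), class = "gamma_spec")
}

#' Convert a cumulative probability to its per-year equivalent
#'
#' Trial outcome probabilities are reported cumulatively over the follow-up
#' horizon; the cycle model needs per-cycle probabilities. Under a constant
#' hazard, a probability `p` cumulative over `years` years corresponds to an
#' annual probability `1 - (1 - p)^(1/years)`; compounding the annual value
#' back over `years` recovers `p` exactly.
#'
#' @param p_cum Cumulative probability in `[0, 1)`.
#' @param years Positive length of the horizon over which `p_cum` accrues.
#' @return Annual probability.
#' @export
#' @examples
#' annual_prob_from_cumulative(0.153, 5)
annual_prob_from_cumulative <- function(p_cum, years) {
  stopifnot(is.numeric(p_cum), is.numeric(years))
  if (any(years <= 0)) stop("annual_prob_from_cumulative: years must be positive")
  if (any(p_cum < 0) || any(p_cum >= 1))
    stop("annual_prob_from_cumulative: p_cum must lie in [0, 1); ",
         "a probability of 1 has no finite hazard")
  1 - (1 - p_cum)^(1 / years)
}

# inverse: compound an annual probability over `years`
.cumulative_from_annual <- function(p_annual, years) 1 - (1 - p_annual)^years
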