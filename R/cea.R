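#' Construct an arm-level result from published values
#'
#' Builds a minimal `"valvecea_arm_result"` directly from a per-patient
#' cost and QALY figure, e.g. to rework published table values through
#' [incremental()] without re-running the model.
#'
#' @param arm `"TAVI"` or `"SAVR"`.
#' @param cost Discounted lifetime cost per patient (IRR).
#' @param qalys Discounted QALYs per patient.
#' @return A `"valvecea_arm_result"` (without a trace).
#' @export
#' @examples
#' incremental(arm_result("TAVI", 720257876, 1.27),
#'             arm_result("SAVR", 352077775, 0.90))
arm_result <- function(arm, cost, qalys) {
  structure(list(arm = .match_arm(arm), cost = cost, qalys = qalys,
                 undiscounted_qalys = NA_real_, life_years = NA_real_,
                 acute_cost = NA_real_, trace = NULL),
            class = "valvecea_arm_result")
}

#' Incremental cost-effectiveness comparison
#'
#' Computes the cost and effect differences between an intervention and a
#' comparator and, when the signs admit a meaningful ratio, the incremental
#' cost-effectiveness ratio (ICER). Quadrant logic on the
#' cost-effectiveness plane:
#' \itemize{
#'   \item dE > 0, dC > 0: north-east, ICER reported (`label = "RATIO"`);
#'   \item dE > 0, dC <= 0: intervention dominant, no ratio;
#'   \item dE < 0, dC >= 0: intervention dominated, no ratio;
#'   \item dE < 0, dC < 0: south-west ratio, reported with an explicit
#'     quadrant flag because its decision meaning inverts;
#'   \item dE == 0: no ratio, flagged.
#' }
#'
#' @param intervention,comparator `"valvecea_arm_result"` objects (from
#'   [run_arm()] or [arm_result()]) evaluated under the same configuration.
#' @param exchange_rate IRR per US$ for the mirrored dollar views
#'   (default 250,000, the 2020 average).
#' @return Object of class `"valvecea_incremental"`: `delta_cost`,
#'   `delta_qalys`, `label` (`"RATIO"`, `"DOMINANT"`, `"DOMINATED"` or
#'   `"NO_RATIO"`), `quadrant`, `icer` (`NA` unless a ratio), and `usd`
#'   mirror (`delta_cost`, `icer`, rounded half-up to whole dollars).
#' @export
incremental <- function(intervention, comparator, exchange_rate = 250000) {
  dc <- intervention$cost - comparator$cost
  de <- intervention$qalys - comparator$qalys
  if (de > 0 && dc > 0)      { label <- "RATIO";     quadrant <- "NE" }
  else if (de > 0)           { label <- "DOMINANT";  quadrant <- "SE" }
  else if (de < 0 && dc >= 0){ label <- "DOMINATED"; quadrant <- "NW" }
  else if (de < 0)           { label <- "RATIO";     quadrant <- "SW" }
  else                       { label <- "NO_RATIO";  quadrant <- if (dc < 0) "W" else "E" }
  icer <- if (label == "RATIO") dc / de else NA_real_
  structure(list(
    delta_cost = dc, delta_qalys = de, label = label, quadrant = quadrant,
    icer = icer,
    exchange_rate = exchange_rate,
    usd = list(delta_cost = .round_half_up(dc / exchange_rate),
               icer = if (is.na(icer)) NA_real_ else .round_half_up(icer / exchange_rate))),
    class = "valvecea_incremental")
}

#' Net monetary benefit
#'
#' `NMB(wtp) = wtp * dE - dC`; positive exactly when the intervention is
#' cost-effective at that willingness-to-pay threshold.
#'
#' @param inc A `"valvecea_incremental"` from [incremental()].
#' @param wtp Willingness to pay per QALY (money, `>= 0`); vectorized.
#' @return Net monetary benefit in the same money units as `delta_cost`.
#' @export
#' @examples
#' inc <- incremental(arm_result("TAVI", 720257876, 1.27),
#'                    arm_result("SAVR", 352077775, 0.90))
#' nmb(inc, 551400000)
nmb <- function(inc, wtp) {
  stopifnot(inherits(inc, "valvecea_incremental"), all(wtp >= 0))
  wtp * inc$delta_qalys - inc$delta_cost
}

.round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Convert Iranian Rial to US dollars
#'
#' Divides by the configured exchange rate (default 250,000 IRR per US$,
#' the 2020 average used throughout). For display the result is rounded
#' half-up to whole dollars; pass `round = FALSE` for the unrounded value.
#'
#' @param amount Money amount(s) in IRR.
#' @param cfg A `"valvecea_config"`, or a numeric exchange rate directly.
#' @param round Round half-up to whole dollars (default `TRUE`).
#' @return Amount(s) in US$.
#' @export
#' @examples
#' to_usd(995081354, default_config())
to_usd <- function(amount, cfg = default_config(), round = TRUE) {
  rate <- if (is.numeric(cfg)) cfg else cfg$econ$exchange_rate
  stopifnot(rate > 0)
  x <- amount / rate
  if (round) .round_half_up(x) else x
}

#' Ratio of an ICER to a willingness-to-pay threshold
#'
#' Dimensionless positioning of an ICER against a threshold (e.g. 1x GDP
#' per capita); values above 1 mean the ICER exceeds the threshold.
#' Displayed to one decimal by convention; the unrounded value is returned.
#'
#' @param icer Money per QALY.
#' @param wtp Positive threshold, money per QALY.
#' @return `icer / wtp`.
#' @export
#' @examples
#' threshold_ratio(995081354, 551400000)
threshold_ratio <- function(icer, wtp) {
  stopifnot(all(wtp > 0))
  icer / wtp
}

#' @export
print.valvecea_incremental <- function(x, ...) {
  cat("Incremental cost-effectiveness (intervention vs comparator)\n")
  cat(sprintf("  delta cost : %s IRR (US$ %s)\n",
              format(round(x$delta_cost), big.mark = ","),
              format(x$usd$delta_cost, big.mark = ",")))
  cat(sprintf("  delta QALYs: %.2f\n", x$delta_qalys))
  if (x$label == "RATIO") {
    cat(sprintf("  ICER       : %s IRR/QALY (US$ %s)%s\n",
                format(round(x$icer), big.mark = ","),
                format(x$usd$icer, big.mark = ","),
                if (x$quadrant == "SW") "  [south-west quadrant: interpret inversely]" else ""))
  } else {
    cat("  ICER       : not reported (", x$label, ")\n", sep = "")
  }
  invisible(x)
}

#' @export
print.valvecea_arm_result <- function(x, ...) {
  cat(sprintf("%s: cost %s IRR, %.3f QALYs per patient\n",
              x$arm, format(round(x$cost), big.mark = ","), x$qalys))
  invisible(x)
}
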