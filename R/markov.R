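#' Discount factor
#'
#' End-of-cycle discounting: cycle `t` is weighted by `1/(1+rate)^t`, so the
#' entry cohort's first cycle of rewards (cycle 1) is already discounted one
#' period. Both costs and effects use the same rate.
#'
#' @param cycle Non-negative cycle index (0 = entry).
#' @param rate Annual discount rate as a fraction, `>= 0`.
#' @return Discount factor in `(0, 1]`.
#' @export
#' @examples
#' discount_factor(1, 0.065)
discount_factor <- function(cycle, rate) {
  stopifnot(is.numeric(cycle), is.numeric(rate), rate >= 0)
  if (any(cycle < 0)) stop("discount_factor: cycle must be non-negative")
  1 / (1 + rate)^cycle
}

# internal: discount factor honouring a non-unit cycle length
.df <- function(cycle, cfg) {
  1 / (1 + cfg$econ$discount_rate)^(cycle * cfg$econ$cycle_length_years)
}

# ---------------------------------------------------------------------------

.tmat <- function(arm, cycle, cfg) {
  pd <- .death_prob(cfg, arm, cycle)
  ps <- .per_cycle_event_prob(cfg, arm, "stroke")
  if (pd < 0 || pd > 1 || ps < 0 || ps > 1)
    stop(sprintf(
      "transition probabilities outside [0, 1] at cycle %d (death %.4f, stroke %.4f)",
      cycle, pd, ps))
  M <- matrix(0, .N_STATES, .N_STATES,
              dimnames = list(health_states(), health_states()))
  # competing risks composed multiplicatively: stroke applies to survivors,
  # so each alive state has the identical probability pd of moving to death
  for (k in .NYHA) {
    M[k, k] <- (1 - pd) * (1 - ps)
    M[k, k + 4L] <- (1 - pd) * ps
    M[k, .DEAD] <- pd
  }
  for (k in .NYHA_STROKE) {
    M[k, k] <- 1 - pd       # stroke is absorbing among the alive states
    M[k, .DEAD] <- pd
  }
  M[.DEAD, .DEAD] <- 1
  attr(M, "arm") <- arm
  attr(M, "cycle") <- cycle
  M
}

#' Per-cycle transition matrix
#'
#' Builds the 9x9 transition matrix for one strategy and cycle. Structure:
#' every alive state moves to death with the same all-cause probability
#' (identical-death-transition assumption); surviving NYHA-k patients
#' suffer a major stroke with the per-cycle stroke probability and move to
#' the matching post-stroke state, which they never leave while alive (NYHA
#' class itself is frozen absent stroke or death); death is absorbing. Rows
#' sum to one exactly by construction.
#'
#' The per-cycle death probability comes from the assumption knobs: by
#' default (`CONSTANT_YEAR1`) the first-year all-cause death probability is
#' held constant for all later cycles; `annual_death_override` (scalar or
#' per-arm) or a `USER_TABLE` of per-cycle probabilities replace it.
#'
#' @param arm `"TAVI"` or `"SAVR"`.
#' @param cycle Cycle index, `>= 1`.
#' @param cfg A validated `"valvecea_config"`.
#' @return 9x9 matrix with state dimnames and attributes `arm`, `cycle`.
#' @export
build_transition_matrix <- function(arm, cycle, cfg) {
  arm <- .match_arm(arm)
  .assert_valid(cfg)
  stopifnot(length(cycle) == 1L, cycle >= 1)
  .tmat(arm, as.integer(cycle), cfg)
}

# ---------------------------------------------------------------------------

.rewards <- function(arm, cycle, cfg) {
  cl <- cfg$econ$cycle_length_years
  u <- cfg$utilities$mean
  q <- numeric(.N_STATES)
  q[.NYHA] <- u * cl
  # the stroke disutility is deferred for the first Markov cycle: first-year
  # rehabilitation is assumed to preserve the pre-stroke quality of life
  q[.NYHA_STROKE] <- if (cycle >= 2)
    pmax(0, u - cfg$utilities$stroke_disutility) * cl
  else u * cl
  cost <- numeric(.N_STATES)
  per_cycle <- 0
  for (it in cfg$costs) for (a in it$assignment) {
    if (a$arm != arm || a$phase != "PER_CYCLE_EVENT") next
    if (identical(a$event, "rehospitalization") &&
        !cfg$knobs$rehospitalization_recurring && cycle > 1) next
    per_cycle <- per_cycle + .per_cycle_event_prob(cfg, arm, a$event) * it$mean
  }
  cost[c(.NYHA, .NYHA_STROKE)] <- per_cycle
  names(q) <- names(cost) <- health_states()
  list(qaly = q, cost = cost, cycle = cycle)
}

#' Per-cycle reward vector
#'
#' QALY and cost rewards by state for one strategy and cycle. NYHA-k states
#' earn their utility times the cycle length; post-stroke states earn the
#' same utility minus the major-stroke disutility (floored at zero) from
#' cycle 2 onward — the disutility is deferred during the first cycle to
#' credit post-stroke rehabilitation. Death earns nothing. The cost reward
#' carries the expected per-cycle event costs (by default the annualized
#' rehospitalization probability times the arm's hospitalization cost),
#' identical across alive states.
#'
#' @inheritParams build_transition_matrix
#' @return List with named numeric vectors `qaly` and `cost` (length 9) and
#'   the `cycle` index.
#' @export
cycle_rewards <- function(arm, cycle, cfg) {
  arm <- .match_arm(arm)
  .assert_valid(cfg)
  stopifnot(length(cycle) == 1L, cycle >= 1)
  .rewards(arm, as.integer(cycle), cfg)
}

# ---------------------------------------------------------------------------

.trace <- function(entry, arm, cfg) {
  Tmax <- cfg$econ$max_cycles
  eps <- cfg$econ$survival_stop_epsilon
  rows <- matrix(NA_real_, Tmax + 1L, .N_STATES,
                 dimnames = list(0:Tmax, health_states()))
  rows[1L, ] <- entry
  t <- 0L
  M <- NULL
  constant_death <- is.null(cfg$knobs$death_table)
  while (1 - rows[t + 1L, .DEAD] >= eps && t < Tmax) {
    t <- t + 1L
    if (is.null(M) || !constant_death) M <- .tmat(arm, t, cfg)
    rows[t + 1L, ] <- as.numeric(rows[t, , drop = FALSE] %*% M)
  }
  occupancy <- rows[seq_len(t + 1L), , drop = FALSE]
  converged <- (1 - occupancy[t + 1L, .DEAD]) < eps
  structure(list(arm = arm, occupancy = occupancy, stopped_at = t,
                 converged = converged,
                 warning = if (!converged)
                   sprintf("survival still %.3g after %d cycles",
                           1 - occupancy[t + 1L, .DEAD], t)),
            class = "valvecea_trace")
}

#' Propagate a cohort through the Markov model
#'
#' Row 0 of the trace is the entry distribution; row `t` is row `t-1` times
#' the cycle-`t` transition matrix. Propagation stops when survival drops
#' below `econ$survival_stop_epsilon` (the numeric stand-in for "nobody left
#' alive") or after `econ$max_cycles` cycles, whichever comes first; hitting
#' the cycle cap with survivors records a warning in the trace rather than
#' failing.
#'
#' @param entry Named probability vector over [health_states()] (see
#'   [entry_distribution()]).
#' @param arm `"TAVI"` or `"SAVR"`.
#' @param cfg A validated `"valvecea_config"`.
#' @return Object of class `"valvecea_trace"`: `occupancy` matrix (rows =
#'   cycles 0..T), `stopped_at`, `converged`, optional `warning`.
#' @export
run_cohort <- function(entry, arm, cfg) {
  arm <- .match_arm(arm)
  .assert_valid(cfg)
  stopifnot(length(entry) == .N_STATES, all(entry >= -1e-12),
            abs(sum(entry) - 1) < 1e-9)
  .trace(as.numeric(entry), arm, cfg)
}

# ---------------------------------------------------------------------------

.accumulate <- function(trace, arm, cfg, acute = NULL) {
  occ <- trace$occupancy
  Tn <- trace$stopped_at
  hcc <- isTRUE(cfg$econ$half_cycle_correction)
  qd <- qu <- cd <- ly <- 0
  alive <- c(rep(1, 8), 0)
  for (t in seq_len(Tn)) {
    r <- .rewards(arm, t, cfg)
    start_q <- sum(occ[t, ] * r$qaly)
    start_c <- sum(occ[t, ] * r$cost)
    if (hcc) {
      # average the start- and end-of-cycle occupancy (trapezoid correction)
      start_q <- (start_q + sum(occ[t + 1L, ] * r$qaly)) / 2
      start_c <- (start_c + sum(occ[t + 1L, ] * r$cost)) / 2
    }
    df <- .df(t, cfg)
    qd <- qd + df * start_q
    cd <- cd + df * start_c
    qu <- qu + start_q
    ly <- ly + sum(occ[t, ] * alive) * cfg$econ$cycle_length_years
  }
  if (is.null(acute)) acute <- acute_cost(arm, cfg)
  structure(list(arm = arm,
                 cost = acute$expected_cost + cd,
                 qalys = qd,
                 undiscounted_qalys = qu,
                 life_years = ly,
                 acute_cost = acute$expected_cost,
                 trace = trace),
            class = "valvecea_arm_result")
}

#' Accumulate discounted costs and QALYs over a cohort trace
#'
#' Rewards accrue at end of cycle: the occupancy at the start of cycle `t`
#' (trace row `t-1`) earns the cycle-`t` rewards discounted by
#' `1/(1+r)^t`. Discounted cost additionally includes the arm's acute
#' (decision-tree) cost, which is incurred at entry undiscounted. With the
#' half-cycle correction enabled the start- and end-of-cycle occupancies are
#' averaged.
#'
#' @param trace A `"valvecea_trace"` from [run_cohort()] under the same
#'   configuration.
#' @inheritParams run_cohort
#' @return Object of class `"valvecea_arm_result"` with `cost`, `qalys`
#'   (both discounted, per patient), `undiscounted_qalys`, `life_years`,
#'   `acute_cost` and the `trace`.
#' @export
accumulate <- function(trace, arm, cfg) {
  arm <- .match_arm(arm)
  .assert_valid(cfg)
  if (!inherits(trace, "valvecea_trace")) stop("trace must come from run_cohort()")
  if (!identical(trace$arm, arm))
    stop("trace was produced for arm ", trace$arm, ", not ", arm)
  if (ncol(trace$occupancy) != .N_STATES) stop("trace/config mismatch")
  .accumulate(trace, arm, cfg)
}

#' Run one strategy end to end
#'
#' Convenience wrapper: entry distribution, cohort propagation, and reward
#' accumulation for one arm.
#'
#' @inheritParams run_cohort
#' @return A `"valvecea_arm_result"`; see [accumulate()].
#' @export
#' @examples
#' res <- run_arm("TAVI", default_config())
#' c(cost = res$cost, qalys = res$qalys)
run_arm <- function(arm, cfg) {
  arm <- .match_arm(arm)
  .assert_valid(cfg)
  .run_arm(arm, cfg)
}

# lean internal path (no re-validation) used by PSA/OWSA loops
.run_arm <- function(arm, cfg) {
  e <- cfg$entry[[arm]]
  entry <- numeric(.N_STATES)
  entry[.NYHA] <- e[paste0("NYHA", 1:4)]
  entry[.DEAD] <- e[["death"]]
  tr <- .trace(entry, arm, cfg)
  .acute <- local({
    bd <- 0
    for (it in cfg$costs) for (a in it$assignment) {
      if (a$arm != arm) next
      if (a$phase == "PROCEDURE") bd <- bd + it$mean
      else if (a$phase == "ACUTE_EVENT") bd <- bd + cfg$events[[arm]][[a$event]] * it$mean
    }
    list(expected_cost = bd)
  })
  .accumulate(tr, arm, cfg, acute = .acute)
}

#' Run the full two-strategy model
#'
#' Evaluates both arms under one configuration and forms the incremental
#' comparison (TAVI as intervention, SAVR as comparator).
#'
#' @param cfg A validated `"valvecea_config"`.
#' @return List with elements `TAVI`, `SAVR` (each a
#'   `"valvecea_arm_result"`) and `incremental` (a
#'   `"valvecea_incremental"`).
#' @export
run_model <- function(cfg) {
  .assert_valid(cfg)
  tavi <- .run_arm("TAVI", cfg)
  savr <- .run_arm("SAVR", cfg)
  list(TAVI = tavi, SAVR = savr,
       incremental = incremental(tavi, savr,
                                 exchange_rate = cfg$econ$exchange_rate))
}
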