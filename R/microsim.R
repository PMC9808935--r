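#' @title Patient-level microsimulation
#'
#' @description Independent validation oracle for the cohort engine: the
#' identical state process (same entry distribution, transition rows,
#' rewards and discounting) simulated patient by patient. Each patient owns
#' an independently seeded random substream derived from the master seed,
#' so increasing `n` extends the cohort without perturbing earlier
#' patients. One uniform draw selects the entry state; one uniform per
#' cycle selects the successor state through the inverse CDF of the
#' transition-matrix row.
#'
#' @name microsim
NULL

# per-patient substream seeds; step is coprime with the modulus, so ids map
# to distinct seeds below 2^31
.patient_seeds <- function(master, ids) {
  (as.numeric(master) %% 2147483647 + 1000003 * as.numeric(ids)) %% 2147483647
}

# vectorized core: simulate the state paths of all patients in `pseeds`
.sim_paths <- function(arm, cfg, pseeds) {
  Tmax <- cfg$econ$max_cycles
  n <- length(pseeds)
  U <- matrix(NA_real_, n, Tmax + 1L)
  for (i in seq_len(n)) {
    set.seed(pseeds[i])
    U[i, ] <- stats::runif(Tmax + 1L)
  }
  entry <- as.numeric(entry_distribution(arm, cfg))
  cum_entry <- cumsum(entry)
  S <- matrix(NA_integer_, n, Tmax + 1L)   # states at cycles 0..Tmax
  S[, 1L] <- pmin(findInterval(U[, 1L], cum_entry) + 1L, .N_STATES)

  acute <- acute_cost(arm, cfg)$expected_cost
  cost <- rep(acute, n)       # discounted; acute cost incurred at entry
  qaly <- numeric(n)
  qaly_undisc <- numeric(n)

  constant_death <- is.null(cfg$knobs$death_table)
  M <- NULL
  cumM <- NULL
  for (t in seq_len(Tmax)) {
    cur <- S[, t]
    alive <- which(cur != .DEAD)
    if (!length(alive)) {
      S[, (t + 1L):(Tmax + 1L)] <- .DEAD
      break
    }
    r <- .rewards(arm, t, cfg)
    df <- .df(t, cfg)
    qaly[alive] <- qaly[alive] + df * r$qaly[cur[alive]]
    qaly_undisc[alive] <- qaly_undisc[alive] + r$qaly[cur[alive]]
    cost[alive] <- cost[alive] + df * r$cost[cur[alive]]
    if (is.null(M) || !constant_death) {
      M <- .tmat(arm, t, cfg)
      cumM <- t(apply(M, 1L, cumsum))
    }
    nxt <- rep(.DEAD, n)
    u <- U[, t + 1L]
    for (s in unique(cur[alive])) {
      idx <- alive[cur[alive] == s]
      nxt[idx] <- pmin(findInterval(u[idx], cumM[s, ]) + 1L, .N_STATES)
    }
    S[, t + 1L] <- nxt
  }
  list(states = S, cost = cost, qaly = qaly, qaly_undisc = qaly_undisc,
       acute = acute)
}

#' Simulate a single patient path
#'
#' Samples one patient's trajectory through the model using the same
#' transition rows, rewards and discounting as the cohort engine. The
#' patient's substream is derived from `(seed, id)`, so the path is exactly
#' the one patient `id` follows inside [simulate_cohort()] run with the
#' same master seed.
#'
#' @param arm `"TAVI"` or `"SAVR"`.
#' @param cfg A validated `"valvecea_config"`.
#' @param seed Master seed of the simulation.
#' @param id Patient index (`>= 1`) within the simulated cohort.
#' @return List of class `"valvecea_patient_path"`: `id`, `arm`, `states`
#'   (labels from entry until death or the cycle horizon), `cost` and
#'   `qalys` (discounted), `undiscounted_qalys`.
#' @export
simulate_patient <- function(arm, cfg, seed, id = 1L) {
  arm <- .match_arm(arm)
  .assert_valid(cfg)
  stopifnot(id >= 1)
  res <- .sim_paths(arm, cfg, .patient_seeds(seed, id))
  states <- res$states[1L, ]
  dead_at <- match(.DEAD, states)
  keep <- if (is.na(dead_at)) seq_along(states) else seq_len(dead_at)
  structure(list(id = as.integer(id), arm = arm,
                 states = health_states()[states[keep]],
                 cost = res$cost[1L], qalys = res$qaly[1L],
                 undiscounted_qalys = res$qaly_undisc[1L]),
            class = "valvecea_patient_path")
}

#' Simulate a cohort of individual patients
#'
#' Runs [simulate_patient()]-equivalent paths for `n` patients (vectorized)
#' and aggregates mean discounted cost and QALYs with Monte-Carlo standard
#' errors. Used to validate the cohort engine: the cohort result should lie
#' within a few standard errors of the microsimulation mean.
#'
#' @inheritParams simulate_patient
#' @param n Number of patients (`>= 1`).
#' @param keep_log Build the per-cycle event log (data frame with columns
#'   `patient_id`, `arm`, `cycle`, `state`, `event`, `cost_irr`, `qaly`).
#'   Defaults to `TRUE` for `n <= 10000`; the log for very large cohorts is
#'   rarely needed and dominates memory.
#' @return Object of class `"valvecea_microsim"`: `arm`, `n`, `seed`,
#'   `mean_cost`, `se_cost`, `mean_qalys`, `se_qalys`, per-patient vectors
#'   `cost` and `qalys`, `states` (integer matrix of state indices into
#'   [health_states()], one row per patient, columns = cycles 0..max),
#'   and `log` (or `NULL`).
#' @export
simulate_cohort <- function(arm, cfg, n, seed, keep_log = n <= 10000) {
  arm <- .match_arm(arm)
  .assert_valid(cfg)
  stopifnot(n >= 1)
  res <- .sim_paths(arm, cfg, .patient_seeds(seed, seq_len(n)))
  log <- if (keep_log) .event_log(arm, cfg, res) else NULL
  structure(list(arm = arm, n = as.integer(n), seed = as.integer(seed),
                 mean_cost = mean(res$cost),
                 se_cost = stats::sd(res$cost) / sqrt(n),
                 mean_qalys = mean(res$qaly),
                 se_qalys = stats::sd(res$qaly) / sqrt(n),
                 cost = res$cost, qalys = res$qaly,
                 states = res$states,
                 log = log),
            class = "valvecea_microsim")
}

# event log: one row per patient-cycle up to (and including) the first DEAD
# cycle or the horizon. The row for cycle c carries the state occupied at
# cycle index c and the discounted rewards that occupant earns over the
# following cycle, so per-patient column sums reproduce the path totals
# exactly (the entry row additionally carries the acute cost).
.event_log <- function(arm, cfg, res) {
  S <- res$states
  n <- nrow(S)
  Tmax <- ncol(S) - 1L
  dead_at <- apply(S == .DEAD, 1L, function(z) {
    w <- which(z)
    if (length(w)) w[1L] else Tmax + 1L
  })
  rows <- vector("list", n)
  labels <- health_states()
  # per-cycle reward tables (cycle 1 differs from the rest)
  rew <- lapply(seq_len(Tmax), function(t) .rewards(arm, cfg = cfg, cycle = t))
  dfs <- .df(seq_len(Tmax), cfg)
  for (i in seq_len(n)) {
    last <- dead_at[i]                 # column index of first DEAD (or horizon)
    st <- S[i, seq_len(last)]
    ncyc <- length(st)
    q <- c0 <- numeric(ncyc)
    for (c in seq_len(ncyc)) {
      t <- c                           # reward earned over cycle c (rows are 0-based)
      if (t <= Tmax && st[c] != .DEAD) {
        q[c] <- dfs[t] * rew[[t]]$qaly[st[c]]
        c0[c] <- dfs[t] * rew[[t]]$cost[st[c]]
      }
    }
    c0[1L] <- c0[1L] + res$acute
    prev <- c(NA_integer_, st[-ncyc])
    event <- rep("", ncyc)
    event[1L] <- "entry"
    event[which(st %in% .NYHA_STROKE & !(prev %in% .NYHA_STROKE))] <- "stroke"
    event[which(st == .DEAD)] <- "death"
    rows[[i]] <- data.frame(patient_id = i, arm = arm,
                            cycle = seq_len(ncyc) - 1L,
                            state = labels[st], event = event,
                            cost_irr = c0, qaly = q)
  }
  do.call(rbind, rows)
}

#' Write a microsimulation event log to CSV
#'
#' Deterministic ordering (patient, then cycle); the documented header is
#' `patient_id, arm, cycle, state, event, cost_irr, qaly`. Reading the file
#' back and summing `qaly` (or `cost_irr`) per patient reproduces each
#' path's discounted totals exactly.
#'
#' @param paths A `"valvecea_microsim"` with a log, or the log data frame
#'   itself (possibly empty).
#' @param destination File path to write.
#' @return The destination path, invisibly.
#' @export
write_event_log <- function(paths, destination) {
  log <- if (inherits(paths, "valvecea_microsim")) paths$log else paths
  if (is.null(log))
    stop("no event log present; rerun simulate_cohort() with keep_log = TRUE")
  if (is.list(log) && !is.data.frame(log) && !length(log)) log <- data.frame()
  if (!nrow(log) && !ncol(log))
    log <- data.frame(patient_id = integer(), arm = character(),
                      cycle = integer(), state = character(),
                      event = character(), cost_irr = numeric(),
                      qaly = numeric())
  utils::write.csv(log, destination, row.names = FALSE, quote = FALSE)
  invisible(destination)
}

#' Read a microsimulation event log
#'
#' @param path CSV written by [write_event_log()].
#' @return Data frame with the documented columns.
#' @export
read_event_log <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
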