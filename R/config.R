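#' @title Model configuration
#'
#' @description The whole parameter set of the evaluation lives in a single
#' configuration object (class `"valvecea_config"`): utility weights with
#' their sampling SDs, adverse-event and transition probabilities per arm,
#' the entry (first-year) outcome distribution per arm, the unit-cost
#' inventory with its arm/phase assignment table, economic settings
#' (discount rate, exchange rate, willingness-to-pay grid, cycle settings)
#' and explicit assumption knobs for every choice the source evidence leaves
#' open. Configurations are read from YAML with [load_model_config()] or
#' built in code from [default_config()].
#'
#' @name valvecea_config
NULL

.EVENT_NAMES <- c("TIA", "stroke", "rehospitalization", "myocardial_infarction",
                  "new_atrial_fibrillation", "new_pacemaker",
                  "aortic_valve_reintervention")
.PHASES <- c("PROCEDURE", "ACUTE_EVENT", "PER_CYCLE_EVENT")

.default_knobs <- function() {
  list(
    longterm_death_mode = "CONSTANT_YEAR1",
    annual_death_override = NULL,
    death_table = NULL,
    event_annualization = "CUMULATIVE_OVER_FOLLOWUP",
    rehospitalization_recurring = TRUE,
    owsa_mode = "MULTIPLIER",
    owsa_grid = c(0.05, 0.25, 0.50, 0.75, 1.00, 1.50, 2.00, 2.50),
    psa_icer_summary = "RATIO_OF_MEANS"
  )
}

.default_econ <- function() {
  list(
    discount_rate = 0.065,
    exchange_rate = 250000,
    # quarter-GDP-per-capita steps; includes the 1x and 3x GDP anchors
    # (551,400,000 and 1,654,200,000 IRR per QALY) exactly
    wtp_grid = 137850000 * (0:16),
    cycle_length_years = 1,
    max_cycles = 50L,
    survival_stop_epsilon = 1e-4,
    half_cycle_correction = FALSE
  )
}

.cost_item <- function(name, mean, sd = NULL, sampling = if (is.null(sd)) "FIXED" else "GAMMA",
                       assignment = list()) {
  list(name = name, mean = mean, sd = sd, sampling = sampling, assignment = assignment)
}

.assign <- function(arm, phase, event = NULL) list(arm = arm, phase = phase, event = event)

#' Default model configuration
#'
#' Returns the bundled base-case parameter set: EQ-5D utility weights by
#' NYHA class with a 0.39 major-stroke disutility; five-year trial event
#' probabilities per arm; the 0-12-month entry distribution over NYHA class
#' and death per arm; the 2020 Iranian-Rial unit-cost inventory with its
#' default arm/phase assignment table; and the economic settings (6.5%
#' annual discounting of costs and effects, 250,000 IRR/US$, a
#' willingness-to-pay grid anchored at one and three times GDP per capita,
#' one-year cycles).
#'
#' The same parameter set ships as YAML at
#' `system.file("extdata", "model_default.yaml", package = "valvecea")`.
#'
#' @return A validated object of class `"valvecea_config"`.
#' @seealso [load_model_config()], [validate_config()]
#' @export
default_config <- function() {
  cfg <- list(
    utilities = list(
      mean = c(NYHA1 = 0.72, NYHA2 = 0.72, NYHA3 = 0.53, NYHA4 = 0.47),
      sd   = c(NYHA1 = 0.25, NYHA2 = 0.25, NYHA3 = 0.32, NYHA4 = 0.35),
      stroke_disutility = 0.39
    ),
    events = list(
      followup_years = 5,
      TAVI = c(TIA = 0.053, stroke = 0.153, rehospitalization = 0.333,
               myocardial_infarction = 0.111, new_atrial_fibrillation = 0.158,
               new_pacemaker = 0.155, aortic_valve_reintervention = 0.032),
      SAVR = c(TIA = 0.043, stroke = 0.125, rehospitalization = 0.252,
               myocardial_infarction = 0.082, new_atrial_fibrillation = 0.304,
               new_pacemaker = 0.130, aortic_valve_reintervention = 0.008)
    ),
    entry = list(
      TAVI = c(NYHA1 = 0.36, NYHA2 = 0.28, NYHA3 = 0.10, NYHA4 = 0.01, death = 0.25),
      SAVR = c(NYHA1 = 0.34, NYHA2 = 0.30, NYHA3 = 0.07, NYHA4 = 0.02, death = 0.27)
    ),
    costs = list(
      .cost_item("savr_procedure", 12811000,
                 assignment = list(.assign("SAVR", "PROCEDURE"))),
      .cost_item("tavi_procedure", 20052000,
                 assignment = list(.assign("TAVI", "PROCEDURE"))),
      .cost_item("tavi_hospitalization", 43200000, sd = 4032654,
                 assignment = list(.assign("TAVI", "PROCEDURE"),
                                   .assign("TAVI", "PER_CYCLE_EVENT", "rehospitalization"))),
      .cost_item("savr_hospitalization", 75750000, sd = 4326731,
                 assignment = list(.assign("SAVR", "PROCEDURE"),
                                   .assign("SAVR", "PER_CYCLE_EVENT", "rehospitalization"))),
      .cost_item("tavi_stent", 450000000,
                 assignment = list(.assign("TAVI", "PROCEDURE"))),
      .cost_item("valve_prosthesis", 800000000,
                 assignment = list(.assign("TAVI", "ACUTE_EVENT", "aortic_valve_reintervention"),
                                   .assign("SAVR", "ACUTE_EVENT", "aortic_valve_reintervention"))),
      .cost_item("pacemaker_icd", 9183500,
                 assignment = list(.assign("TAVI", "ACUTE_EVENT", "new_pacemaker"),
                                   .assign("SAVR", "ACUTE_EVENT", "new_pacemaker"))),
      .cost_item("angioplasty", 7398300,
                 assignment = list(.assign("TAVI", "ACUTE_EVENT", "myocardial_infarction"),
                                   .assign("SAVR", "ACUTE_EVENT", "myocardial_infarction"))),
      .cost_item("tavi_reoperation", 10026000, sd = 1430401,
                 assignment = list(.assign("TAVI", "ACUTE_EVENT", "aortic_valve_reintervention"))),
      .cost_item("savr_reoperation", 6405500, sd = 2720528,
                 assignment = list(.assign("SAVR", "ACUTE_EVENT", "aortic_valve_reintervention"))),
      .cost_item("cabg", 22280000,
                 assignment = list(.assign("TAVI", "ACUTE_EVENT", "myocardial_infarction"),
                                   .assign("SAVR", "ACUTE_EVENT", "myocardial_infarction")))
    ),
    econ = .default_econ(),
    knobs = .default_knobs()
  )
  class(cfg) <- "valvecea_config"
  cfg
}

# ---------------------------------------------------------------------------
# loading

.check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop(sprintf("unknown key%s in %s: %s",
                 if (length(unknown) > 1) "s" else "", where,
                 paste(unknown, collapse = ", ")), call. = FALSE)
}

.as_named_numeric <- function(x, where) {
  if (is.null(x)) stop("missing block: ", where, call. = FALSE)
  out <- unlist(x)
  if (!is.numeric(out)) stop(where, " must be numeric", call. = FALSE)
  out
}

#' Load and validate a model configuration from YAML
#'
#' Reads a YAML file with the documented blocks `utilities`, `events`,
#' `entry`, `costs`, `econ` and `knobs`, fills omitted `econ`/`knobs`
#' entries with the documented defaults, rejects unknown keys (nothing is
#' silently ignored), and validates every invariant via
#' [validate_config()]. Any violation aborts the load with a message naming
#' the offending block.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated object of class `"valvecea_config"`.
#' @export
#' @examples
#' cfg <- load_model_config(system.file("extdata", "model_default.yaml",
#'                                      package = "valvecea"))
#' cfg$utilities$mean[["NYHA1"]]
load_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  # money amounts exceed .Machine$integer.max; read all ints as doubles
  raw <- yaml::read_yaml(path, handlers = list(int = function(x) as.numeric(x)))
  .check_keys(raw, c("utilities", "events", "entry", "costs", "econ", "knobs"),
              "top level")
  for (block in c("utilities", "events", "entry", "costs"))
    if (is.null(raw[[block]])) stop("config is missing required block: ", block)

  .check_keys(raw$utilities, c("mean", "sd", "stroke_disutility"), "utilities")
  utilities <- list(
    mean = .as_named_numeric(raw$utilities$mean, "utilities$mean")[paste0("NYHA", 1:4)],
    sd   = .as_named_numeric(raw$utilities$sd, "utilities$sd")[paste0("NYHA", 1:4)],
    stroke_disutility = raw$utilities$stroke_disutility
  )

  .check_keys(raw$events, c("followup_years", "TAVI", "SAVR"), "events")
  events <- list(followup_years = raw$events$followup_years %||% 5)
  for (arm in arms()) {
    .check_keys(raw$events[[arm]], .EVENT_NAMES, paste0("events$", arm))
    events[[arm]] <- .as_named_numeric(raw$events[[arm]],
                                       paste0("events$", arm))[.EVENT_NAMES]
    names(events[[arm]]) <- .EVENT_NAMES
  }

  .check_keys(raw$entry, arms(), "entry")
  entry <- list()
  for (arm in arms()) {
    .check_keys(raw$entry[[arm]], c(paste0("NYHA", 1:4), "death"),
                paste0("entry$", arm))
    entry[[arm]] <- .as_named_numeric(raw$entry[[arm]], paste0("entry$", arm))[
      c(paste0("NYHA", 1:4), "death")]
  }

  costs <- lapply(seq_along(raw$costs), function(i) {
    it <- raw$costs[[i]]
    .check_keys(it, c("name", "mean", "sd", "sampling", "assignment"),
                sprintf("costs[[%d]]", i))
    if (is.null(it$name) || is.null(it$mean))
      stop(sprintf("costs[[%d]]: 'name' and 'mean' are required", i))
    asg <- lapply(seq_along(it$assignment), function(j) {
      a <- it$assignment[[j]]
      .check_keys(a, c("arm", "phase", "event"),
                  sprintf("costs[[%d]]$assignment[[%d]]", i, j))
      .assign(a$arm, a$phase, a$event)
    })
    .cost_item(it$name, it$mean, sd = it$sd,
               sampling = it$sampling %||% if (is.null(it$sd)) "FIXED" else "GAMMA",
               assignment = asg)
  })

  econ <- .default_econ()
  if (!is.null(raw$econ)) {
    .check_keys(raw$econ, names(econ), "econ")
    econ[names(raw$econ)] <- raw$econ
  }
  econ$wtp_grid <- as.numeric(unlist(econ$wtp_grid))
  econ$max_cycles <- as.integer(econ$max_cycles)

  knobs <- .default_knobs()
  if (!is.null(raw$knobs)) {
    .check_keys(raw$knobs, names(knobs), "knobs")
    knobs[names(raw$knobs)] <- raw$knobs
  }
  knobs$owsa_grid <- as.numeric(unlist(knobs$owsa_grid))
  if (!is.null(knobs$annual_death_override))
    knobs$annual_death_override <- unlist(knobs$annual_death_override)
  if (!is.null(knobs$death_table))
    knobs$death_table <- lapply(knobs$death_table, as.numeric)

  cfg <- structure(list(utilities = utilities, events = events, entry = entry,
                        costs = costs, econ = econ, knobs = knobs),
                   class = "valvecea_config")
  viol <- validate_config(cfg)
  if (length(viol))
    stop("invalid configuration:\n  - ", paste(viol, collapse = "\n  - "),
         call. = FALSE)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# validation

#' Validate a model configuration
#'
#' Checks every structural invariant of the parameter set and returns the
#' violations as a character vector (empty when the configuration is valid;
#' nothing is thrown). Checks include: utilities and probabilities in
#' `[0, 1]`; Beta moment feasibility (`sd^2 < mean * (1 - mean)`) for every
#' utility with a positive SD; per-arm entry probabilities summing to one
#' within `1e-9`; cost means non-negative with an SD present exactly when
#' the item is Gamma-sampled; event-linked cost assignments resolving to a
#' known event probability; and economic/knob settings within range.
#'
#' @param cfg A `"valvecea_config"` object (structurally complete).
#' @return Character vector of human-readable violation descriptions;
#'   `character(0)` when valid.
#' @export
validate_config <- function(cfg) {
  v <- character()
  add <- function(msg) v <<- c(v, msg)

  u <- cfg$utilities
  for (k in paste0("NYHA", 1:4)) {
    m <- u$mean[[k]]; s <- u$sd[[k]]
    if (is.na(m) || m < 0 || m > 1)
      add(sprintf("utilities$mean$%s = %s outside [0, 1]", k, format(m)))
    if (is.na(s) || s < 0)
      add(sprintf("utilities$sd$%s must be >= 0", k))
    else if (!is.na(m) && m > 0 && m < 1 && s > 0 && s^2 >= m * (1 - m))
      add(sprintf(
        "utilities$%s: variance %.4f >= mean*(1-mean) = %.4f; no Beta distribution has these moments",
        k, s^2, m * (1 - m)))
  }
  if (u$stroke_disutility < 0 || u$stroke_disutility > 1)
    add("utilities$stroke_disutility outside [0, 1]")

  if (cfg$events$followup_years <= 0) add("events$followup_years must be positive")
  for (arm in arms()) {
    p <- cfg$events[[arm]]
    bad <- names(p)[is.na(p) | p < 0 | p > 1]
    for (b in bad) add(sprintf("events$%s$%s outside [0, 1]", arm, b))
  }

  for (arm in arms()) {
    e <- cfg$entry[[arm]]
    if (any(is.na(e) | e < 0 | e > 1))
      add(sprintf("entry$%s has probabilities outside [0, 1]", arm))
    if (abs(sum(e) - 1) > 1e-9)
      add(sprintf("entry$%s probabilities sum to %.10f, not 1", arm, sum(e)))
  }

  seen <- character()
  for (it in cfg$costs) {
    where <- sprintf("costs$%s", it$name)
    if (it$name %in% seen) add(paste0(where, ": duplicate cost item name"))
    seen <- c(seen, it$name)
    if (it$mean < 0) add(paste0(where, ": mean must be >= 0"))
    if (!it$sampling %in% c("FIXED", "GAMMA"))
      add(paste0(where, ": sampling must be FIXED or GAMMA"))
    if (it$sampling == "GAMMA" && is.null(it$sd))
      add(paste0(where, ": GAMMA sampling requires an sd"))
    if (it$sampling == "FIXED" && !is.null(it$sd))
      add(paste0(where, ": sd given but sampling is FIXED"))
    if (!is.null(it$sd) && it$sd <= 0) add(paste0(where, ": sd must be positive"))
    for (a in it$assignment) {
      if (!a$arm %in% arms())
        add(sprintf("%s: unknown arm '%s' in assignment", where, a$arm))
      if (!a$phase %in% .PHASES)
        add(sprintf("%s: unknown phase '%s' in assignment", where, a$phase))
      if (a$phase %in% c("ACUTE_EVENT", "PER_CYCLE_EVENT")) {
        if (is.null(a$event))
          add(sprintf("%s: %s assignment needs an 'event'", where, a$phase))
        else if (!a$event %in% .EVENT_NAMES)
          add(sprintf("%s: assignment event '%s' matches no event probability",
                      where, a$event))
      }
    }
  }

  ec <- cfg$econ
  if (ec$discount_rate < 0 || ec$discount_rate >= 1)
    add("econ$discount_rate must lie in [0, 1)")
  if (ec$exchange_rate <= 0) add("econ$exchange_rate must be positive")
  if (length(ec$wtp_grid) < 1 || anyNA(ec$wtp_grid) ||
      any(diff(ec$wtp_grid) <= 0))
    add("econ$wtp_grid must be strictly increasing")
  if (ec$cycle_length_years <= 0) add("econ$cycle_length_years must be positive")
  if (is.na(ec$max_cycles) || ec$max_cycles < 1) add("econ$max_cycles must be >= 1")
  if (ec$survival_stop_epsilon < 0 || ec$survival_stop_epsilon >= 1)
    add("econ$survival_stop_epsilon must lie in [0, 1)")

  kn <- cfg$knobs
  if (!kn$longterm_death_mode %in% c("CONSTANT_YEAR1", "USER_TABLE"))
    add("knobs$longterm_death_mode must be CONSTANT_YEAR1 or USER_TABLE")
  if (kn$longterm_death_mode == "USER_TABLE") {
    if (is.null(kn$death_table) || !all(arms() %in% names(kn$death_table)))
      add("knobs$death_table must give a per-cycle death probability vector for each arm")
    else for (arm in arms()) {
      dt <- kn$death_table[[arm]]
      if (!length(dt) || any(dt < 0 | dt > 1))
        add(sprintf("knobs$death_table$%s must be probabilities in [0, 1]", arm))
    }
  }
  if (!is.null(kn$annual_death_override)) {
    ov <- kn$annual_death_override
    if (any(ov < 0 | ov > 1)) add("knobs$annual_death_override outside [0, 1]")
    if (length(ov) > 1 && !all(arms() %in% names(ov)))
      add("knobs$annual_death_override must be a single probability or named per arm")
  }
  if (!kn$event_annualization %in% c("CUMULATIVE_OVER_FOLLOWUP", "ALREADY_ANNUAL"))
    add("knobs$event_annualization must be CUMULATIVE_OVER_FOLLOWUP or ALREADY_ANNUAL")
  if (!kn$owsa_mode %in% "MULTIPLIER") add("knobs$owsa_mode must be MULTIPLIER")
  if (!length(kn$owsa_grid) || any(kn$owsa_grid <= 0) || is.unsorted(kn$owsa_grid, strictly = TRUE))
    add("knobs$owsa_grid must be strictly positive and strictly increasing")
  if (!kn$psa_icer_summary %in% c("RATIO_OF_MEANS", "MEAN_OF_RATIOS"))
    add("knobs$psa_icer_summary must be RATIO_OF_MEANS or MEAN_OF_RATIOS")

  v
}

.assert_valid <- function(cfg) {
  if (!inherits(cfg, "valvecea_config"))
    stop("expected a 'valvecea_config' object; see default_config() / load_model_config()")
  viol <- validate_config(cfg)
  if (length(viol))
    stop("invalid configuration:\n  - ", paste(viol, collapse = "\n  - "),
         call. = FALSE)
  invisible(cfg)
}

# ---------------------------------------------------------------------------
# derived quantities shared by the engines

# per-cycle probability for an adverse event, after optional annualization
# of the trial-horizon cumulative value and rescaling to the cycle length
.per_cycle_event_prob <- function(cfg, arm, event) {
  p <- cfg$events[[arm]][[event]]
  p_annual <- switch(cfg$knobs$event_annualization,
    CUMULATIVE_OVER_FOLLOWUP = annual_prob_from_cumulative(p, cfg$events$followup_years),
    ALREADY_ANNUAL = p)
  cl <- cfg$econ$cycle_length_years
  if (cl == 1) p_annual else .cumulative_from_annual(p_annual, cl)
}

# per-cycle all-cause death probability for Markov cycle `cycle` (>= 1)
.death_prob <- function(cfg, arm, cycle) {
  kn <- cfg$knobs
  p_annual <- if (!is.null(kn$annual_death_override)) {
    ov <- kn$annual_death_override
    if (length(ov) > 1) ov[[arm]] else ov[[1]]
  } else if (kn$longterm_death_mode == "USER_TABLE") {
    dt <- kn$death_table[[arm]]
    dt[[min(cycle, length(dt))]]
  } else {
    # CONSTANT_YEAR1: hold the first-year all-cause death probability
    cfg$entry[[arm]][["death"]]
  }
  cl <- cfg$econ$cycle_length_years
  if (cl == 1 || p_annual >= 1) p_annual else .cumulative_from_annual(p_annual, cl)
}

# ---------------------------------------------------------------------------
# hashing (FNV-1a over the canonical JSON rendering; plumbing for manifests)

#' Stable hash of a configuration
#'
#' @param cfg A `"valvecea_config"` object.
#' @return Hex string; identical configurations hash identically.
#' @export
config_hash <- function(cfg) {
  txt <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                          null = "null")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte since b < 256; keeps h a double in 2^32
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply by the FNV prime, split to stay exact in doubles
    lo16 <- h %% 65536
    hi16 <- (h - lo16) / 65536
    h <- (lo16 * 16777619 + ((hi16 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}
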