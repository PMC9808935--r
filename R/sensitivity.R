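#' Draw one parameter set for probabilistic sensitivity analysis
#'
#' Samples every parameter that carries a sampling distribution from the
#' current R random stream and returns a configuration with the sampled
#' values in place of the means: each NYHA utility with a positive SD from
#' its moment-matched Beta distribution, and each Gamma-tagged cost item
#' from its moment-matched Gamma. Everything without a stated SD (procedure
#' and device costs, event probabilities, the stroke disutility) is fixed.
#' Sampling order is documented and fixed: utilities NYHA I-IV, then cost
#' items in configuration order.
#'
#' The caller owns the stream: seed with `set.seed()` (or use [run_psa()],
#' which seeds once per analysis).
#'
#' @param cfg A validated `"valvecea_config"`.
#' @return A `"valvecea_config"` with sampled values; the draw is attached
#'   as attribute `"sampled"` (named numeric vector).
#' @export
sample_parameter_set <- function(cfg) {
  sampled <- numeric()
  u <- cfg$utilities
  for (k in paste0("NYHA", 1:4)) {
    if (u$sd[[k]] > 0) {
      sp <- beta_from_moments(u$mean[[k]], u$sd[[k]])
      val <- stats::rbeta(1, sp$alpha, sp$beta)
      cfg$utilities$mean[[k]] <- val
      sampled[paste0("utility_", k)] <- val
    }
  }
  for (i in seq_along(cfg$costs)) {
    it <- cfg$costs[[i]]
    if (it$sampling == "GAMMA") {
      sp <- gamma_from_moments(it$mean, it$sd)
      val <- stats::rgamma(1, shape = sp$shape, scale = sp$scale)
      cfg$costs[[i]]$mean <- val
      sampled[paste0("cost_", it$name)] <- val
    }
  }
  attr(cfg, "sampled") <- sampled
  cfg
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo propagation of parameter uncertainty: for each iteration a
#' parameter set is drawn with [sample_parameter_set()], the full two-arm
#' model is run, and the incremental cost and effect pair is recorded.
#' Deterministic given `(cfg, n, seed)`.
#'
#' @param cfg A validated `"valvecea_config"`.
#' @param n Number of iterations (`>= 1`; 10,000 is a typical production
#'   size).
#' @param seed Integer seed for the draw stream.
#' @return Object of class `"valvecea_psa"`: `draws` (data frame with the
#'   sampled parameter values, per-arm cost/QALYs, `delta_cost`,
#'   `delta_qalys`, `icer_label`), `n`, `seed`, `wtp_grid`, `base`
#'   (the deterministic base-case incremental result) and `config_hash`.
#' @seealso [ceac()], [psa_summary()]
#' @export
run_psa <- function(cfg, n, seed) {
  .assert_valid(cfg)
  stopifnot(n >= 1)
  base <- run_model(cfg)
  set.seed(seed)
  rows <- vector("list", n)
  for (d in seq_len(n)) {
    cfg_d <- sample_parameter_set(cfg)
    tavi <- .run_arm("TAVI", cfg_d)
    savr <- .run_arm("SAVR", cfg_d)
    inc <- incremental(tavi, savr, exchange_rate = cfg$econ$exchange_rate)
    rows[[d]] <- c(attr(cfg_d, "sampled"),
                   tavi_cost = tavi$cost, tavi_qalys = tavi$qalys,
                   savr_cost = savr$cost, savr_qalys = savr$qalys,
                   delta_cost = inc$delta_cost, delta_qalys = inc$delta_qalys)
  }
  draws <- as.data.frame(do.call(rbind, rows))
  draws <- cbind(iteration = seq_len(n), draws)
  draws$icer_label <- ifelse(
    draws$delta_qalys > 0 & draws$delta_cost > 0, "RATIO",
    ifelse(draws$delta_qalys > 0, "DOMINANT",
           ifelse(draws$delta_qalys < 0 & draws$delta_cost >= 0, "DOMINATED",
                  ifelse(draws$delta_qalys < 0, "SW_RATIO", "NO_RATIO"))))
  structure(list(draws = draws, n = as.integer(n), seed = as.integer(seed),
                 wtp_grid = cfg$econ$wtp_grid, base = base$incremental,
                 config_hash = config_hash(cfg)),
            class = "valvecea_psa")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value the probability of cost-effectiveness
#' is the fraction of PSA draws with strictly positive net monetary benefit
#' `wtp * dE - dC > 0`; a draw with NMB exactly zero counts as not
#' cost-effective.
#'
#' @param psa A `"valvecea_psa"` from [run_psa()].
#' @param wtp_grid Strictly increasing willingness-to-pay values; defaults
#'   to the grid stored in the PSA (from the configuration).
#' @return Data frame with columns `wtp` and `probability`.
#' @export
ceac <- function(psa, wtp_grid = psa$wtp_grid) {
  stopifnot(inherits(psa, "valvecea_psa"), nrow(psa$draws) >= 1,
            length(wtp_grid) >= 1, !is.unsorted(wtp_grid, strictly = TRUE))
  prob <- vapply(wtp_grid, function(w)
    mean(w * psa$draws$delta_qalys - psa$draws$delta_cost > 0), numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' Summarize a probabilistic sensitivity analysis
#'
#' Reports both readings of the "mean ICER": the ratio of means
#' (`mean(dC) / mean(dE)`, the conventional headline) and the mean of
#' per-draw ratios over the draws in the north-east ratio quadrant (with
#' the count excluded from that average), along with quadrant counts and
#' the 2.5/97.5 percentile bounds of the scatter plane.
#'
#' @param psa A `"valvecea_psa"` from [run_psa()].
#' @return List with `icer_ratio_of_means`, `icer_mean_of_ratios`,
#'   `n_excluded_from_mean_of_ratios`, `mean_delta_cost`,
#'   `mean_delta_qalys`, `quadrant_counts`, and `scatter_bounds`
#'   (2.5%/97.5% quantiles of dC and dE).
#' @export
psa_summary <- function(psa) {
  stopifnot(inherits(psa, "valvecea_psa"), nrow(psa$draws) >= 1)
  d <- psa$draws
  mdc <- mean(d$delta_cost); mde <- mean(d$delta_qalys)
  rom <- if (mde == 0) NA_real_ else mdc / mde
  in_ratio <- d$icer_label == "RATIO"
  mor <- if (any(in_ratio))
    mean(d$delta_cost[in_ratio] / d$delta_qalys[in_ratio]) else NA_real_
  qc <- table(factor(d$icer_label,
                     levels = c("RATIO", "DOMINANT", "DOMINATED", "SW_RATIO", "NO_RATIO")))
  list(icer_ratio_of_means = rom,
       icer_mean_of_ratios = mor,
       n_excluded_from_mean_of_ratios = sum(!in_ratio),
       mean_delta_cost = mdc,
       mean_delta_qalys = mde,
       ratio_of_means_defined = mde != 0,
       quadrant_counts = qc,
       scatter_bounds = list(
         delta_cost = stats::quantile(d$delta_cost, c(0.025, 0.975), names = FALSE),
         delta_qalys = stats::quantile(d$delta_qalys, c(0.025, 0.975), names = FALSE)))
}

# ---------------------------------------------------------------------------
# one-way sensitivity analysis

#' Parameters varied in the default one-way sensitivity analysis
#'
#' The five adverse-event rates driving the tornado analysis.
#' @return Character vector of event names.
#' @export
owsa_default_parameters <- function() {
  c("stroke", "new_pacemaker", "myocardial_infarction",
    "new_atrial_fibrillation", "rehospitalization")
}

# apply a multiplier to one scalar parameter; event names hit both arms
.apply_multiplier <- function(cfg, parameter, m) {
  if (parameter %in% .EVENT_NAMES) {
    for (arm in arms()) {
      p <- cfg$events[[arm]][[parameter]] * m
      if (p > 1) {
        warning(sprintf("%s (%s) clipped from %.4f to 1", parameter, arm, p))
        p <- 1 - 1e-12
      }
      cfg$events[[arm]][[parameter]] <- p
    }
    return(cfg)
  }
  # dotted path into the configuration, e.g. "utilities.mean.NYHA1"
  path <- strsplit(parameter, ".", fixed = TRUE)[[1]]
  node <- cfg
  for (p in path) {
    if (is.null(node[[p]]))
      stop("unknown parameter '", parameter, "'; eligible event rates: ",
           paste(.EVENT_NAMES, collapse = ", "),
           " (or a dotted config path such as utilities.mean.NYHA1)")
    node <- node[[p]]
  }
  if (!is.numeric(node) || length(node) != 1L)
    stop("parameter '", parameter, "' is not a scalar")
  cfg[[path]] <- node * m
  cfg
}

#' One-way sensitivity analysis over a multiplier grid
#'
#' Rebuilds the configuration with one parameter scaled by each multiplier
#' (event rates are scaled in both arms simultaneously and clipped to
#' `[0, 1]` with a warning), runs both arms deterministically, and records
#' the ICER.
#'
#' @param cfg A validated `"valvecea_config"`.
#' @param parameter An adverse-event rate name (see
#'   [owsa_default_parameters()]; any entry of the events table is
#'   eligible) or a dotted configuration path to a scalar, e.g.
#'   `"utilities.mean.NYHA1"`.
#' @param grid Strictly increasing positive multipliers; defaults to the
#'   `owsa_grid` knob (0.05x to 2.5x).
#' @return Data frame of class `"valvecea_owsa"`: `parameter`,
#'   `multiplier`, `delta_cost`, `delta_qalys`, `icer`.
#' @export
owsa <- function(cfg, parameter, grid = cfg$knobs$owsa_grid) {
  .assert_valid(cfg)
  stopifnot(length(grid) >= 1, all(grid > 0))
  rows <- lapply(grid, function(m) {
    cfg_m <- .apply_multiplier(cfg, parameter, m)
    tavi <- .run_arm("TAVI", cfg_m)
    savr <- .run_arm("SAVR", cfg_m)
    inc <- incremental(tavi, savr, exchange_rate = cfg$econ$exchange_rate)
    data.frame(parameter = parameter, multiplier = m,
               delta_cost = inc$delta_cost, delta_qalys = inc$delta_qalys,
               icer = inc$icer)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("valvecea_owsa", "data.frame")
  out
}

#' Tornado ordering of one-way sensitivity curves
#'
#' Ranks parameters by the swing of the ICER over their multiplier grid
#' (max minus min), descending, with a stable alphabetical tie-break.
#'
#' @param curves A list of [owsa()] results (or a single one).
#' @return Data frame: `parameter`, `icer_low`, `icer_high`, `swing`,
#'   sorted by descending swing.
#' @export
tornado <- function(curves) {
  if (inherits(curves, "valvecea_owsa")) curves <- list(curves)
  stopifnot(length(curves) >= 1)
  rows <- lapply(curves, function(cv) {
    ic <- cv$icer[!is.na(cv$icer)]
    if (!length(ic))
      return(data.frame(parameter = cv$parameter[1], icer_low = NA_real_,
                        icer_high = NA_real_, swing = NA_real_))
    data.frame(parameter = cv$parameter[1], icer_low = min(ic),
               icer_high = max(ic), swing = max(ic) - min(ic))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$swing, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  out
}
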