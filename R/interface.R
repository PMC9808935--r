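#' @title Pipeline entry points and report writers
#'
#' @description [run_base_case()] and [run_uncertainty()] tie the modules
#' together: they load (or accept) a configuration, run the requested
#' analysis, and write plain-CSV tables plus a JSON run manifest to an
#' output directory. A thin command-line wrapper over exactly these
#' functions ships at `system.file("cli", "valvecea", package =
#' "valvecea")`.
#'
#' @name interface
NULL

.resolve_config <- function(config) {
  if (inherits(config, "valvecea_config")) {
    .assert_valid(config)
    config
  } else load_model_config(config)
}

.ensure_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
    message("created output directory ", out_dir)
  }
  out_dir
}

.manifest <- function(command, cfg, out_dir, files, seed = NULL) {
  man <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    command = command,
    config_hash = config_hash(cfg),
    seed = seed,
    files = files,
    package_version = as.character(utils::packageVersion("valvecea")))
  path <- file.path(out_dir, paste0("manifest_", command, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  man$files <- c(files, basename(path))
  invisible(man)
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  basename(path)
}

#' Export a cohort trace as CSV
#'
#' One row per cycle, columns in the canonical [health_states()] order.
#'
#' @param trace A `"valvecea_trace"`.
#' @param path Destination file.
#' @return The path, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(cycle = as.integer(rownames(trace$occupancy)),
                   trace$occupancy, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the deterministic base case and write its reports
#'
#' Evaluates both strategies, writes a results table in the shape of a
#' published base-case table (per-arm cost and QALYs with the incremental
#' columns, in IRR and US$), a structured JSON summary, per-arm trace CSVs
#' and the arm-level acute-cost breakdowns, plus a run manifest.
#'
#' @param config Path to a YAML configuration, or a `"valvecea_config"`.
#' @param out_dir Output directory (created if missing).
#' @return The run manifest, invisibly.
#' @export
run_base_case <- function(config, out_dir) {
  cfg <- .resolve_config(config)
  .ensure_dir(out_dir)
  res <- run_model(cfg)
  inc <- res$incremental

  tab <- data.frame(
    strategy = c("TAVI", "SAVR"),
    cost_irr = c(res$TAVI$cost, res$SAVR$cost),
    cost_usd = to_usd(c(res$TAVI$cost, res$SAVR$cost), cfg),
    qalys = c(res$TAVI$qalys, res$SAVR$qalys),
    incremental_cost_irr = c(inc$delta_cost, NA),
    incremental_qalys = c(inc$delta_qalys, NA),
    icer_irr_per_qaly = c(inc$icer, NA))
  files <- .write_csv(tab, file.path(out_dir, "base_case.csv"))

  summary <- list(
    arms = list(
      TAVI = list(cost_irr = res$TAVI$cost, cost_usd = to_usd(res$TAVI$cost, cfg),
                  qalys = res$TAVI$qalys, life_years = res$TAVI$life_years),
      SAVR = list(cost_irr = res$SAVR$cost, cost_usd = to_usd(res$SAVR$cost, cfg),
                  qalys = res$SAVR$qalys, life_years = res$SAVR$life_years)),
    incremental = list(
      delta_cost_irr = inc$delta_cost, delta_cost_usd = inc$usd$delta_cost,
      delta_qalys = inc$delta_qalys, label = inc$label,
      icer_irr_per_qaly = inc$icer, icer_usd_per_qaly = inc$usd$icer),
    nmb_irr = stats::setNames(
      as.list(nmb(inc, cfg$econ$wtp_grid)),
      paste0("wtp_", cfg$econ$wtp_grid)))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  files <- c(files, "summary.json")

  for (arm in arms()) {
    f <- file.path(out_dir, paste0("trace_", arm, ".csv"))
    write_trace_csv(res[[arm]]$trace, f)
    ac <- acute_cost(arm, cfg)
    bf <- .write_csv(
      data.frame(item = names(ac$breakdown), cost_irr = as.numeric(ac$breakdown)),
      file.path(out_dir, paste0("acute_cost_", arm, ".csv")))
    files <- c(files, basename(f), bf)
  }
  .manifest("run-base", cfg, out_dir, files)
}

#' Run an uncertainty analysis and write its reports
#'
#' * `mode = "psa"`: Monte-Carlo probabilistic sensitivity analysis;
#'   writes the scatter table (`psa_scatter.csv`), the acceptability curve
#'   (`ceac.csv`) and a JSON summary with both mean-ICER readings.
#' * `mode = "owsa"`: one-way analysis over the multiplier grid for the
#'   requested parameters; writes the per-parameter curves
#'   (`owsa_curves.csv`) and the tornado ordering (`tornado.csv`).
#' * `mode = "ceac"`: recomputes the acceptability curve from a previously
#'   written `psa_scatter.csv` in `out_dir` (run `psa` first).
#'
#' @param config Path to a YAML configuration, or a `"valvecea_config"`.
#' @param mode `"psa"`, `"owsa"` or `"ceac"`.
#' @param out_dir Output directory (created if missing).
#' @param n PSA iterations (default 10000).
#' @param seed Integer seed for the PSA draw stream.
#' @param parameters Character vector of parameters for `owsa`, or
#'   `"all"` for the default five event-rate drivers.
#' @param wtp_grid Optional willingness-to-pay grid override for the CEAC.
#' @return The run manifest, invisibly.
#' @export
run_uncertainty <- function(config, mode = c("psa", "owsa", "ceac"), out_dir,
                            n = 10000, seed = 1, parameters = "all",
                            wtp_grid = NULL) {
  mode <- match.arg(mode)
  cfg <- .resolve_config(config)
  .ensure_dir(out_dir)
  grid <- wtp_grid %||% cfg$econ$wtp_grid

  if (mode == "psa") {
    psa <- run_psa(cfg, n = n, seed = seed)
    scatter <- psa$draws[, c("iteration", "delta_cost", "delta_qalys", "icer_label")]
    names(scatter) <- c("iteration", "delta_cost_irr", "delta_qalys", "icer_label")
    files <- .write_csv(scatter, file.path(out_dir, "psa_scatter.csv"))
    cc <- ceac(psa, grid)
    files <- c(files, .write_csv(
      data.frame(wtp_irr = cc$wtp, probability = cc$probability),
      file.path(out_dir, "ceac.csv")))
    sm <- psa_summary(psa)
    sm$quadrant_counts <- as.list(sm$quadrant_counts)
    sm$base_icer_irr <- psa$base$icer
    jsonlite::write_json(sm, file.path(out_dir, "psa_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    files <- c(files, "psa_summary.json")
    return(.manifest("run-psa", cfg, out_dir, files, seed = seed))
  }

  if (mode == "owsa") {
    pars <- if (identical(parameters, "all")) owsa_default_parameters() else parameters
    curves <- lapply(pars, function(p) owsa(cfg, p))
    all_curves <- do.call(rbind, curves)
    files <- .write_csv(all_curves, file.path(out_dir, "owsa_curves.csv"))
    files <- c(files, .write_csv(tornado(curves),
                                 file.path(out_dir, "tornado.csv")))
    return(.manifest("run-owsa", cfg, out_dir, files))
  }

  # mode == "ceac": derive the curve from an existing PSA scatter
  scatter_path <- file.path(out_dir, "psa_scatter.csv")
  if (!file.exists(scatter_path))
    stop("no psa_scatter.csv in ", out_dir,
         "; run run_uncertainty(mode = \"psa\") first")
  d <- utils::read.csv(scatter_path)
  prob <- vapply(grid, function(w)
    mean(w * d$delta_qalys - d$delta_cost_irr > 0), numeric(1))
  files <- .write_csv(data.frame(wtp_irr = grid, probability = prob),
                      file.path(out_dir, "ceac.csv"))
  .manifest("ceac", cfg, out_dir, files)
}
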