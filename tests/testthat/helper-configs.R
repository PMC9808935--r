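# config builders shared across the suite

cfg_calibrated <- function() {
  load_model_config(system.file("extdata", "model_calibrated.yaml",
                                package = "valvecea"))
}

# single-utility, constant-hazard, stroke-free configuration whose value
# function has a geometric-series closed form
cfg_degenerate <- function(u = 0.72, p_entry_death = 0.25, p_death = 0.25,
                           rate = 0.065, max_cycles = 50L, eps = 1e-4,
                           stroke = 0, costs = list()) {
  cfg <- default_config()
  cfg$utilities$mean[] <- u
  cfg$utilities$sd[] <- 0
  for (arm in arms()) {
    cfg$events[[arm]][] <- 0
    cfg$events[[arm]][["stroke"]] <- stroke
    cfg$entry[[arm]][] <- c(1 - p_entry_death, 0, 0, 0, p_entry_death)
  }
  cfg$costs <- costs
  cfg$econ$discount_rate <- rate
  cfg$econ$max_cycles <- as.integer(max_cycles)
  cfg$econ$survival_stop_epsilon <- eps
  cfg$knobs$annual_death_override <- p_death
  cfg
}

# randomized valid configuration (fixed seed per call site)
cfg_random <- function(seed) {
  set.seed(seed)
  cfg <- default_config()
  u <- sort(runif(4, 0.3, 0.9), decreasing = TRUE)
  cfg$utilities$mean[] <- u
  cfg$utilities$sd[] <- vapply(u, function(m) runif(1, 0.05, 0.9 * sqrt(m * (1 - m))),
                               numeric(1))
  cfg$utilities$stroke_disutility <- runif(1, 0.1, 0.5)
  for (arm in arms()) {
    cfg$events[[arm]][] <- runif(7, 0, 0.4)
    w <- runif(5, 0.05, 1)
    cfg$entry[[arm]][] <- w / sum(w)
  }
  cfg$knobs$annual_death_override <- runif(1, 0.15, 0.6)
  stopifnot(length(validate_config(cfg)) == 0)
  cfg
}

# strip every sampling distribution so the PSA collapses to the base case
cfg_zero_variance <- function(cfg) {
  cfg$utilities$sd[] <- 0
  for (i in seq_along(cfg$costs)) {
    cfg$costs[[i]]$sd <- NULL
    cfg$costs[[i]]$sampling <- "FIXED"
  }
  cfg
}

# moment pairs printed with a Beta/Gamma tag in the parameter tables
table_beta_moments <- function() {
  list(c(0.72, 0.25), c(0.72, 0.25), c(0.53, 0.32), c(0.47, 0.35))
}
table_gamma_moments <- function() {
  list(c(43200000, 4032654), c(75750000, 4326731),
       c(10026000, 1430401), c(6405500, 2720528))
}

# re-read a bundled YAML as a raw list (big money amounts exceed integer
# range, so ints must come back as doubles)
read_raw_yaml <- function(path) {
  yaml::read_yaml(path, handlers = list(int = function(x) as.numeric(x)))
}
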