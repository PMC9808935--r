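test_that("bundled default YAML reproduces the in-code defaults", {
  cfg <- load_model_config(system.file("extdata", "model_default.yaml",
                                       package = "valvecea"))
  expect_equal(unclass(cfg), unclass(default_config()))
  expect_equal(cfg$utilities$mean[["NYHA1"]], 0.72)
  expect_identical(config_hash(cfg), config_hash(default_config()))
})

test_that("omitted econ/knobs blocks are filled with documented defaults", {
  cfg0 <- default_config()
  raw <- read_raw_yaml(system.file("extdata", "model_default.yaml",
                                            package = "valvecea"))
  raw$knobs <- NULL
  raw$econ <- NULL
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(raw, path)
  cfg <- load_model_config(path)
  expect_length(cfg$knobs$owsa_grid, 8)
  expect_equal(cfg$econ$discount_rate, 0.065)
  expect_equal(cfg$knobs, cfg0$knobs)
})

test_that("loading rejects invalid values and unknown keys loudly", {
  raw <- read_raw_yaml(system.file("extdata", "model_default.yaml",
                                            package = "valvecea"))
  bad <- raw
  bad$utilities$mean$NYHA1 <- 1.3
  p1 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(bad, p1)
  expect_error(load_model_config(p1), "NYHA1")

  bad2 <- raw
  bad2$unknown_block <- list(a = 1)
  p2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(bad2, p2)
  expect_error(load_model_config(p2), "unknown_block")

  bad3 <- raw
  bad3$events$TAVI$typo_event <- 0.1
  p3 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(bad3, p3)
  expect_error(load_model_config(p3), "typo_event")
})

test_that("validate_config flags exactly the broken invariants", {
  expect_identical(validate_config(default_config()), character(0))

  cfg <- default_config()
  cfg$entry$TAVI[["death"]] <- 0.15   # sum 0.9
  v <- validate_config(cfg)
  expect_length(v, 1)
  expect_match(v, "entry\\$TAVI")

  cfg <- default_config()
  cfg$utilities$sd[["NYHA4"]] <- 0.50  # 0.25 >= 0.47 * 0.53 = 0.2491
  v <- validate_config(cfg)
  expect_length(v, 1)
  expect_match(v, "Beta")

  cfg <- default_config()
  cfg$costs[[1]]$assignment[[1]]$event <- "not_an_event"
  cfg$costs[[1]]$assignment[[1]]$phase <- "ACUTE_EVENT"
  expect_match(validate_config(cfg), "not_an_event")
})

test_that("beta moment matching round-trips and rejects infeasible variance", {
  sp <- beta_from_moments(0.72, 0.25)
  expect_equal(sp$alpha, 1.6024, tolerance = 1e-4)
  expect_equal(sp$beta, 0.6232, tolerance = 1e-4)
  sp2 <- beta_from_moments(0.47, 0.35)
  expect_equal(sp2$alpha, 0.4857, tolerance = 1e-4)
  expect_equal(sp2$beta, 0.54774, tolerance = 1e-4)

  for (ms in table_beta_moments()) {
    sp <- beta_from_moments(ms[1], ms[2])
    implied_mean <- sp$alpha / (sp$alpha + sp$beta)
    implied_var <- sp$alpha * sp$beta /
      ((sp$alpha + sp$beta)^2 * (sp$alpha + sp$beta + 1))
    expect_equal(implied_mean, ms[1], tolerance = 1e-9)
    expect_equal(sqrt(implied_var), ms[2], tolerance = 1e-9)
  }

  # symmetric, vanishing-variance limit concentrates at the mean
  sp <- beta_from_moments(0.5, 1e-6)
  expect_equal(sp$alpha, sp$beta)
  expect_gt(sp$alpha, 1e10)

  expect_error(beta_from_moments(0.47, 0.51), "not feasible")
  expect_error(beta_from_moments(1.1, 0.1), "inside")
})

test_that("gamma moment matching round-trips", {
  sp <- gamma_from_moments(43200000, 4032654)
  expect_equal(sp$shape, 114.8, tolerance = 1e-3)
  expect_equal(sp$shape * sp$scale, 43200000, tolerance = 1e-9)
  expect_equal(gamma_from_moments(6405500, 2720528)$shape, 5.543, tolerance = 1e-3)
  for (ms in table_gamma_moments()) {
    sp <- gamma_from_moments(ms[1], ms[2])
    expect_equal(sp$shape * sp$scale, ms[1], tolerance = 1e-9)
    expect_equal(sqrt(sp$shape) * sp$scale, ms[2], tolerance = 1e-9)
  }
  # sd equal to the mean is the exponential special case
  expect_equal(gamma_from_moments(5e6, 5e6)$shape, 1)
  expect_error(gamma_from_moments(-1, 1), "positive")
})

test_that("annualization inverts cumulation over the follow-up horizon", {
  expect_lt(abs(annual_prob_from_cumulative(0.153, 5) - 0.0327), 1e-4)
  # independent oracle through the hazard scale
  expect_equal(annual_prob_from_cumulative(0.153, 5),
               1 - exp(log(1 - 0.153) / 5), tolerance = 1e-12)
  expect_identical(annual_prob_from_cumulative(0, 7), 0)
  expect_equal(annual_prob_from_cumulative(0.4, 1), 0.4)
  for (p in seq(0, 0.99, by = 0.03)) {
    for (yrs in c(1, 2, 5, 10)) {
      a <- annual_prob_from_cumulative(p, yrs)
      expect_equal(1 - (1 - a)^yrs, p, tolerance = 1e-12)
    }
  }
  expect_error(annual_prob_from_cumulative(1, 5), "hazard")
})
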