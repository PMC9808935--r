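test_that("PSA draws vary only the parameters with a stated distribution", {
  cfg <- default_config()
  set.seed(1)
  draws <- replicate(50, sample_parameter_set(cfg), simplify = FALSE)
  for (d in draws) {
    expect_identical(d$events, cfg$events)
    expect_identical(d$entry, cfg$entry)
    fixed <- vapply(cfg$costs, function(it) it$sampling == "FIXED", TRUE)
    expect_identical(lapply(d$costs[fixed], `[[`, "mean"),
                     lapply(cfg$costs[fixed], `[[`, "mean"))
    expect_true(all(d$utilities$mean >= 0 & d$utilities$mean <= 1))
    expect_true(all(vapply(d$costs, `[[`, 0, "mean") >= 0))
  }
  # same stream position, same draw
  set.seed(99); a <- sample_parameter_set(cfg)
  set.seed(99); b <- sample_parameter_set(cfg)
  expect_identical(a, b)
})

test_that("PSA is deterministic given (config, n, seed)", {
  cfg <- default_config()
  p1 <- run_psa(cfg, n = 25, seed = 7)
  p2 <- run_psa(cfg, n = 25, seed = 7)
  expect_identical(p1$draws, p2$draws)
  expect_identical(ceac(p1), ceac(p2))
  p3 <- run_psa(cfg, n = 25, seed = 8)
  expect_false(identical(p1$draws$delta_cost, p3$draws$delta_cost))
})

test_that("a zero-variance PSA collapses to the base case", {
  cfg <- cfg_zero_variance(default_config())
  base <- run_model(cfg)$incremental
  psa <- run_psa(cfg, n = 3, seed = 5)
  expect_equal(psa$draws$delta_cost, rep(base$delta_cost, 3))
  expect_equal(psa$draws$delta_qalys, rep(base$delta_qalys, 3))

  # CEAC is an exact step at the base ICER (ties count as not cost-effective)
  grid <- sort(c(base$icer * c(0.5, 0.9, 1.1, 2), base$icer))
  cc <- ceac(psa, grid)
  expect_equal(cc$probability, as.numeric(grid > base$icer))

  sm <- psa_summary(psa)
  expect_equal(sm$icer_ratio_of_means, base$icer)
  expect_equal(sm$icer_mean_of_ratios, base$icer)
})

test_that("PSA means recover the base case within Monte-Carlo error", {
  cfg <- default_config()
  base <- run_model(cfg)$incremental
  psa <- run_psa(cfg, n = 400, seed = 11)
  se_de <- sd(psa$draws$delta_qalys) / sqrt(psa$n)
  expect_lt(abs(mean(psa$draws$delta_qalys) - base$delta_qalys), 3 * se_de)
  se_dc <- sd(psa$draws$delta_cost) / sqrt(psa$n)
  expect_lt(abs(mean(psa$draws$delta_cost) - base$delta_cost), 3 * se_dc)
})

test_that("CEAC definition and monotonicity hold", {
  cfg <- default_config()
  psa <- run_psa(cfg, n = 200, seed = 3)
  cc <- ceac(psa, c(1, psa$wtp_grid[-1]))
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  expect_equal(ceac(psa, c(1e-9, 1))$probability[1],
               mean(psa$draws$delta_cost < 0))
  if (all(psa$draws$delta_qalys > 0))
    expect_true(all(diff(cc$probability) >= 0))
})

test_that("summary quadrant counts partition the draws", {
  psa <- run_psa(default_config(), n = 60, seed = 21)
  sm <- psa_summary(psa)
  expect_equal(sum(sm$quadrant_counts), psa$n)
  expect_equal(sm$n_excluded_from_mean_of_ratios,
               psa$n - sm$quadrant_counts[["RATIO"]])
})

test_that("ratio-of-means recovers a planted truth on synthetic draws", {
  # symmetric cloud around (delta C, delta E) = (4e8, 0.4): planted ICER 1e9
  set.seed(17)
  n <- 4000
  d <- data.frame(iteration = 1:n,
                  delta_cost = 4e8 + rnorm(n, 0, 4e7),
                  delta_qalys = 0.4 + rnorm(n, 0, 0.04))
  d$icer_label <- ifelse(d$delta_qalys > 0 & d$delta_cost > 0, "RATIO", "OTHER")
  psa <- structure(list(draws = d, n = n, seed = 17, wtp_grid = c(5e8, 1e9)),
                   class = "valvecea_psa")
  sm <- psa_summary(psa)
  expect_equal(sm$icer_ratio_of_means, 1e9, tolerance = 0.02)
})

test_that("one-way analysis reproduces the base ICER at multiplier one", {
  cfg <- default_config()
  base <- run_model(cfg)$incremental
  cv <- owsa(cfg, "stroke", grid = c(0.5, 1.0, 2.5))
  expect_equal(cv$icer[cv$multiplier == 1], base$icer)
  # TAVI's stroke excess makes the ICER increase with the stroke rate
  expect_gt(cv$icer[cv$multiplier == 2.5], cv$icer[cv$multiplier == 1])
  expect_error(owsa(cfg, "no_such_parameter"), "eligible")
})

test_that("owsa can scale scalar parameters by dotted path", {
  cfg <- default_config()
  cv <- owsa(cfg, "utilities.stroke_disutility", grid = c(1, 2))
  expect_equal(nrow(cv), 2)
  expect_false(identical(cv$icer[1], cv$icer[2]))
})

test_that("a zero stroke rate empties the stroke compartment", {
  cfg <- default_config()
  for (arm in arms()) cfg$events[[arm]][["stroke"]] <- 0
  tr <- run_arm("TAVI", cfg)$trace
  expect_true(all(tr$occupancy[, 5:8] == 0))
})

test_that("tornado ordering is by descending swing with stable tie-break", {
  mk <- function(name, icers) data.frame(parameter = name,
                                         multiplier = seq_along(icers),
                                         delta_cost = NA, delta_qalys = NA,
                                         icer = icers)
  one <- tornado(list(mk("a", c(5, 10))))
  expect_equal(nrow(one), 1)
  expect_equal(one$swing, 5)

  tor <- tornado(list(mk("b", c(0, 5)), mk("a", c(10, 20)),
                      mk("c", c(100, 105))))
  expect_equal(tor$parameter, c("a", "b", "c"))  # swings 10, 5, 5; b < c
  expect_equal(tor$icer_low, c(10, 0, 100))
  expect_equal(tor$icer_high, c(20, 5, 105))
})

test_that("stroke is the dominant driver among the default five parameters", {
  cfg <- default_config()
  curves <- lapply(owsa_default_parameters(), function(p) owsa(cfg, p))
  tor <- tornado(curves)
  expect_equal(tor$parameter[1], "stroke")
  expect_true(all(diff(tor$swing) <= 0))
})
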