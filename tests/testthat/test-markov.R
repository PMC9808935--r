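test_that("discount factors follow 1/(1+r)^t", {
  expect_identical(discount_factor(0, 0.065), 1)
  expect_equal(discount_factor(1, 0.065), 0.938967, tolerance = 1e-6)
  expect_equal(discount_factor(0:10, 0), rep(1, 11))
  expect_error(discount_factor(-1, 0.065), "non-negative")
})

test_that("transition matrices have the published structure", {
  cfg <- default_config()
  for (arm in arms()) {
    M <- build_transition_matrix(arm, 1, cfg)
    expect_equal(unname(rowSums(M)), rep(1, 9), tolerance = 1e-12)
    expect_true(all(M >= 0 & M <= 1))
    # death absorbing
    expect_equal(unname(M["DEAD", ]), c(rep(0, 8), 1))
    # identical all-cause death probability from every alive state
    expect_equal(unname(M[1:8, "DEAD"]),
                 rep(cfg$entry[[arm]][["death"]], 8))
    # NYHA1 row supported only on {stay, stroke counterpart, death}
    expect_equal(unname(which(M["NYHA1", ] > 0)),
                 which(health_states() %in% c("NYHA1", "NYHA1_STROKE", "DEAD")))
    # no return from the post-stroke compartment
    expect_equal(unname(M[5:8, 1:4]), matrix(0, 4, 4))
  }
})

test_that("competing risks compose multiplicatively (stroke among survivors)", {
  cfg <- cfg_degenerate(p_death = 0.25, stroke = 0.0327)
  cfg$knobs$event_annualization <- "ALREADY_ANNUAL"
  M <- build_transition_matrix("TAVI", 1, cfg)
  expect_equal(M["NYHA1", "NYHA1_STROKE"], 0.75 * 0.0327, tolerance = 1e-12)
  expect_equal(M["NYHA1", "NYHA1"], 0.75 * (1 - 0.0327), tolerance = 1e-12)

  # stroke probability zero leaves the stroke block unreachable
  M0 <- build_transition_matrix("TAVI", 1, cfg_degenerate(stroke = 0))
  expect_true(all(M0[1:4, 5:8] == 0))
})

test_that("cohort traces conserve probability and mortality is monotone", {
  configs <- c(list(default_config(), cfg_calibrated()),
               lapply(1:8, cfg_random))
  for (cfg in configs) for (arm in arms()) {
    tr <- run_cohort(entry_distribution(arm, cfg), arm, cfg)
    expect_equal(unname(rowSums(tr$occupancy)),
                 rep(1, nrow(tr$occupancy)), tolerance = 1e-9)
    dead <- tr$occupancy[, "DEAD"]
    expect_true(all(diff(dead) >= -1e-12))
  }
})

test_that("degenerate cohorts follow closed forms", {
  # all dead at entry: absorbing forever
  cfg <- cfg_degenerate(p_entry_death = 1)
  tr <- run_cohort(entry_distribution("TAVI", cfg), "TAVI", cfg)
  expect_true(all(tr$occupancy[, "DEAD"] == 1))

  # certain death in one cycle
  cfg1 <- cfg_degenerate(p_death = 1)
  tr1 <- run_cohort(entry_distribution("TAVI", cfg1), "TAVI", cfg1)
  expect_equal(tr1$occupancy[nrow(tr1$occupancy), "DEAD"], 1)

  # constant hazard, no strokes: geometric survival decay
  cfg2 <- cfg_degenerate(p_entry_death = 0.25, p_death = 0.25)
  tr2 <- run_cohort(entry_distribution("TAVI", cfg2), "TAVI", cfg2)
  surv <- 1 - tr2$occupancy[, "DEAD"]
  t <- seq_len(nrow(tr2$occupancy)) - 1
  expect_equal(unname(surv), 0.75 * 0.75^t, tolerance = 1e-12)
})

test_that("accumulated QALYs match the geometric-series closed form", {
  u <- 0.72; s0 <- 0.75; p <- 0.25; r <- 0.065
  cfg <- cfg_degenerate(u = u, p_entry_death = 1 - s0, p_death = p, rate = r)
  res <- run_arm("TAVI", cfg)
  Tn <- res$trace$stopped_at
  t <- seq_len(Tn)
  closed <- u * s0 * sum((1 - p)^(t - 1) / (1 + r)^t)
  expect_equal(res$qalys, closed, tolerance = 1e-9)

  # single-cycle horizon: one discounted utility term
  cfg1 <- cfg_degenerate(u = 0.72, p_entry_death = 0, p_death = 1, rate = 0.065,
                         max_cycles = 1)
  expect_equal(run_arm("TAVI", cfg1)$qalys, 0.72 / 1.065, tolerance = 1e-12)
})

test_that("zero rate without half-cycle correction leaves sums undiscounted", {
  cfg <- cfg_degenerate(rate = 0)
  res <- run_arm("TAVI", cfg)
  expect_identical(res$qalys, res$undiscounted_qalys)

  cfg0 <- cfg_degenerate(u = 0)
  expect_equal(run_arm("TAVI", cfg0)$qalys, 0)
})

test_that("reward vectors defer the stroke disutility to cycle 2", {
  cfg <- default_config()
  r1 <- cycle_rewards("TAVI", 1, cfg)
  r3 <- cycle_rewards("TAVI", 3, cfg)
  expect_equal(r3$qaly[["NYHA4_STROKE"]], max(0, 0.47 - 0.39))
  expect_equal(r1$qaly[["NYHA2_STROKE"]], 0.72)  # rehabilitation year
  expect_equal(r3$qaly[["NYHA2_STROKE"]], 0.72 - 0.39)
  expect_equal(r1$qaly[["DEAD"]], 0)
  expect_equal(r1$cost[["DEAD"]], 0)
  # floor at zero when the disutility exceeds the class utility
  cfg$utilities$mean[["NYHA4"]] <- 0.30
  expect_equal(cycle_rewards("TAVI", 2, cfg)$qaly[["NYHA4_STROKE"]], 0)
})

test_that("half-cycle correction averages start and end occupancy", {
  cfg <- cfg_degenerate()
  on <- cfg; on$econ$half_cycle_correction <- TRUE
  q_off <- run_arm("TAVI", cfg)$qalys
  q_on <- run_arm("TAVI", on)$qalys
  # occupancy declines, so the trapezoid value is strictly smaller here
  expect_lt(q_on, q_off)
  expect_gt(q_on, 0.5 * q_off)
})

test_that("costs scale linearly and never fall below the acute cost", {
  cfg <- default_config()
  res <- run_arm("TAVI", cfg)
  expect_gte(res$cost, res$acute_cost)
  cfg2 <- cfg
  for (i in seq_along(cfg2$costs)) cfg2$costs[[i]]$mean <- 2 * cfg2$costs[[i]]$mean
  expect_equal(run_arm("TAVI", cfg2)$cost, 2 * res$cost, tolerance = 1e-12)
})
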