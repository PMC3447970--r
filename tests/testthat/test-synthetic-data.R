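test_that("design counts match the blocked 3x3 experiment", {
  cfg <- generator_config(seed = 3)
  des <- build_design(cfg)
  expect_equal(nrow(des$conditions), 9)
  expect_equal(nrow(des$schedule), 7 * 36)
  per_subj <- table(des$schedule$subject_id)
  expect_true(all(per_subj == 36))
  # every condition appears exactly blocks_per_condition times per subject
  tab <- table(des$schedule$subject_id, des$schedule$condition_id)
  expect_true(all(tab == 4))
  trials <- simulate_experiment(cfg)
  expect_equal(nrow(trials), 7 * 1080)
  expect_equal(nrow(simulate_experiment(
    generator_config(n_subjects = 1, blocks_per_condition = 1, seed = 3))),
    270)
})

test_that("policies map onto MEG excursions as specified", {
  cfg_opt <- generator_config(policy = "optimal", seed = 5)
  cfg_s1 <- generator_config(policy = "scaled", kappa = 1, seed = 5)
  cfg_s8 <- generator_config(policy = "scaled", kappa = 0.8, seed = 5)
  p_opt <- policy_excursions(cfg_opt)
  expect_equal(policy_excursions(cfg_s1), p_opt)
  expect_equal(policy_excursions(cfg_s8)$planned_excursion_mm,
               0.8 * p_opt$planned_excursion_mm)
  fx <- setNames(rep(-3, 9), reach_conditions()$condition_id)
  p_fx <- policy_excursions(
    generator_config(policy = "fixed", fixed_excursions_mm = fx, seed = 5))
  expect_equal(p_fx$planned_excursion_mm, rep(-3, 9))
})

test_that("optimal policy matches a brute-force grid oracle on a toy model", {
  cfg <- generator_config(sigma_truth = toy_sigma(), seed = 2)
  plan <- policy_excursions(cfg)
  for (i in c(1, 5, 9)) {
    ci <- cfg$conditions[i, ]
    mu2 <- cfg$endpoint_bias_mm[ci$obstacle_location_index]
    g <- seq(-40, 0, by = 0.01)
    s1 <- 2 - 0.1 * g
    s2 <- 2 - 0.1 * g
    eg <- ci$obstacle_cost_points * pnorm(g / s1) +
      ci$target_reward_points *
        (pnorm((3.25 - mu2) / s2) - pnorm((-3.25 - mu2) / s2))
    expect_lt(abs(plan$planned_excursion_mm[i] - g[which.max(eg)]), 0.05)
  }
})

test_that("simulation is seed-reproducible and moment-faithful", {
  cfg <- small_config(seed = 11)
  expect_identical(simulate_experiment(cfg), simulate_experiment(cfg))
  expect_false(identical(simulate_experiment(small_config(seed = 12)),
                         simulate_experiment(cfg)))

  # large per-condition n: sample SDs within 3% of ground truth
  big <- generator_config(n_subjects = 1, blocks_per_condition = 112,
                          seed = 21) # 3360 trials/condition
  trials <- simulate_experiment(big)
  plan <- policy_excursions(big)
  cond <- big$conditions
  for (i in c(2, 6)) {
    sub <- trials[trials$condition_id == cond$condition_id[i], ]
    e <- plan$planned_excursion_mm[i]
    loc <- cond$obstacle_location_index[i]
    s1 <- predict_sigma(big$sigma_truth, loc, "obstacle", e)
    s2 <- predict_sigma(big$sigma_truth, loc, "target", e)
    expect_lt(abs(sd(sub$excursion_mm) / s1 - 1), 0.04)
    expect_lt(abs(sd(sub$endpoint_mm) / s2 - 1), 0.04)
    expect_lt(abs(mean(sub$excursion_mm) - e), 4 * s1 / sqrt(nrow(sub)))
  }
})

test_that("generated outcome frequencies match the generating distribution", {
  big <- generator_config(n_subjects = 1, blocks_per_condition = 112,
                          seed = 31)
  trials <- simulate_experiment(big)
  plan <- policy_excursions(big)
  i <- 3 # V = -5 at the nearest obstacle: non-trivial obstacle risk
  ci <- big$conditions[i, ]
  e <- plan$planned_excursion_mm[i]
  d <- crossing_distribution(
    e, plan$planned_endpoint_mm[i],
    predict_sigma(big$sigma_truth, ci$obstacle_location_index, "obstacle", e),
    predict_sigma(big$sigma_truth, ci$obstacle_location_index, "target", e)
  )
  an <- outcome_probabilities(d, ci)
  sub <- trials[trials$condition_id == ci$condition_id, ]
  n <- nrow(sub)
  for (lev in names(an)) {
    se <- sqrt(max(an[[lev]] * (1 - an[[lev]]), 1e-8) / n)
    expect_lt(abs(mean(sub$outcome == lev) - an[[lev]]), 3.5 * se)
  }
})

test_that("AR(1) switch induces the requested lag-1 autocorrelation", {
  cfg <- generator_config(n_subjects = 1, blocks_per_condition = 40,
                          trials_per_block = 30, ar1_coef = 0.5, seed = 8)
  trials <- simulate_experiment(cfg)
  one <- trials[trials$condition_id == trials$condition_id[1], ]
  blocks <- split(one$excursion_mm, one$block_index)
  lag1 <- vapply(blocks, function(b) {
    trial_autocorrelation(b, max_lag = 2)$acf[2]
  }, numeric(1))
  # short-series acf is biased low (~ -1/n plus AR shrinkage); wide check
  expect_gt(mean(lag1), 0.3)
  expect_lt(mean(lag1), 0.6)
  # marginal SD is preserved by the stationary AR construction
  e <- policy_excursions(cfg)$planned_excursion_mm[1]
  s1 <- predict_sigma(cfg$sigma_truth, 1, "obstacle", e)
  expect_lt(abs(sd(one$excursion_mm) / s1 - 1), 0.1)
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(kappa = 0), "kappa")
  expect_error(generator_config(kappa = 1.2), "kappa")
  expect_error(generator_config(policy = "fixed"), "fixed")
  expect_error(generator_config(n_subjects = 0))
})
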