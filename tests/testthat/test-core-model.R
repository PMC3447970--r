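test_that("condition table encodes the 3x3 design geometry", {
  cond <- reach_conditions()
  expect_equal(nrow(cond), 9)
  expect_equal(cond$obstacle_edge_mm - cond$target_center_mm, rep(6.6, 9))
  expect_true(all(cond$obstacle_cost_points < 0))
  expect_true(all(cond$target_reward_points > 0))
  expect_equal(sort(unique(cond$target_center_mm)), c(0, 38, 75))
  expect_equal(sort(unique(cond$obstacle_cost_points)), c(-5, -2, -1))
})

test_that("outcomes are classified from the two crossing coordinates", {
  cond <- reach_conditions()[1, ]
  expect_equal(classify_outcome(-5, 0, cond), "hit_target_only")
  expect_equal(classify_outcome(0.1, 4, cond), "hit_obstacle_only")
  # target boundary is inclusive; obstacle requires strictly x1 > 0
  expect_equal(classify_outcome(1, 3.25, cond), "hit_both")
  expect_equal(classify_outcome(0, 3.26, cond), "miss_both")
  expect_equal(
    classify_outcome(c(-1, 2), c(0, 10), cond),
    c("hit_target_only", "hit_obstacle_only")
  )
  expect_error(classify_outcome(NaN, 0, cond), "finite")
  expect_error(classify_outcome(1, Inf, cond), "finite")
})

test_that("marginal hit probabilities match the Gaussian closed forms", {
  cond <- reach_conditions()[1, ]
  expect_equal(prob_hit_obstacle(crossing_distribution(0, 0, 3, 1)), 0.5)
  expect_equal(prob_hit_obstacle(crossing_distribution(-4, 0, 4, 1)),
               1 - pnorm(1))
  wide <- list(target_width_mm = 1e9)
  expect_equal(prob_hit_target(crossing_distribution(0, 0, 1, 2), wide), 1,
               tolerance = 1e-12)
  d <- crossing_distribution(0, 0, 1, 3)
  expect_equal(prob_hit_target(d, list(target_width_mm = 6)),
               pnorm(1) - pnorm(-1))
})

test_that("analytic probabilities agree with a Monte-Carlo oracle", {
  cond <- reach_conditions()[6, ]
  cases <- list(
    c(-8, 0, 4, 3, 0.1),
    c(-4, 1.5, 3, 3, 0),
    c(-4, 1, 3, 3, 0.3)
  )
  n <- 2e5
  for (i in seq_along(cases)) {
    p <- cases[[i]]
    d <- crossing_distribution(p[1], p[2], p[3], p[4], p[5])
    s <- sample_crossings(d, n, seed = 100 + i)
    freq_obs <- mean(s$excursion_mm > 0)
    freq_tar <- mean(abs(s$endpoint_mm) <= cond$target_width_mm / 2)
    expect_lt(abs(freq_obs - prob_hit_obstacle(d)),
              3 * sqrt(0.25 / n) + 1e-12)
    expect_lt(abs(freq_tar - prob_hit_target(d, cond)),
              3 * sqrt(0.25 / n) + 1e-12)
    oc <- classify_outcome(s$excursion_mm, s$endpoint_mm, cond)
    an <- outcome_probabilities(d, cond)
    for (lev in names(an)) {
      se <- sqrt(max(an[[lev]] * (1 - an[[lev]]), 1e-8) / n)
      expect_lt(abs(mean(oc == lev) - an[[lev]]), 3.5 * se)
    }
  }
})

test_that("four outcome probabilities are a distribution and factor at rho = 0", {
  cond <- reach_conditions()[1, ]
  d0 <- crossing_distribution(-3, 0.5, 2, 2.5, 0)
  p <- outcome_probabilities(d0, cond)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_equal(p[["hit_both"]],
               prob_hit_obstacle(d0) * prob_hit_target(d0, cond),
               tolerance = 1e-9)
  # nonzero correlation changes the joint but not the margins
  d1 <- crossing_distribution(-3, 0.5, 2, 2.5, 0.4)
  p1 <- outcome_probabilities(d1, cond)
  expect_equal(sum(p1), 1, tolerance = 1e-9)
  expect_equal(p1[["hit_both"]] + p1[["hit_obstacle_only"]],
               prob_hit_obstacle(d1), tolerance = 1e-7)
  expect_false(isTRUE(all.equal(p1[["hit_both"]], p[["hit_both"]])))
})

test_that("expected gain is additive in the marginals and rho-invariant", {
  cond <- reach_conditions()[1, ] # V_T = 2, V_O = -1
  d <- crossing_distribution(-3, 0, 2, 2)
  expect_equal(
    expected_gain(d, cond),
    2 * prob_hit_target(d, cond) - 1 * prob_hit_obstacle(d)
  )
  for (rho in c(0, 0.3, -0.5)) {
    dr <- crossing_distribution(-3, 0, 2, 2, rho)
    expect_equal(expected_gain(dr, cond), expected_gain(d, cond),
                 tolerance = 1e-9)
  }
  # V_O = 0 reduces to the reward term alone
  free <- cond
  free$obstacle_cost_points <- 0
  free$target_width_mm <- 4
  d2 <- crossing_distribution(0, 0, 1, 2)
  expect_equal(expected_gain(d2, free), 2 * (pnorm(1) - pnorm(-1)))
})

test_that("obstacle-hit probability is monotone in mean and spread", {
  mus <- seq(-10, 2, by = 1)
  p <- vapply(mus, function(m)
    prob_hit_obstacle(crossing_distribution(m, 0, 2, 2)), numeric(1))
  expect_true(all(diff(p) > 0))
  sds <- seq(0.5, 6, by = 0.5)
  p2 <- vapply(sds, function(s)
    prob_hit_obstacle(crossing_distribution(-4, 0, s, 2)), numeric(1))
  expect_true(all(diff(p2) > 0)) # mu < 0: fatter tails reach the obstacle
})

test_that("crossing sampler is seeded, reproducible and moment-consistent", {
  d <- crossing_distribution(-5, 1, 2, 3, 0.5)
  a <- sample_crossings(d, 1e5, seed = 42)
  b <- sample_crossings(d, 1e5, seed = 42)
  expect_identical(a, b)
  expect_lt(abs(mean(a$excursion_mm) + 5), 4 * 2 / sqrt(1e5))
  expect_lt(abs(mean(a$endpoint_mm) - 1), 4 * 3 / sqrt(1e5))
  expect_lt(abs(sd(a$excursion_mm) - 2), 0.05)
  expect_lt(abs(cor(a$excursion_mm, a$endpoint_mm) - 0.5), 0.02)
})

test_that("degenerate distribution parameters are rejected", {
  expect_error(crossing_distribution(0, 0, 0, 1), "positive")
  expect_error(crossing_distribution(0, 0, 1, -2), "positive")
  expect_error(crossing_distribution(0, 0, 1, 1, 1), "correlation")
  expect_error(crossing_distribution(NaN, 0, 1, 1), "finite")
  expect_error(prob_hit_obstacle(list(mean_mm = 0)), "crossing_distribution")
})
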