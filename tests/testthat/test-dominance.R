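# Two-condition counterexample with flat noise (sigma = 2 at both planes):
# condition A (cost -5) is observed skirting the obstacle at -1 mm while
# condition B (cost -1) is observed at -4 mm. B's strategy applied under A's
# costs avoids most of the obstacle risk, so A is dominated. Expected gains
# below were computed by hand from the Gaussian closed forms:
#   reward term (both rows): 2 * (pnorm(3.25/2) - pnorm(-3.25/2)) = 1.7916749
#   G[A,A] = 1.7916749 - 5 * pnorm(-0.5) = 0.2489872
#   G[A,B] = 1.7916749 - 5 * pnorm(-2)   = 1.6779242
#   G[B,B] = 1.7916749 - 1 * pnorm(-2)   = 1.7689248
#   G[B,A] = 1.7916749 - 1 * pnorm(-0.5) = 1.4831373
two_condition_fixture <- function() {
  cond <- reach_conditions()[c(3, 1), ] # T1_V3 (cost -5), T1_V1 (cost -1)
  summaries <- tibble::tibble(
    condition_id = cond$condition_id,
    mean_excursion_mm = c(-1, -4),
    mean_endpoint_mm = c(0, 0)
  )
  list(cond = cond, summaries = summaries, model = flat_sigma(2))
}

test_that("gain matrix reproduces hand-computed cross-condition gains", {
  fx <- two_condition_fixture()
  G <- cross_condition_gain_matrix(fx$summaries, fx$model, fx$cond)
  expect_equal(G["T1_V3", "T1_V3"], 0.248987188709, tolerance = 1e-9)
  expect_equal(G["T1_V3", "T1_V1"], 1.677924222600, tolerance = 1e-9)
  expect_equal(G["T1_V1", "T1_V1"], 1.768924750390, tolerance = 1e-9)
  expect_equal(G["T1_V1", "T1_V3"], 1.483137343610, tolerance = 1e-9)
  res <- dominance_test(G)
  expect_equal(res$dominated, c(TRUE, FALSE))
  expect_equal(res$margin_points[1], 1.42893703389, tolerance = 1e-9)
  expect_equal(res$best_strategy_from[1], "T1_V1")
})

test_that("diagonal is the own-strategy gain and shared strategies level rows", {
  cfg <- generator_config(seed = 41)
  su <- summarize_conditions(simulate_experiment(cfg))
  fit <- fit_sigma_lines(su, cfg$conditions)
  G <- cross_condition_gain_matrix(su, fit, cfg$conditions)
  for (i in seq_len(9)) {
    ci <- cfg$conditions[i, ]
    e <- su$mean_excursion_mm[su$condition_id == ci$condition_id]
    mu2 <- su$mean_endpoint_mm[su$condition_id == ci$condition_id]
    d <- crossing_distribution(
      e, mu2,
      predict_sigma(fit, ci$obstacle_location_index, "obstacle", e),
      predict_sigma(fit, ci$obstacle_location_index, "target", e)
    )
    expect_equal(unname(G[i, i]), expected_gain(d, ci), tolerance = 1e-10)
  }
  # all conditions sharing one strategy: each row is constant
  su_same <- su
  su_same$mean_excursion_mm <- -8
  Gs <- cross_condition_gain_matrix(su_same, fit, cfg$conditions)
  expect_equal(apply(Gs, 1, function(r) max(r) - min(r)), rep(0, 9),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("dominance flags depend only on the matrix and respect permutations", {
  fx <- two_condition_fixture()
  G <- cross_condition_gain_matrix(fx$summaries, fx$model, fx$cond)
  perm <- c(2, 1)
  Gp <- G[perm, perm]
  res <- dominance_test(G)
  resp <- dominance_test(Gp)
  expect_equal(resp$dominated[match(res$condition_id, resp$condition_id)],
               res$dominated)
  # threshold larger than every margin suppresses all flags
  res_eps <- dominance_test(G, epsilon = 2)
  expect_false(any(res_eps$dominated))
})

test_that("strategies outside a row's admissible range are excluded, not extrapolated", {
  cond <- reach_conditions()[c(1, 2), ]
  m <- sigma_model(tibble::tibble(
    obstacle_location_index = 1, plane = c("obstacle", "target"),
    intercept_mm = 2, slope = 0.2 # sigma hits zero at e = -10
  ))
  summaries <- tibble::tibble(
    condition_id = cond$condition_id,
    mean_excursion_mm = c(-3, -25),
    mean_endpoint_mm = c(0, 0)
  )
  G <- cross_condition_gain_matrix(summaries, m, cond)
  expect_true(all(is.na(G[, 2]))) # -25 outside sigma-positive range
  expect_error(dominance_test(G), "not evaluable")
  expect_false(any(dominance_test(G[1, 1, drop = FALSE])$dominated))
})

test_that("an agent playing each condition's optimum is never dominated", {
  m <- default_sigma_truth()
  cond <- reach_conditions()
  e_star <- vapply(seq_len(9), function(i)
    optimize_excursion(cond[i, ], m, 0)$e_star_mm, numeric(1))
  summaries <- tibble::tibble(
    condition_id = cond$condition_id,
    mean_excursion_mm = e_star,
    mean_endpoint_mm = 0
  )
  G <- cross_condition_gain_matrix(summaries, m, cond)
  expect_false(any(dominance_test(G)$dominated))
})

test_that("bootstrap flag rates are extreme for clear-cut cases", {
  cfg <- small_config(seed = 51)
  trials <- simulate_experiment(cfg)
  rates <- dominance_bootstrap(trials, cfg$conditions, n_boot = 15, seed = 2,
                               epsilon = 0.05)
  expect_equal(nrow(rates), 9)
  expect_true(all(rates$flag_rate >= 0 & rates$flag_rate <= 1))
})
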