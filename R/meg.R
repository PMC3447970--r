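#' Expected-gain curve over theoretical excursions
#'
#' Sweeps a grid of theoretical (non-positive) planned excursions e' for one
#' condition. At each e' the crossing distribution has mean (e',
#' `endpoint_mean_mm`), standard deviations from the fitted sigma lines at
#' e', and zero correlation; expected cost, expected reward and their sum are
#' evaluated there.
#'
#' @param condition One row of [reach_conditions()].
#' @param model A fitted [sigma_model()].
#' @param endpoint_mean_mm Planned endpoint mu2 for this condition (the
#'   observed average endpoint error; not optimized over).
#' @param step_mm Grid spacing, default 0.1 mm.
#' @param range_mm Search interval before the sigma-positivity restriction,
#'   default `c(-40, 0)`.
#' @return A list of class `eg_curve`: `curve` (tibble `excursion_mm`,
#'   `expected_cost`, `expected_reward`, `expected_gain`), `e_star_mm`,
#'   `gain_at_max`, `condition_id`.
#' @export
eg_curve <- function(condition, model, endpoint_mean_mm,
                     step_mm = 0.1, range_mm = c(-40, 0)) {
  rng <- sigma_positive_range(model, condition$obstacle_location_index,
                              range_mm = range_mm)
  grid <- seq(rng[1], rng[2], by = step_mm)
  if (length(grid) == 0 || grid[length(grid)] < rng[2]) {
    grid <- c(grid, rng[2])
  }
  comp <- eg_components(condition, model, endpoint_mean_mm, grid)
  opt <- optimize_excursion(condition, model, endpoint_mean_mm,
                            range_mm = range_mm)
  structure(
    list(
      curve = tibble::tibble(
        excursion_mm = grid,
        expected_cost = comp$cost,
        expected_reward = comp$reward,
        expected_gain = comp$gain
      ),
      e_star_mm = opt$e_star_mm,
      gain_at_max = opt$gain,
      condition_id = condition$condition_id
    ),
    class = "eg_curve"
  )
}

# Vectorised expected-gain components at excursions e (mm) for one condition.
eg_components <- function(condition, model, endpoint_mean_mm, e) {
  loc <- condition$obstacle_location_index
  s1 <- predict_sigma(model, loc, "obstacle", e)
  s2 <- predict_sigma(model, loc, "target", e)
  half <- condition$target_width_mm / 2
  p_obs <- stats::pnorm(e / s1)
  p_tar <- stats::pnorm((half - endpoint_mean_mm) / s2) -
    stats::pnorm((-half - endpoint_mean_mm) / s2)
  cost <- condition$obstacle_cost_points * p_obs
  reward <- condition$target_reward_points * p_tar
  list(cost = cost, reward = reward, gain = cost + reward)
}

#' Maximum-expected-gain excursion for one condition
#'
#' Locates the theoretical excursion e* maximizing expected gain by a coarse
#' 0.5 mm grid sweep followed by bounded scalar refinement around the best
#' grid point. Flat maxima are resolved toward the smallest |e*|
#' (minimal-deviation convention).
#'
#' @inheritParams eg_curve
#' @return List with `e_star_mm` and `gain` (points).
#' @export
optimize_excursion <- function(condition, model, endpoint_mean_mm,
                               range_mm = c(-40, 0)) {
  rng <- sigma_positive_range(model, condition$obstacle_location_index,
                              range_mm = range_mm)
  grid <- unique(c(seq(rng[1], rng[2], by = 0.5), rng[2]))
  f <- function(e) {
    eg_components(condition, model, endpoint_mean_mm, e)$gain
  }
  g <- f(grid)
  best <- which.max(g)
  lo <- grid[max(1, best - 1)]
  hi <- grid[min(length(grid), best + 1)]
  cand_e <- grid[best]
  cand_g <- g[best]
  if (hi > lo) {
    ref <- stats::optimize(f, lower = lo, upper = hi, maximum = TRUE,
                           tol = 1e-6)
    if (ref$objective > cand_g) {
      cand_e <- ref$maximum
      cand_g <- ref$objective
    }
  }
  # flat-maximum tie-break: prefer the endpoint nearer zero when it is
  # indistinguishable in gain
  for (edge in c(rng[2], grid[length(grid)])) {
    ge <- f(edge)
    if (ge >= cand_g - 1e-12 && abs(edge) < abs(cand_e)) {
      cand_e <- edge
      cand_g <- ge
    }
  }
  list(e_star_mm = cand_e, gain = cand_g)
}

#' MEG excursions for every condition
#'
#' @param conditions Condition table from [reach_conditions()].
#' @param model Fitted [sigma_model()].
#' @param endpoint_means Tibble `condition_id`, `mean_endpoint_mm` giving the
#'   planned endpoint per condition (observed average endpoint error).
#' @inheritParams eg_curve
#' @return Tibble `condition_id`, `e_star_mm`, `gain_at_max`.
#' @export
meg_table <- function(conditions, model, endpoint_means,
                      range_mm = c(-40, 0)) {
  df <- dplyr::inner_join(conditions, endpoint_means, by = "condition_id")
  if (nrow(df) != nrow(conditions)) {
    stop("meg_table(): endpoint_means must cover every condition",
         call. = FALSE)
  }
  res <- lapply(seq_len(nrow(df)), function(i) {
    opt <- optimize_excursion(df[i, ], model, df$mean_endpoint_mm[i],
                              range_mm = range_mm)
    tibble::tibble(
      condition_id = df$condition_id[i],
      e_star_mm = opt$e_star_mm,
      gain_at_max = opt$gain
    )
  })
  dplyr::bind_rows(res)
}

#' Pair observed mean excursions with MEG predictions
#'
#' Produces the observed-versus-optimal table behind the unity-line
#' comparison: one row per condition with the across-subject mean observed
#' excursion, its standard error, and the theoretical MEG excursion e*.
#'
#' @param summaries Pooled condition summaries from
#'   [summarize_conditions()].
#' @param meg_results Output of [meg_table()].
#' @return Tibble `condition_id`, `observed_mean_mm`, `observed_se_mm`,
#'   `predicted_e_star_mm`.
#' @export
predicted_vs_observed <- function(summaries, meg_results) {
  if (!setequal(summaries$condition_id, meg_results$condition_id)) {
    stop("predicted_vs_observed(): condition sets differ", call. = FALSE)
  }
  se <- if ("subject_se_excursion_mm" %in% names(summaries) &&
            all(is.finite(summaries$subject_se_excursion_mm))) {
    summaries$subject_se_excursion_mm
  } else {
    summaries$se_excursion_mm
  }
  dplyr::inner_join(
    tibble::tibble(
      condition_id = summaries$condition_id,
      observed_mean_mm = summaries$mean_excursion_mm,
      observed_se_mm = se
    ),
    meg_results[, c("condition_id", "e_star_mm")],
    by = "condition_id"
  ) |>
    dplyr::rename(predicted_e_star_mm = "e_star_mm")
}
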