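#' Cross-condition expected-gain matrix
#'
#' Entry `G[i, j]` is the expected gain obtained in condition i by playing
#' the strategy actually observed in condition j. Strategies transfer as
#' obstacle-relative excursions: applying strategy j in condition i means
#' evaluating condition i's costs and sigma lines at strategy j's observed
#' mean excursion, with condition i's observed mean endpoint as the planned
#' endpoint. Excursions outside condition i's sigma-positive range are left
#' `NA` (not evaluable), never extrapolated to a degenerate distribution.
#'
#' @param summaries Pooled condition summaries from
#'   [summarize_conditions()] (need `mean_excursion_mm`,
#'   `mean_endpoint_mm`).
#' @param model Fitted [sigma_model()].
#' @param conditions Condition table from [reach_conditions()].
#' @param range_mm Admissible excursion interval, default `c(-40, 0)`.
#' @return Square matrix with condition ids as dim names.
#' @export
cross_condition_gain_matrix <- function(summaries, model, conditions,
                                        range_mm = c(-40, 0)) {
  df <- dplyr::inner_join(
    conditions,
    summaries[, c("condition_id", "mean_excursion_mm", "mean_endpoint_mm")],
    by = "condition_id"
  )
  if (nrow(df) != nrow(conditions)) {
    stop("cross_condition_gain_matrix(): summaries must cover every condition",
         call. = FALSE)
  }
  k <- nrow(df)
  G <- matrix(NA_real_, k, k,
              dimnames = list(df$condition_id, df$condition_id))
  for (i in seq_len(k)) {
    rng <- sigma_positive_range(model, df$obstacle_location_index[i],
                                range_mm = range_mm)
    ok <- df$mean_excursion_mm >= rng[1] & df$mean_excursion_mm <= rng[2]
    if (any(ok)) {
      G[i, ok] <- eg_components(
        df[i, ], model, df$mean_endpoint_mm[i],
        df$mean_excursion_mm[ok]
      )$gain
    }
  }
  G
}

#' The Dominance Test
#'
#' A condition's observed strategy is dominated when some other condition's
#' observed strategy would have earned more expected gain in that condition
#' — direct evidence that the subject failed to maximize expected gain
#' there, using only strategies the subject demonstrably can produce.
#'
#' @param gain_matrix Matrix from [cross_condition_gain_matrix()]; `NA`
#'   entries are excluded from the row maxima.
#' @param epsilon Margin (points) a competitor must exceed the own-strategy
#'   gain by to count, default `1e-6`.
#' @return Tibble `condition_id`, `own_gain`, `best_gain`,
#'   `best_strategy_from`, `margin_points`, `dominated`.
#' @export
dominance_test <- function(gain_matrix, epsilon = 1e-6) {
  stopifnot(is.matrix(gain_matrix),
            nrow(gain_matrix) == ncol(gain_matrix),
            epsilon >= 0)
  ids <- rownames(gain_matrix)
  res <- lapply(seq_len(nrow(gain_matrix)), function(i) {
    row <- unname(gain_matrix[i, ])
    own <- row[i]
    if (is.na(own)) {
      stop(sprintf("dominance_test(): own-strategy gain not evaluable for %s",
                   ids[i]), call. = FALSE)
    }
    others <- row[-i]
    others <- others[!is.na(others)]
    best <- if (length(others)) max(others) else -Inf
    tibble::tibble(
      condition_id = ids[i],
      own_gain = unname(own),
      best_gain = max(best, own),
      best_strategy_from = if (best > own) {
        ids[which(!is.na(row) & row == best & seq_along(row) != i)[1]]
      } else {
        ids[i]
      },
      margin_points = max(0, best - own),
      dominated = (best - own) > epsilon
    )
  })
  dplyr::bind_rows(res)
}

#' Realized points of each trial
#'
#' Reward and cost actually earned on each reach, from its outcome label and
#' the condition's point values.
#'
#' @param trials Trial table with `condition_id` and `outcome`.
#' @param conditions Condition table.
#' @return Numeric vector of points per trial.
#' @export
trial_points <- function(trials, conditions) {
  j <- match(trials$condition_id, conditions$condition_id)
  if (anyNA(j)) stop("trial_points(): unknown condition id", call. = FALSE)
  hit_t <- trials$outcome %in% c("hit_both", "hit_target_only")
  hit_o <- trials$outcome %in% c("hit_both", "hit_obstacle_only")
  hit_t * conditions$target_reward_points[j] +
    hit_o * conditions$obstacle_cost_points[j]
}

#' Gain resolution of an experiment
#'
#' The largest per-condition standard error of mean realized gain. Expected
#' gain differences below this are not measurable at the experiment's scale;
#' the pipeline uses it as the default margin for headline dominance flags.
#'
#' @inheritParams trial_points
#' @return Points (scalar).
#' @export
gain_resolution <- function(trials, conditions) {
  pts <- trial_points(trials, conditions)
  se <- tapply(pts, trials$condition_id,
               function(x) stats::sd(x) / sqrt(length(x)))
  max(se)
}

#' Bootstrap stability of dominance flags
#'
#' Resamples trials with replacement within each subject x condition cell,
#' recomputes summaries, the sigma fit, the gain matrix and the dominance
#' flags, and reports how often each condition is flagged. Auxiliary
#' uncertainty output; headline flags use the point estimates.
#'
#' @param trials Trial table.
#' @param conditions Condition table.
#' @param n_boot Number of resamples, default 200.
#' @param epsilon Dominance margin, default `1e-6`.
#' @param seed RNG seed.
#' @return Tibble `condition_id`, `flag_rate`.
#' @export
dominance_bootstrap <- function(trials, conditions, n_boot = 200,
                                epsilon = 1e-6, seed = 1L) {
  set.seed(seed)
  ids <- sort(unique(trials$condition_id))
  counts <- stats::setNames(numeric(length(ids)), ids)
  grp <- split(
    seq_len(nrow(trials)),
    paste(trials$subject_id, trials$condition_id)
  )
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(grp, function(g) g[sample.int(length(g),
                                                       replace = TRUE)]),
                  use.names = FALSE)
    boot <- trials[idx, ]
    summ <- summarize_conditions(boot, pooling = "pooled")
    fit <- fit_sigma_lines(summ, conditions)
    G <- cross_condition_gain_matrix(summ, fit, conditions)
    flags <- dominance_test(G, epsilon = epsilon)
    counts[flags$condition_id] <- counts[flags$condition_id] +
      as.numeric(flags$dominated)
  }
  tibble::tibble(condition_id = ids,
                 flag_rate = unname(counts[ids]) / n_boot)
}
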