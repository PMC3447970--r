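#' Ground-truth sigma lines used by the default generator
#'
#' Fixture noise model for synthetic experiments. Obstacle-plane noise
#' starts at 3.0/3.8/4.6 mm for the three obstacle locations (noise grows
#' with target eccentricity) and roughly doubles over a 20 mm leftward
#' excursion (slopes -0.15/-0.19/-0.23, steeper for farther obstacles);
#' target-plane lines are slightly wider with shallower growth. Under the
#' optimal policy these lines put MEG excursions between roughly -5 and
#' -19 mm — the scale of speeded-reach excursions this task elicits — and
#' keep the six slopes well identified from the nine-condition design
#' (|slope| about 4-5 times its sampling error). They are generator choices
#' with the qualitative shape the task shows (noise grows with excursion
#' magnitude and with obstacle distance from screen centre), not measured
#' values.
#'
#' @return A [sigma_model()].
#' @export
default_sigma_truth <- function() {
  sigma_model(
    tibble::tibble(
      obstacle_location_index = rep(1:3, each = 2),
      plane = rep(c("obstacle", "target"), 3),
      intercept_mm = c(3.0, 3.2, 3.8, 4.0, 4.6, 4.8),
      slope = c(-0.15, -0.12, -0.19, -0.15, -0.23, -0.18)
    ),
    weighting = "ground truth (generator fixture)"
  )
}

#' Configuration for a synthetic reaching experiment
#'
#' Defaults reproduce the study design: 7 subjects, 9 conditions (3 target
#' positions x 3 obstacle costs), 4 blocks of 30 reaches per condition (1080
#' reaches per subject). The behavioural policy sets each condition's planned
#' excursion: `"optimal"` plays the MEG excursion e* under the ground-truth
#' sigma lines, `"scaled"` plays `kappa * e*` (e.g. an agent stopping 80% of
#' the way to the optimum), `"fixed"` plays user-supplied excursions.
#'
#' @param n_subjects Number of subjects, default 7.
#' @param blocks_per_condition Blocks per condition, default 4.
#' @param trials_per_block Reaches per block, default 30.
#' @param policy `"optimal"`, `"scaled"` or `"fixed"`.
#' @param kappa Scaling in (0, 1] for `policy = "scaled"`, default 0.8.
#' @param fixed_excursions_mm Named numeric (by `condition_id`) for
#'   `policy = "fixed"`.
#' @param sigma_truth Ground-truth [sigma_model()]; default
#'   [default_sigma_truth()].
#' @param endpoint_bias_mm Planned endpoint error per target position
#'   (length 3), default `c(0.5, -0.5, -1.5)` mm — small biases varying with
#'   target position but not excursion.
#' @param correlation Cross-plane correlation rho of executed crossings,
#'   default 0.
#' @param between_subject_sd_mm SD of Gaussian jitter applied to each
#'   subject's policy excursions (0 = homogeneous subjects, default).
#' @param ar1_coef Optional within-block AR(1) coefficient on the noise
#'   (default 0, trial-to-trial independence); exists to exercise the
#'   autocorrelation diagnostic.
#' @param conditions Condition table, default [reach_conditions()].
#' @param seed Integer RNG seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 7,
                             blocks_per_condition = 4,
                             trials_per_block = 30,
                             policy = c("optimal", "scaled", "fixed"),
                             kappa = 0.8,
                             fixed_excursions_mm = NULL,
                             sigma_truth = default_sigma_truth(),
                             endpoint_bias_mm = c(0.5, -0.5, -1.5),
                             correlation = 0,
                             between_subject_sd_mm = 0,
                             ar1_coef = 0,
                             conditions = reach_conditions(),
                             seed = 1L) {
  policy <- match.arg(policy)
  stopifnot(
    n_subjects >= 1, blocks_per_condition >= 1, trials_per_block >= 2,
    is.finite(kappa), kappa > 0, kappa <= 1,
    inherits(sigma_truth, "sigma_model"),
    length(endpoint_bias_mm) ==
      length(unique(conditions$obstacle_location_index)),
    abs(correlation) < 1,
    between_subject_sd_mm >= 0,
    abs(ar1_coef) < 1
  )
  if (policy == "fixed") {
    if (is.null(fixed_excursions_mm) ||
        !all(conditions$condition_id %in% names(fixed_excursions_mm))) {
      stop("generator_config(): policy 'fixed' needs named excursions for ",
           "every condition", call. = FALSE)
    }
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      blocks_per_condition = as.integer(blocks_per_condition),
      trials_per_block = as.integer(trials_per_block),
      policy = policy,
      kappa = kappa,
      fixed_excursions_mm = fixed_excursions_mm,
      sigma_truth = sigma_truth,
      endpoint_bias_mm = endpoint_bias_mm,
      correlation = correlation,
      between_subject_sd_mm = between_subject_sd_mm,
      ar1_coef = ar1_coef,
      conditions = tibble::as_tibble(conditions),
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' Build the blocked trial schedule
#'
#' Each subject runs every condition in `blocks_per_condition` blocks of
#' `trials_per_block` reaches; block order is an independent random
#' permutation per subject (seeded from `config$seed`).
#'
#' @param config A [generator_config()].
#' @return List with `conditions` (tibble) and `schedule` (tibble
#'   `subject_id`, `block_index`, `condition_id`).
#' @export
build_design <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  ids <- config$conditions$condition_id
  schedule <- dplyr::bind_rows(lapply(seq_len(config$n_subjects), function(s) {
    blocks <- sample(rep(ids, config$blocks_per_condition))
    tibble::tibble(
      subject_id = sprintf("S%02d", s),
      block_index = seq_along(blocks),
      condition_id = blocks
    )
  }))
  list(conditions = config$conditions, schedule = schedule)
}

#' Per-condition planned strategies under a behavioural policy
#'
#' @param config A [generator_config()].
#' @param model Sigma model used to locate optima; defaults to the config's
#'   ground truth.
#' @param conditions Condition table; defaults to the config's.
#' @return Tibble `condition_id`, `planned_excursion_mm`,
#'   `planned_endpoint_mm`.
#' @export
policy_excursions <- function(config, model = config$sigma_truth,
                              conditions = config$conditions) {
  stopifnot(inherits(config, "generator_config"))
  endpoint <- config$endpoint_bias_mm[conditions$obstacle_location_index]
  if (config$policy == "fixed") {
    exc <- unname(config$fixed_excursions_mm[conditions$condition_id])
  } else {
    if (!inherits(model, "sigma_model")) {
      stop("policy_excursions(): optimal/scaled policies need a sigma model",
           call. = FALSE)
    }
    meg <- meg_table(
      conditions, model,
      tibble::tibble(condition_id = conditions$condition_id,
                     mean_endpoint_mm = endpoint)
    )
    exc <- meg$e_star_mm[match(conditions$condition_id, meg$condition_id)]
    if (config$policy == "scaled") exc <- config$kappa * exc
  }
  tibble::tibble(
    condition_id = conditions$condition_id,
    planned_excursion_mm = exc,
    planned_endpoint_mm = endpoint
  )
}

#' Simulate a complete reaching experiment
#'
#' Draws every scheduled reach from the bivariate Gaussian implied by the
#' policy's planned strategy for its condition, with standard deviations
#' from the ground-truth sigma lines evaluated at the planned excursion, and
#' labels outcomes via [classify_outcome()]. Fully reproducible from
#' `config$seed`.
#'
#' @param config A [generator_config()].
#' @return Trial tibble: `subject_id`, `condition_id`, `block_index`,
#'   `trial_in_block`, `excursion_mm`, `endpoint_mm`, `outcome`.
#' @export
#' @examples
#' trials <- simulate_experiment(generator_config(n_subjects = 1, seed = 42))
#' nrow(trials) # 1080
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  design <- build_design(config) # seeds the RNG stream
  plan <- policy_excursions(config)
  conditions <- config$conditions

  schedule <- design$schedule |>
    dplyr::inner_join(plan, by = "condition_id") |>
    dplyr::inner_join(
      conditions[, c("condition_id", "obstacle_location_index",
                     "target_width_mm")],
      by = "condition_id"
    )

  if (config$between_subject_sd_mm > 0) {
    subj <- unique(schedule$subject_id)
    jit <- stats::rnorm(length(subj), 0, config$between_subject_sd_mm)
    names(jit) <- subj
    schedule$planned_excursion_mm <- pmin(
      0, schedule$planned_excursion_mm + jit[schedule$subject_id]
    )
  }

  sigma_for <- function(plane) {
    out <- numeric(nrow(schedule))
    for (loc in unique(schedule$obstacle_location_index)) {
      idx <- schedule$obstacle_location_index == loc
      out[idx] <- predict_sigma(config$sigma_truth, loc, plane,
                                schedule$planned_excursion_mm[idx])
    }
    if (any(out <= 0)) {
      stop("simulate_experiment(): non-positive sigma for condition ",
           schedule$condition_id[which(out <= 0)[1]], call. = FALSE)
    }
    out
  }
  s1 <- sigma_for("obstacle")
  s2 <- sigma_for("target")

  m <- config$trials_per_block
  n_blocks <- nrow(schedule)
  draw_block_noise <- function() {
    z <- matrix(stats::rnorm(n_blocks * m), nrow = n_blocks)
    phi <- config$ar1_coef
    if (phi != 0) {
      # stationary AR(1) on standardized noise, per block
      for (t in 2:m) {
        z[, t] <- phi * z[, t - 1] + sqrt(1 - phi^2) * z[, t]
      }
    }
    z
  }
  z1 <- draw_block_noise()
  z2 <- draw_block_noise()
  rho <- config$correlation
  e1 <- schedule$planned_excursion_mm + s1 * z1
  e2 <- schedule$planned_endpoint_mm +
    s2 * (rho * z1 + sqrt(1 - rho^2) * z2)

  trials <- tibble::tibble(
    subject_id = rep(schedule$subject_id, each = m),
    condition_id = rep(schedule$condition_id, each = m),
    block_index = rep(schedule$block_index, each = m),
    trial_in_block = rep(seq_len(m), times = n_blocks),
    excursion_mm = as.vector(t(e1)),
    endpoint_mm = as.vector(t(e2)),
    target_width_mm = rep(schedule$target_width_mm, each = m)
  )
  trials$outcome <- NA_character_
  for (w in unique(trials$target_width_mm)) {
    idx <- trials$target_width_mm == w
    trials$outcome[idx] <- classify_outcome(
      trials$excursion_mm[idx], trials$endpoint_mm[idx],
      list(target_width_mm = w)
    )
  }
  trials$target_width_mm <- NULL
  dplyr::arrange(trials, .data$subject_id, .data$block_index,
                 .data$trial_in_block)
}
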