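# Shared fixtures built in code.

# Flat-noise sigma model: sigma constant in excursion, handy for
# hand-computable expected gains.
flat_sigma <- function(sd_mm = 2, locations = 1:3) {
  sigma_model(tibble::tibble(
    obstacle_location_index = rep(locations, each = 2),
    plane = rep(c("obstacle", "target"), length(locations)),
    intercept_mm = sd_mm,
    slope = 0
  ))
}

# Small toy model with excursion-dependent noise for optimizer tests.
toy_sigma <- function() {
  sigma_model(tibble::tibble(
    obstacle_location_index = rep(1:3, each = 2),
    plane = rep(c("obstacle", "target"), 3),
    intercept_mm = 2,
    slope = -0.1
  ))
}

# Condition summaries built directly from known values (bypassing trials),
# for exact-fit tests.
manual_summaries <- function(mean_exc, sd_obs, sd_tar, se = 0.05,
                             conditions = reach_conditions()) {
  tibble::tibble(
    condition_id = conditions$condition_id,
    n_trials = 1000L,
    mean_excursion_mm = mean_exc,
    mean_endpoint_mm = 0,
    sd_excursion_mm = sd_obs,
    sd_endpoint_mm = sd_tar,
    se_excursion_mm = se,
    se_endpoint_mm = se,
    se_sd_excursion_mm = se,
    se_sd_endpoint_mm = se,
    subject_se_excursion_mm = se,
    subject_se_endpoint_mm = se,
    correlation_hat = 0
  )
}

small_config <- function(...) {
  generator_config(n_subjects = 2, blocks_per_condition = 2, ...)
}
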