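#' Condition-level crossing summaries
#'
#' Summarises per-trial crossing coordinates into the per-condition
#' statistics behind the value diagrams: mean excursion and endpoint, their
#' standard deviations and standard errors, and the cross-plane correlation.
#'
#' Two pooling modes:
#' \describe{
#'   \item{`pooled`}{Each subject's trials are centred on that subject's own
#'     condition mean before second moments are pooled across subjects
#'     (mirroring value diagrams plotted centred on the pooled mean). The
#'     condition mean is the average of subject means. Trial-based SEs
#'     (`se_*_mm = sd/sqrt(n)`) and across-subject SEs of the mean
#'     (`subject_se_*_mm`) are both emitted, as are standard errors of the SD
#'     estimates (`se_sd_*_mm = sd/sqrt(2(n-1))`) used as weights in
#'     [fit_sigma_lines()].}
#'   \item{`per_subject`}{Within-subject statistics are computed first and
#'     then averaged across subjects; SEs are across-subject. The
#'     subject-level table is attached as attribute `"by_subject"`.}
#' }
#' Sample SDs use the n-1 denominator throughout.
#'
#' @param trials Trial table with columns `subject_id`, `condition_id`,
#'   `excursion_mm`, `endpoint_mm`.
#' @param pooling `"pooled"` (default) or `"per_subject"`.
#' @return A tibble, one row per condition (or per subject x condition).
#' @export
summarize_conditions <- function(trials,
                                 pooling = c("pooled", "per_subject")) {
  pooling <- match.arg(pooling)
  needed <- c("subject_id", "condition_id", "excursion_mm", "endpoint_mm")
  if (!all(needed %in% names(trials))) {
    stop("summarize_conditions(): trials must have columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  counts <- dplyr::count(trials, .data$condition_id)
  if (any(counts$n < 2)) {
    bad <- counts$condition_id[counts$n < 2][1]
    stop(sprintf(
      "summarize_conditions(): condition '%s' has fewer than 2 trials", bad),
      call. = FALSE)
  }

  per_subj <- trials |>
    dplyr::group_by(.data$condition_id, .data$subject_id) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      mean_excursion_mm = mean(.data$excursion_mm),
      mean_endpoint_mm = mean(.data$endpoint_mm),
      sd_excursion_mm = stats::sd(.data$excursion_mm),
      sd_endpoint_mm = stats::sd(.data$endpoint_mm),
      correlation_hat = suppressWarnings(
        stats::cor(.data$excursion_mm, .data$endpoint_mm)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      se_excursion_mm = .data$sd_excursion_mm / sqrt(.data$n_trials),
      se_endpoint_mm = .data$sd_endpoint_mm / sqrt(.data$n_trials),
      se_sd_excursion_mm = .data$sd_excursion_mm /
        sqrt(2 * (.data$n_trials - 1)),
      se_sd_endpoint_mm = .data$sd_endpoint_mm /
        sqrt(2 * (.data$n_trials - 1))
    )

  if (pooling == "per_subject") {
    out <- per_subj |>
      dplyr::group_by(.data$condition_id) |>
      dplyr::summarise(
        n_subjects = dplyr::n(),
        n_trials = sum(.data$n_trials),
        se_excursion_mm = stats::sd(.data$mean_excursion_mm) /
          sqrt(dplyr::n()),
        se_endpoint_mm = stats::sd(.data$mean_endpoint_mm) /
          sqrt(dplyr::n()),
        se_sd_excursion_mm = stats::sd(.data$sd_excursion_mm) /
          sqrt(dplyr::n()),
        se_sd_endpoint_mm = stats::sd(.data$sd_endpoint_mm) /
          sqrt(dplyr::n()),
        mean_excursion_mm = mean(.data$mean_excursion_mm),
        mean_endpoint_mm = mean(.data$mean_endpoint_mm),
        sd_excursion_mm = mean(.data$sd_excursion_mm),
        sd_endpoint_mm = mean(.data$sd_endpoint_mm),
        correlation_hat = mean(.data$correlation_hat),
        pooled_over = paste(sort(unique(.data$subject_id)), collapse = ","),
        .groups = "drop"
      ) |>
      dplyr::arrange(.data$condition_id)
    attr(out, "by_subject") <-
      dplyr::arrange(per_subj, .data$condition_id, .data$subject_id)
    return(out)
  }

  centred <- trials |>
    dplyr::group_by(.data$condition_id, .data$subject_id) |>
    dplyr::mutate(
      c_exc = .data$excursion_mm - mean(.data$excursion_mm),
      c_end = .data$endpoint_mm - mean(.data$endpoint_mm)
    ) |>
    dplyr::ungroup()

  pooled_second <- centred |>
    dplyr::group_by(.data$condition_id) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      sd_excursion_mm = sqrt(sum(.data$c_exc^2) / (dplyr::n() - 1)),
      sd_endpoint_mm = sqrt(sum(.data$c_end^2) / (dplyr::n() - 1)),
      correlation_hat = suppressWarnings(
        stats::cor(.data$c_exc, .data$c_end)),
      .groups = "drop"
    )

  first_moments <- per_subj |>
    dplyr::group_by(.data$condition_id) |>
    dplyr::summarise(
      n_subjects = dplyr::n(),
      mean_excursion_mm = mean(.data$mean_excursion_mm),
      mean_endpoint_mm = mean(.data$mean_endpoint_mm),
      subject_se_excursion_mm = stats::sd(.data$mean_excursion_mm) /
        sqrt(dplyr::n()),
      subject_se_endpoint_mm = stats::sd(.data$mean_endpoint_mm) /
        sqrt(dplyr::n()),
      pooled_over = paste(sort(unique(.data$subject_id)), collapse = ","),
      .groups = "drop"
    )

  dplyr::inner_join(first_moments, pooled_second, by = "condition_id") |>
    dplyr::mutate(
      se_excursion_mm = .data$sd_excursion_mm / sqrt(.data$n_trials),
      se_endpoint_mm = .data$sd_endpoint_mm / sqrt(.data$n_trials),
      se_sd_excursion_mm = .data$sd_excursion_mm /
        sqrt(2 * (.data$n_trials - 1)),
      se_sd_endpoint_mm = .data$sd_endpoint_mm /
        sqrt(2 * (.data$n_trials - 1))
    ) |>
    dplyr::arrange(.data$condition_id)
}
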