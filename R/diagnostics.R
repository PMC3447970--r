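#' Decibel / odds conversions for model evidence
#'
#' Evidence for one model over another is expressed in decibels:
#' `10 * log10(odds)`. 3 dB is roughly 2:1 odds; 3–4.75 dB (2:1 to 3:1) is a
#' conventional floor for statistically meaningful evidence.
#'
#' @param odds Posterior odds, > 0.
#' @param db Evidence in decibels.
#' @return `db_from_odds()` returns decibels; `odds_from_db()` returns odds.
#'   They are exact inverses.
#' @export
#' @examples
#' db_from_odds(2)     # 3.0103
#' odds_from_db(12.99) # about 20:1
db_from_odds <- function(odds) {
  if (any(!is.finite(odds)) || any(odds <= 0)) {
    stop("db_from_odds(): odds must be positive and finite", call. = FALSE)
  }
  10 * log10(odds)
}

#' @rdname db_from_odds
#' @export
odds_from_db <- function(db) {
  if (any(!is.finite(db))) {
    stop("odds_from_db(): db must be finite", call. = FALSE)
  }
  10^(db / 10)
}

#' Bayesian evidence for the unity line
#'
#' Compares two accounts of the observed-vs-optimal excursion pairs: M0, the
#' optimal-planning model, under which observed mean excursions scatter
#' around the identity line (slope 1, intercept 0) with their per-condition
#' standard errors; and M1, a free line with slope and intercept drawn from
#' uniform priors. M0 has no free parameters; M1's marginal likelihood
#' integrates the Gaussian likelihood over the prior box on a trapezoid
#' grid. Evidence is reported in decibels for M0 (positive favours optimal
#' planning). The exact prior box is configurable and deliberately
#' weakly-informative, centred on the unity line.
#'
#' @param predicted_mm MEG excursions e* (x-axis), length >= 3.
#' @param observed_mm Observed mean excursions.
#' @param se_mm Per-point standard errors, > 0.
#' @param slope_range Uniform prior support for M1's slope, default
#'   `c(0, 2)`.
#' @param intercept_range Uniform prior support for M1's intercept (mm),
#'   default `c(-20, 20)`.
#' @param n_grid Grid points per dimension for the marginalization,
#'   default 401.
#' @return List of class `evidence_result`: `evidence_db`, `odds`,
#'   `log_lik_m0`, `log_marg_m1`, `prior_spec`.
#' @export
unity_line_evidence <- function(predicted_mm, observed_mm, se_mm,
                                slope_range = c(0, 2),
                                intercept_range = c(-20, 20),
                                n_grid = 401) {
  n <- length(predicted_mm)
  if (n < 3 || length(observed_mm) != n || length(se_mm) != n) {
    stop("unity_line_evidence(): need >= 3 aligned (predicted, observed, se)",
         call. = FALSE)
  }
  if (any(!is.finite(c(predicted_mm, observed_mm, se_mm))) ||
      any(se_mm <= 0)) {
    stop("unity_line_evidence(): inputs must be finite with positive SEs",
         call. = FALSE)
  }
  x <- predicted_mm
  y <- observed_mm
  w <- 1 / se_mm^2
  base <- -sum(log(se_mm)) - n / 2 * log(2 * pi)
  # weighted residual sum of squares as a quadratic form in (slope a, int b)
  chisq <- function(a, b) {
    sum(w * x^2) * a^2 + sum(w) * b^2 + 2 * sum(w * x) * a * b -
      2 * sum(w * x * y) * a - 2 * sum(w * y) * b + sum(w * y^2)
  }
  log_lik_m0 <- base - chisq(1, 0) / 2

  da <- diff(slope_range)
  db_ <- diff(intercept_range)
  if (da == 0 && db_ == 0) {
    log_marg_m1 <- base - chisq(slope_range[1], intercept_range[1]) / 2
  } else if (da == 0 || db_ == 0) {
    fixed_a <- da == 0
    grid <- if (fixed_a) {
      seq(intercept_range[1], intercept_range[2], length.out = n_grid)
    } else {
      seq(slope_range[1], slope_range[2], length.out = n_grid)
    }
    ll <- vapply(grid, function(g) {
      if (fixed_a) base - chisq(slope_range[1], g) / 2
      else base - chisq(g, intercept_range[1]) / 2
    }, numeric(1))
    lw <- log(trapezoid_weights(grid))
    log_marg_m1 <- logsumexp(ll + lw) - log(max(da, db_))
  } else {
    a_grid <- seq(slope_range[1], slope_range[2], length.out = n_grid)
    b_grid <- seq(intercept_range[1], intercept_range[2],
                  length.out = n_grid)
    A <- sum(w * x^2)
    B <- sum(w)
    C <- sum(w * x)
    D <- sum(w * x * y)
    E <- sum(w * y)
    F_ <- sum(w * y^2)
    S <- outer(a_grid, b_grid, function(a, b) {
      A * a^2 + B * b^2 + 2 * C * a * b - 2 * D * a - 2 * E * b + F_
    })
    ll <- base - S / 2
    lw <- log(outer(trapezoid_weights(a_grid), trapezoid_weights(b_grid)))
    log_marg_m1 <- logsumexp(ll + lw) - log(da * db_)
  }

  log_odds <- log_lik_m0 - log_marg_m1
  structure(
    list(
      evidence_db = 10 * log_odds / log(10),
      odds = exp(log_odds),
      log_lik_m0 = log_lik_m0,
      log_marg_m1 = log_marg_m1,
      prior_spec = list(slope_range = slope_range,
                        intercept_range = intercept_range,
                        type = "uniform")
    ),
    class = "evidence_result"
  )
}

#' @export
print.evidence_result <- function(x, ...) {
  cat(sprintf(
    "<evidence_result> %.2f dB for the unity-line model (odds %.3g:1)\n",
    x$evidence_db, x$odds
  ))
  invisible(x)
}

trapezoid_weights <- function(grid) {
  n <- length(grid)
  h <- diff(grid)
  w <- numeric(n)
  w[1] <- h[1] / 2
  w[n] <- h[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (h[-1] + h[-(n - 1)]) / 2
  w
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Within-block excursion profile
#'
#' Tests for within-block drift ("homing in"): removes each block's mean
#' excursion, averages the centred values at each within-block trial
#' position, and fits a line to the profile. A stationary strategy gives a
#' flat profile.
#'
#' @param trials Trial table with `subject_id`, `block_index`,
#'   `trial_in_block`, `excursion_mm`.
#' @return List: `profile` (tibble `trial_in_block`,
#'   `mean_centered_excursion_mm`, `n`), `slope_mm_per_trial`, `slope_se`.
#' @export
block_position_profile <- function(trials) {
  needed <- c("subject_id", "block_index", "trial_in_block", "excursion_mm")
  if (!all(needed %in% names(trials))) {
    stop("block_position_profile(): trials must have columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  positions <- sort(unique(trials$trial_in_block))
  if (length(positions) != max(positions) ||
      !all(positions == seq_len(max(positions)))) {
    stop("block_position_profile(): missing within-block positions",
         call. = FALSE)
  }
  centred <- trials |>
    dplyr::group_by(.data$subject_id, .data$block_index) |>
    dplyr::mutate(c_exc = .data$excursion_mm - mean(.data$excursion_mm)) |>
    dplyr::ungroup()
  profile <- centred |>
    dplyr::group_by(.data$trial_in_block) |>
    dplyr::summarise(
      mean_centered_excursion_mm = mean(.data$c_exc),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$trial_in_block)
  fit <- stats::lm(mean_centered_excursion_mm ~ trial_in_block,
                   data = profile)
  list(
    profile = profile,
    slope_mm_per_trial = unname(stats::coef(fit)[2]),
    slope_se = summary(fit)$coefficients[2, 2]
  )
}

#' Sample autocorrelation with white-noise bounds
#'
#' Sample autocorrelations up to `max_lag` with the biased (1/n)
#' normalization, plus the usual +/- 1.96/sqrt(n) white-noise band.
#'
#' @param series Numeric vector, length > `max_lag + 1`, non-constant.
#' @param max_lag Default 15.
#' @return Tibble `lag` (0..max_lag), `acf`, `lower`, `upper`.
#' @export
trial_autocorrelation <- function(series, max_lag = 15) {
  n <- length(series)
  if (n <= max_lag + 1) {
    stop("trial_autocorrelation(): series too short for max_lag",
         call. = FALSE)
  }
  if (stats::sd(series) == 0) {
    stop("trial_autocorrelation(): constant series has undefined autocorrelation",
         call. = FALSE)
  }
  ac <- stats::acf(series, lag.max = max_lag, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  bound <- 1.96 / sqrt(n)
  tibble::tibble(
    lag = 0:max_lag,
    acf = ac,
    lower = -bound,
    upper = bound
  )
}

#' Normal quantile-quantile diagnostic
#'
#' Standardizes the sample, sorts it, and pairs it with standard-normal
#' quantiles at plotting positions `(i - 0.5)/n` (or `i/(n + 1)`). The
#' Pearson correlation of the pairs is a linearity coefficient: Gaussian
#' data give values near 1.
#'
#' @param values Numeric sample, n >= 10, non-degenerate.
#' @param positions `"midpoint"` for `(i - 0.5)/n` (default) or `"rankit"`
#'   for `i/(n + 1)`.
#' @return List: `table` (tibble `theoretical`, `empirical`) and
#'   `linearity` (correlation).
#' @export
qq_gaussian <- function(values, positions = c("midpoint", "rankit")) {
  positions <- match.arg(positions)
  n <- length(values)
  if (n < 10) stop("qq_gaussian(): need at least 10 values", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("qq_gaussian(): zero-variance sample", call. = FALSE)
  }
  emp <- sort((values - mean(values)) / s)
  p <- if (positions == "midpoint") (seq_len(n) - 0.5) / n
       else seq_len(n) / (n + 1)
  theo <- stats::qnorm(p)
  list(
    table = tibble::tibble(theoretical = theo, empirical = emp),
    linearity = stats::cor(theo, emp)
  )
}
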