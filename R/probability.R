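#' Bivariate crossing distribution of a motor strategy
#'
#' Executing a planned trajectory induces a bivariate Gaussian distribution
#' over the fingertip's horizontal crossing coordinates at the obstacle plane
#' (x1, obstacle-relative) and the target plane (x2, target-relative). The
#' planned coordinates are the mean; motor noise sets the standard deviations
#' and a (typically small, default-ignored) cross-plane correlation.
#'
#' @param mean_excursion_mm Planned obstacle-plane crossing mu1, mm.
#' @param mean_endpoint_mm Planned target-plane endpoint mu2, mm.
#' @param sd_excursion_mm sigma1 > 0, mm.
#' @param sd_endpoint_mm sigma2 > 0, mm.
#' @param correlation rho, |rho| < 1. Default 0.
#'
#' @return An object of class `crossing_distribution`.
#' @export
#' @examples
#' crossing_distribution(-8, 0, 2, 2)
crossing_distribution <- function(mean_excursion_mm, mean_endpoint_mm,
                                  sd_excursion_mm, sd_endpoint_mm,
                                  correlation = 0) {
  vals <- c(mean_excursion_mm, mean_endpoint_mm, sd_excursion_mm,
            sd_endpoint_mm, correlation)
  if (length(vals) != 5 || !all(is.finite(vals))) {
    stop("crossing_distribution(): all five parameters must be finite scalars",
         call. = FALSE)
  }
  if (sd_excursion_mm <= 0 || sd_endpoint_mm <= 0) {
    stop("crossing_distribution(): standard deviations must be positive",
         call. = FALSE)
  }
  if (abs(correlation) >= 1) {
    stop("crossing_distribution(): |correlation| must be < 1", call. = FALSE)
  }
  structure(
    list(
      mean_mm = c(excursion = mean_excursion_mm, endpoint = mean_endpoint_mm),
      sd_mm = c(excursion = sd_excursion_mm, endpoint = sd_endpoint_mm),
      correlation = correlation
    ),
    class = "crossing_distribution"
  )
}

#' @export
print.crossing_distribution <- function(x, ...) {
  cat(sprintf(
    "<crossing_distribution> mu = (%.3f, %.3f) mm, sigma = (%.3f, %.3f) mm, rho = %.3f\n",
    x$mean_mm[1], x$mean_mm[2], x$sd_mm[1], x$sd_mm[2], x$correlation
  ))
  invisible(x)
}

check_distribution <- function(d) {
  if (!inherits(d, "crossing_distribution")) {
    stop("expected a crossing_distribution object", call. = FALSE)
  }
  invisible(d)
}

#' Probability of hitting the obstacle
#'
#' Marginal Gaussian mass on x1 > 0 (right of the obstacle edge):
#' `pnorm(mu1 / sigma1)`.
#'
#' @param d A [crossing_distribution()].
#' @return Probability in \[0, 1\].
#' @export
prob_hit_obstacle <- function(d) {
  check_distribution(d)
  stats::pnorm(d$mean_mm[["excursion"]] / d$sd_mm[["excursion"]])
}

#' Probability of hitting the target
#'
#' Marginal Gaussian mass of x2 inside the target strip of width
#' `target_width_mm` centred on 0.
#'
#' @inheritParams prob_hit_obstacle
#' @param condition A one-row condition or list with `target_width_mm`.
#' @return Probability in \[0, 1\].
#' @export
prob_hit_target <- function(d, condition) {
  check_distribution(d)
  half <- condition$target_width_mm / 2
  stopifnot(length(half) == 1, is.finite(half), half > 0)
  mu <- d$mean_mm[["endpoint"]]
  sd <- d$sd_mm[["endpoint"]]
  stats::pnorm((half - mu) / sd) - stats::pnorm((-half - mu) / sd)
}

# P(X1 > 0, lo < X2 <= hi) for the bivariate Gaussian, by adaptive 1-D
# quadrature over the conditional normal of X2 | X1. Exact product of
# marginals when rho = 0.
bvn_obstacle_and_band <- function(d, lo, hi) {
  mu1 <- d$mean_mm[["excursion"]]
  mu2 <- d$mean_mm[["endpoint"]]
  s1 <- d$sd_mm[["excursion"]]
  s2 <- d$sd_mm[["endpoint"]]
  rho <- d$correlation
  if (rho == 0) {
    return(stats::pnorm(mu1 / s1) *
             (stats::pnorm((hi - mu2) / s2) - stats::pnorm((lo - mu2) / s2)))
  }
  s2c <- s2 * sqrt(1 - rho^2)
  integrand <- function(z1) {
    # z1 is standardized x1; conditional mean of x2 shifts with rho * z1
    mu2c <- mu2 + rho * s2 * z1
    stats::dnorm(z1) *
      (stats::pnorm((hi - mu2c) / s2c) - stats::pnorm((lo - mu2c) / s2c))
  }
  zlo <- -mu1 / s1 # x1 > 0 in standardized units
  res <- tryCatch(
    stats::integrate(integrand, lower = max(zlo, -9), upper = 9,
                     rel.tol = 1e-10, abs.tol = 1e-12, subdivisions = 400L),
    error = function(e) {
      stop("bivariate integration failed: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (zlo <= -9) {
    # essentially all x1 mass is right of the edge; tail below -9 negligible
  }
  max(0, min(1, res$value))
}

#' Joint probabilities of the four reach outcomes
#'
#' Computes P(hit both), P(hit target only), P(hit obstacle only),
#' P(miss both) under the bivariate Gaussian crossing distribution. With
#' `rho = 0` these are products of the marginal probabilities; otherwise the
#' rectangle masses are obtained by numerical integration.
#'
#' @inheritParams prob_hit_target
#' @return Named numeric vector over the four outcomes, summing to 1 within
#'   1e-9.
#' @export
outcome_probabilities <- function(d, condition) {
  check_distribution(d)
  half <- condition$target_width_mm / 2
  p_obs <- prob_hit_obstacle(d)
  p_tar <- prob_hit_target(d, condition)
  p_both <- bvn_obstacle_and_band(d, -half, half)
  p <- c(
    hit_both = p_both,
    hit_target_only = p_tar - p_both,
    hit_obstacle_only = p_obs - p_both,
    miss_both = 1 - p_tar - p_obs + p_both
  )
  p <- pmin(pmax(p, 0), 1)
  if (abs(sum(p) - 1) > 1e-9) {
    stop(sprintf("outcome probabilities sum to %.12f, not 1", sum(p)),
         call. = FALSE)
  }
  p
}

#' Expected gain of a motor strategy
#'
#' Reward-weighted target-hit probability plus cost-weighted obstacle-hit
#' probability. Because gain is additive over the two indicator events it
#' depends only on the marginals, hence is invariant to the cross-plane
#' correlation.
#'
#' @inheritParams prob_hit_target
#' @return Expected gain in points.
#' @export
#' @examples
#' cond <- reach_conditions()[1, ]
#' expected_gain(crossing_distribution(-6, 0, 2, 2), cond)
expected_gain <- function(d, condition) {
  condition$target_reward_points * prob_hit_target(d, condition) +
    condition$obstacle_cost_points * prob_hit_obstacle(d)
}

#' Sample crossing coordinates
#'
#' Draws reach crossing pairs (x1, x2) from the bivariate Gaussian via its
#' Cholesky factor. Used by the experiment generator and as a Monte-Carlo
#' oracle in tests.
#'
#' @inheritParams prob_hit_obstacle
#' @param n Number of draws.
#' @param seed Optional integer; when given, sampling is reproducible and the
#'   caller's RNG state is untouched.
#' @return A tibble with columns `excursion_mm`, `endpoint_mm`.
#' @export
sample_crossings <- function(d, n, seed = NULL) {
  check_distribution(d)
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
      add = TRUE
    )
    set.seed(seed)
  }
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  rho <- d$correlation
  tibble::tibble(
    excursion_mm = d$mean_mm[["excursion"]] + d$sd_mm[["excursion"]] * z1,
    endpoint_mm = d$mean_mm[["endpoint"]] +
      d$sd_mm[["endpoint"]] * (rho * z1 + sqrt(1 - rho^2) * z2)
  )
}
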