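#' Construct a sigma model from line coefficients
#'
#' A sigma model is the empirical noise model of the task: for each obstacle
#' location and each plane (`"obstacle"`, `"target"`) a straight line
#' predicting the fingertip standard deviation (mm) from the signed mean
#' excursion (mm, negative leftward). Slopes are therefore typically
#' negative: larger leftward excursions produce noisier crossings.
#'
#' @param lines A data frame with columns `obstacle_location_index`, `plane`,
#'   `intercept_mm`, `slope` and optionally `r_squared`.
#' @param weighting Description of the fit weights (free text, recorded).
#' @return An object of class `sigma_model`.
#' @export
#' @examples
#' sigma_model(data.frame(
#'   obstacle_location_index = rep(1:3, each = 2),
#'   plane = rep(c("obstacle", "target"), 3),
#'   intercept_mm = 1.5, slope = -0.08
#' ))
sigma_model <- function(lines, weighting = "manual") {
  lines <- tibble::as_tibble(lines)
  needed <- c("obstacle_location_index", "plane", "intercept_mm", "slope")
  if (!all(needed %in% names(lines))) {
    stop("sigma_model(): lines must have columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (!all(lines$plane %in% c("obstacle", "target"))) {
    stop("sigma_model(): plane must be 'obstacle' or 'target'", call. = FALSE)
  }
  if (anyDuplicated(lines[, c("obstacle_location_index", "plane")])) {
    stop("sigma_model(): one line per location x plane", call. = FALSE)
  }
  if (!"r_squared" %in% names(lines)) lines$r_squared <- NA_real_
  structure(list(lines = lines, weighting = weighting),
            class = "sigma_model")
}

#' @export
print.sigma_model <- function(x, ...) {
  cat("<sigma_model> sd-vs-excursion lines (weighting: ",
      x$weighting, ")\n", sep = "")
  print(x$lines)
  invisible(x)
}

sigma_line <- function(model, obstacle_location_index, plane) {
  stopifnot(inherits(model, "sigma_model"))
  row <- model$lines[
    model$lines$obstacle_location_index == obstacle_location_index &
      model$lines$plane == plane, ]
  if (nrow(row) != 1) {
    stop(sprintf("sigma_model has no line for location %s, plane '%s'",
                 obstacle_location_index, plane), call. = FALSE)
  }
  row
}

#' Fit the six sd-versus-excursion lines
#'
#' For each obstacle location, regresses the per-condition sample standard
#' deviation at each plane on the condition's mean excursion across the three
#' cost levels, by weighted least squares with weights 1/SE^2 of each SD
#' estimate. Locations are fitted separately: noise may grow differently when
#' skirting near and far obstacles, and pooling them would need extra
#' assumptions.
#'
#' @param summaries Condition summaries as from
#'   [summarize_conditions()] (pooled), with columns `mean_excursion_mm`,
#'   `sd_excursion_mm`, `sd_endpoint_mm`, `se_sd_excursion_mm`,
#'   `se_sd_endpoint_mm`.
#' @param conditions Condition table mapping `condition_id` to
#'   `obstacle_location_index`.
#' @return A [sigma_model()] with per-line `r_squared`.
#' @export
fit_sigma_lines <- function(summaries, conditions) {
  df <- dplyr::inner_join(
    summaries,
    conditions[, c("condition_id", "obstacle_location_index")],
    by = "condition_id"
  )
  if (nrow(df) == 0) stop("fit_sigma_lines(): no matching conditions",
                          call. = FALSE)
  planes <- tibble::tibble(
    plane = c("obstacle", "target"),
    sd_col = c("sd_excursion_mm", "sd_endpoint_mm"),
    se_col = c("se_sd_excursion_mm", "se_sd_endpoint_mm")
  )
  fits <- lapply(sort(unique(df$obstacle_location_index)), function(loc) {
    sub <- df[df$obstacle_location_index == loc, ]
    if (nrow(sub) < 2) {
      stop(sprintf("fit_sigma_lines(): need >= 2 summary points for location %d",
                   loc), call. = FALSE)
    }
    lapply(seq_len(nrow(planes)), function(i) {
      y <- sub[[planes$sd_col[i]]]
      se <- sub[[planes$se_col[i]]]
      if (any(!is.finite(se)) || any(se <= 0)) {
        stop("fit_sigma_lines(): SD standard errors must be positive ",
             "(zero-weight point)", call. = FALSE)
      }
      w <- 1 / se^2
      fit <- stats::lm(y ~ x, data = data.frame(x = sub$mean_excursion_mm, y = y),
                       weights = w)
      tibble::tibble(
        obstacle_location_index = loc,
        plane = planes$plane[i],
        intercept_mm = unname(stats::coef(fit)[1]),
        slope = unname(stats::coef(fit)[2]),
        r_squared = summary(fit)$r.squared,
        intercept_se = summary(fit)$coefficients[1, 2],
        slope_se = summary(fit)$coefficients[2, 2],
        df_residual = fit$df.residual
      )
    })
  })
  lines <- dplyr::bind_rows(unlist(fits, recursive = FALSE))
  out <- sigma_model(lines, weighting = "wls, weights 1/SE(sd)^2")
  out$lines <- lines # keep SE columns for coverage checks
  out
}

#' Predict fingertip standard deviation at a planned excursion
#'
#' @param model A [sigma_model()].
#' @param obstacle_location_index Location 1..3.
#' @param plane `"obstacle"` or `"target"`.
#' @param excursion_mm Signed planned excursion, mm (vectorised).
#' @return Predicted sigma, mm. Errors if any prediction is non-positive
#'   (the excursion lies outside the trustworthy range of the line).
#' @export
predict_sigma <- function(model, obstacle_location_index, plane, excursion_mm) {
  row <- sigma_line(model, obstacle_location_index, plane)
  if (!all(is.finite(excursion_mm))) {
    stop("predict_sigma(): excursion must be finite", call. = FALSE)
  }
  sigma <- row$intercept_mm + row$slope * excursion_mm
  if (any(sigma <= 0)) {
    stop(sprintf(
      "predict_sigma(): non-positive sigma at excursion %.2f mm (location %d, %s plane)",
      excursion_mm[which(sigma <= 0)[1]], obstacle_location_index, plane),
      call. = FALSE)
  }
  sigma
}

#' Excursion range over which predicted noise stays positive
#'
#' Intersection of the requested search range with the excursions at which
#' both planes' predicted sigma exceeds `min_sigma_mm`. Used to restrict the
#' expected-gain search so the optimizer never evaluates a degenerate
#' distribution.
#'
#' @inheritParams predict_sigma
#' @param range_mm Candidate excursion interval, default `c(-40, 0)`.
#' @param min_sigma_mm Smallest admissible sigma, default 0.05 mm.
#' @return Length-2 numeric `c(lower, upper)`.
#' @export
sigma_positive_range <- function(model, obstacle_location_index,
                                 range_mm = c(-40, 0), min_sigma_mm = 0.05) {
  lo <- range_mm[1]
  hi <- range_mm[2]
  for (plane in c("obstacle", "target")) {
    row <- sigma_line(model, obstacle_location_index, plane)
    b0 <- row$intercept_mm
    b1 <- row$slope
    if (b1 == 0) {
      if (b0 <= min_sigma_mm) lo <- hi + 1 # empty
    } else {
      crit <- (min_sigma_mm - b0) / b1
      if (b1 > 0) lo <- max(lo, crit) else hi <- min(hi, crit)
    }
  }
  if (lo >= hi) {
    stop(sprintf(
      "sigma_positive_range(): empty admissible range for location %d",
      obstacle_location_index), call. = FALSE)
  }
  c(lo, hi)
}

#' Write / read a fitted sigma model as CSV
#'
#' @param model A [sigma_model()].
#' @param path File path.
#' @return `write_sigma_model()` returns `path` invisibly;
#'   `read_sigma_model()` returns a [sigma_model()].
#' @export
write_sigma_model <- function(model, path) {
  stopifnot(inherits(model, "sigma_model"))
  readr::write_csv(
    model$lines[, c("obstacle_location_index", "plane", "intercept_mm",
                    "slope", "r_squared")],
    path
  )
  invisible(path)
}

#' @rdname write_sigma_model
#' @export
read_sigma_model <- function(path) {
  sigma_model(readr::read_csv(path, show_col_types = FALSE),
              weighting = "read from file")
}
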