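#!/usr/bin/env Rscript
# Stage 3: fit the six sd-versus-excursion lines (two planes x three
# obstacle locations) by weighted least squares, and check them against the
# generator's ground truth.

library(reachgain)

conditions <- readr::read_csv("results/conditions.csv", show_col_types = FALSE)
truth <- default_sigma_truth()

for (tag in c("optimal", "scaled80")) {
  su <- readr::read_csv(sprintf("results/summaries_%s.csv", tag),
                        show_col_types = FALSE)
  fit <- fit_sigma_lines(su, conditions)
  write_sigma_model(fit, sprintf("results/sigma_fit_%s.csv", tag))
  err <- mapply(function(loc, pl, int, sl) {
    (int + sl * -10) / predict_sigma(truth, loc, pl, -10) - 1
  }, fit$lines$obstacle_location_index, fit$lines$plane,
     fit$lines$intercept_mm, fit$lines$slope)
  message(sprintf(
    "%s: R^2 range [%.3f, %.3f]; predicted sigma at -10 mm within %.1f%% of truth",
    tag, min(fit$lines$r_squared), max(fit$lines$r_squared),
    100 * max(abs(err))
  ))
}
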