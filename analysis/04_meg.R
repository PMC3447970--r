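#!/usr/bin/env Rscript
# Stage 4: maximum-expected-gain excursions. For every condition the fitted
# noise model defines an expected-gain curve over theoretical non-positive
# excursions; its argmax e* is the optimal planner's prediction, paired here
# with the observed mean excursion.

library(reachgain)

conditions <- readr::read_csv("results/conditions.csv", show_col_types = FALSE)

for (tag in c("optimal", "scaled80")) {
  su <- readr::read_csv(sprintf("results/summaries_%s.csv", tag),
                        show_col_types = FALSE)
  fit <- read_sigma_model(sprintf("results/sigma_fit_%s.csv", tag))
  meg <- meg_table(conditions, fit, su[, c("condition_id", "mean_endpoint_mm")])
  pvo <- predicted_vs_observed(su, meg)
  readr::write_csv(meg, sprintf("results/meg_%s.csv", tag))
  readr::write_csv(pvo, sprintf("results/predicted_vs_observed_%s.csv", tag))
  slope <- coef(lm(observed_mean_mm ~ predicted_e_star_mm, pvo))[2]
  message(sprintf(
    "%s: e* spans [%.1f, %.1f] mm; observed-vs-predicted regression slope %.2f",
    tag, min(meg$e_star_mm), max(meg$e_star_mm), slope
  ))
}

# one worked expected-gain curve (middle target, middle cost), as a table
su <- readr::read_csv("results/summaries_optimal.csv", show_col_types = FALSE)
fit <- read_sigma_model("results/sigma_fit_optimal.csv")
mid <- conditions[conditions$condition_id == "T2_V2", ]
cv <- eg_curve(mid, fit, su$mean_endpoint_mm[su$condition_id == "T2_V2"],
               step_mm = 0.25)
readr::write_csv(cv$curve, "results/eg_curve_T2_V2.csv")
message(sprintf("T2_V2 curve: e* = %.2f mm, expected gain %.3f points",
                cv$e_star_mm, cv$gain_at_max))
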