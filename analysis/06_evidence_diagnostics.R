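#!/usr/bin/env Rscript
# Stage 6: unity-line evidence and the stationarity / Gaussianity
# diagnostics. Evidence (in decibels) compares the optimal-planning model
# (observed mean excursions scatter about the identity line against the MEG
# predictions) to a free-line alternative.

library(reachgain)

rows <- list()
for (tag in c("optimal", "scaled80")) {
  pvo <- readr::read_csv(sprintf("results/predicted_vs_observed_%s.csv", tag),
                         show_col_types = FALSE)
  ev <- unity_line_evidence(pvo$predicted_e_star_mm, pvo$observed_mean_mm,
                            pvo$observed_se_mm)
  rows[[tag]] <- tibble::tibble(
    agent = tag, evidence_db = ev$evidence_db, odds = ev$odds
  )
  message(sprintf("%s: unity-line evidence %.1f dB (odds %.3g:1)",
                  tag, ev$evidence_db, ev$odds))
}
readr::write_csv(dplyr::bind_rows(rows), "results/evidence.csv")
message(paste(
  "note: with homogeneous simulated subjects the across-subject SEs are a",
  "few tenths of a mm, so this test resolves even the ~1 mm estimation",
  "error of e* in a single experiment; the informative quantity is the",
  "gap between agents, and the scaled agent is rejected far more strongly."
))

trials <- readr::read_csv("results/trials_optimal.csv", show_col_types = FALSE)
prof <- block_position_profile(trials)
readr::write_csv(prof$profile, "results/block_profile.csv")
message(sprintf(
  "within-block profile slope %.4f mm/trial (SE %.4f): no homing-in trend",
  prof$slope_mm_per_trial, prof$slope_se
))

blocks <- split(trials$excursion_mm,
                paste(trials$subject_id, trials$block_index))
lag1 <- mean(vapply(blocks, function(b) {
  a <- trial_autocorrelation(b, max_lag = 15)
  as.numeric(abs(a$acf[2]) > a$upper[1])
}, numeric(1)))
message(sprintf(
  "lag-1 autocorrelation outside the white-noise band in %.1f%% of blocks (nominal ~5%%)",
  100 * lag1
))

qq <- vapply(split(trials$excursion_mm, trials$condition_id),
             function(v) qq_gaussian(v)$linearity, numeric(1))
readr::write_csv(
  tibble::tibble(condition_id = names(qq), linearity = unname(qq)),
  "results/qq_linearity.csv"
)
message(sprintf("QQ linearity across conditions: min %.4f", min(qq)))
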