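#!/usr/bin/env Rscript
# Stage 2: condition-level crossing summaries (the value-diagram statistics).
# Pooled summaries centre each subject on its own condition mean before
# pooling second moments; across-subject SEs of the means are also kept.

library(reachgain)

for (tag in c("optimal", "scaled80")) {
  trials <- readr::read_csv(sprintf("results/trials_%s.csv", tag),
                            show_col_types = FALSE)
  pooled <- summarize_conditions(trials, pooling = "pooled")
  readr::write_csv(pooled, sprintf("results/summaries_%s.csv", tag))
  by_subj <- summarize_conditions(trials, pooling = "per_subject")
  readr::write_csv(by_subj, sprintf("results/summaries_%s_by_subject.csv", tag))
  message(sprintf(
    "%s: mean excursions span [%.1f, %.1f] mm; pooled excursion SDs span [%.2f, %.2f] mm",
    tag, min(pooled$mean_excursion_mm), max(pooled$mean_excursion_mm),
    min(pooled$sd_excursion_mm), max(pooled$sd_excursion_mm)
  ))
}
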