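#!/usr/bin/env Rscript
# Stage 3 — polynomial degree selection and term pruning.
#
# Candidate Poisson GLMs on the 7-day-averaged covariates differ in the
# polynomial degrees of temperature, humidity, temperature range and the
# secular time trend (searched over {1..20}x{1..10}x{1..5}x{1..20} by
# coordinate descent on AIC), always with weekday and month dummies and
# the per-10,000-subscriber offset. Whole term groups whose removal
# lowers the AIC further are then pruned greedily.

suppressPackageStartupMessages(library(coldcalls))

study <- load_daily_series("results/study.csv")
features <- engineer_features(study)
utils::write.csv(features, "results/engineered.csv", row.names = FALSE)

sr <- select_degrees(features, strategy = "coordinate")
cat(sprintf("degree search: %d candidate fits\n", nrow(sr$aic_trace)))
print(sr)

spec <- prune_terms(features, sr$best_spec)
pruned <- attr(spec, "pruned")
cat("pruned groups:", if (length(pruned)) paste(pruned, collapse = ", ")
    else "(none)", "\n")
print(spec)

write_model_spec(spec, "results/selected_spec.json")
utils::write.csv(sr$aic_trace, "results/aic_trace.csv", row.names = FALSE)
cat("wrote results/selected_spec.json and results/aic_trace.csv\n")
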