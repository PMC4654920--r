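#!/usr/bin/env Rscript
# Stage 2 — exploratory rate-versus-weather curves.
#
# Before any modelling, the call rate is averaged within each distinct
# value of a weather variable at lags 0-34. The curves barely change with
# the lag because the weather variables are themselves strongly
# autocorrelated — the observation that motivates using 7-day trailing
# averages (and not per-lag terms) in the regression.

suppressPackageStartupMessages(library(coldcalls))

study <- load_daily_series("results/study.csv")
dir.create("results/explore", showWarnings = FALSE, recursive = TRUE)

for (v in c("tmin", "humidity", "trange")) {
  curves <- do.call(rbind, lapply(c(0L, 7L, 21L, 34L), function(l) {
    sc <- smoothed_rate_curve(study, v, lag = l)
    sc$lag <- l
    sc
  }))
  utils::write.csv(curves, sprintf("results/explore/rate_vs_%s.csv", v),
                   row.names = FALSE)
  cat(sprintf("%s: %d distinct values; rate at coldest/driest end %.2f\n",
              v, length(unique(curves$value[curves$lag == 0])),
              curves$mean_rate[curves$lag == 0][1]))
}

a <- acf_series(study$tmin_c, 34)
utils::write.csv(a, "results/explore/tmin_acf.csv", row.names = FALSE)
cat(sprintf("tmin autocorrelation lag 1-34: %.3f ... %.3f\n",
            a$r[1], a$r[34]))
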