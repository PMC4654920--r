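# coldcalls

Daily counts of health-related emergency calls — for instance the calls
to a personal-emergency-link service for older adults that end in a
hospital admission — respond to weather. `coldcalls` implements a
complete, tested workflow for quantifying that response from a contiguous
daily series of calls, active subscribers, and weather (minimum/maximum
temperature, relative humidity), and for answering the operational
question behind it: **is there a critical temperature below which demand
for the service accelerates, and by how much per degree?**

It is written for biostatisticians and service planners working with
count time series: the package gives them the model, the model-building
loop, the diagnostics, and a synthetic-study generator with known ground
truth so everything can be validated without access to proprietary call
records.

## The model

Counts are modelled observation-driven (GLARMA: generalized linear
autoregressive moving-average), with log link and subscriber offset:

```
W_t = x_t' beta + log(s_t / 10000) + sum_{j in L} phi_j * e_{t-j}
y_t | past  ~  Poisson(mu_t)   or   NegBin(mu_t, theta),   mu_t = exp(W_t)
e_t = (y_t - mu_t) / sqrt(V(mu_t))        (Pearson residual; V = mu or mu + mu^2/theta)
```

The regression `x_t' beta` holds orthonormal polynomials of 7-day
trailing averages of minimum temperature, humidity and temperature range,
an orthonormal polynomial in scaled time for the secular trend, weekday
and month dummies (Sunday/January references), and an optional date-window
indicator. The workflow is the classic count-time-series loop:

1. AIC search over the polynomial degrees (Poisson GLM fits, coordinate
   descent over `{1..20}x{1..10}x{1..5}x{1..20}`), then greedy pruning of
   whole term groups;
2. residual ACF scan (lags 1–35) → GLARMA refit at the significant lags;
3. deviance/df overdispersion check (default threshold 1.15) → negative
   binomial refit;
4. PIT calibration diagnostics;
5. centered effect curves with delta-method bands, average per-degree
   effects in percent, and detection of the critical cold temperature by
   a segmented-term profile with a flat-band validation.

## Worked example

```r
library(coldcalls)

study <- simulate_study(seed = 3)      # six synthetic years, known truth
res   <- run_pipeline(study, pipeline_config(seed = 3))
print(res)
```

```
pipeline result
  [load] loaded 2192 days (2000-01-01 to 2005-12-31)
  [smooth] 7-day trailing averages; first 6 day(s) excluded
  [select] AIC degrees: tem=11 hum=2 rng=1 time=15 (121 fits)
  [prune] dropped group(s): (none)
  [glm] Poisson GLM: AIC 15230.62, deviance 3634.1 on 2139 df
  [acf] significant residual autocorrelation at lag(s) 1, 3, 5, 6, 7, 8, 9, 13, 26, 27, 28; refitting Poisson GLARMA
  [overdispersion] deviance ratio 1.317 >= 1.15; refitting negative binomial
  [threshold] critical cold threshold 14.0 degC
```

Reading the trace: the degree search settled on an 11th-degree
temperature polynomial and kept every term group; the Poisson GLM's
residuals showed serial correlation at eleven lags, so a Poisson GLARMA
was refit at those lags; its deviance ratio 1.317 flagged moderate
overdispersion, so the final model is a negative binomial GLARMA; and the
segmented-temperature profile put the critical cold threshold at
14.0 °C — one grid step below this study's true value of 15 °C (the
estimator's sampling spread is about ±2 °C at the default cold slope of
3.03% per °C; see the methods vignette).

Individual quantities come from the result object:

```r
res$overdispersion$ratio              # 1.316839
res$final_fit$theta                   # 117.5752  (true value 100)
res$threshold$critical                # 14  (true threshold 15)

q <- quantile(res$final_fit$design$data$avgrng, c(0.1, 0.9))
average_unit_effect(res$final_fit, "avgrng", unname(q))
# avgrng: +2.97% per unit increase over [2.94, 4.72] (95% CI [1.05%, 4.92%])
```

The per-degree cold effect below the detected knot, from the segmented
profile in `res$threshold$scan`, is +4.28% (95% CI [3.03%, 5.54%]) for
this study — the generating value is +3.03%.

All artifacts (`coefficients.json`, `effects_*.csv`, `acf.csv`,
`pit.csv`, `threshold.json`, `decisions.json`, `report.md`) are written
when `pipeline_config(out_dir = ...)` is set.

The numbered scripts under `analysis/` run the same workflow as a
narrated sequence — simulate, explore, select, fit, extract effects —
writing tables under `results/`.

## Limitations

The synthetic generator reproduces the marginal and autocorrelation
structure of subtropical daily weather and paper-scale call volumes, not
extreme events, holidays or epidemics. Threshold estimates are precise to
a couple of degrees at realistic effect sizes — see the methods vignette
(`vignettes/coldcalls-methods.Rmd`) for the information-limit discussion
and every numerical default.
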