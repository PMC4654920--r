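#' Deterministic sub-seed derivation
#'
#' All randomness in a synthetic study flows from one user seed; each
#' stage draws from a sub-seed derived by this counter-based rule, so
#' stage-level and end-to-end runs are reproducible independently.
#'
#' @param seed integer master seed.
#' @param k stage counter (small non-negative integer).
#' @return a 32-bit integer sub-seed.
#' @export
split_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %%
               2147483647)
}

#' Weather generator parameters
#'
#' Defaults emulate a humid subtropical climate: daily minimum temperature
#' as an annual sinusoid (coldest mid-January) plus an AR(1) anomaly,
#' giving a strongly autocorrelated series spanning roughly 6-29 degC;
#' relative humidity around 78% partially driven by the temperature
#' anomaly; a narrow positive daily temperature range around 4 degC.
#'
#' @param n series length in days (default 2192, six years).
#' @param start start date (default `"2000-01-01"`).
#' @param temp_mean annual mean of daily minimum temperature, degC.
#' @param temp_amplitude annual sinusoid amplitude, degC.
#' @param temp_peak_doy day of year of the warmest day (default 196,
#'   mid-July).
#' @param anomaly_rho AR(1) coefficient of the temperature anomaly.
#' @param anomaly_sd annual mean stationary SD of the anomaly, degC.
#' @param anomaly_season_amp relative seasonal modulation of the anomaly
#'   SD (winter cold surges are more variable than summer nights): the
#'   local SD is `anomaly_sd * (1 + amp)` at mid-winter and
#'   `anomaly_sd * (1 - amp)` at mid-summer.
#' @param humidity_mean,humidity_sd marginal mean/SD of humidity, percent.
#' @param humidity_temp_cor correlation of humidity with the temperature
#'   anomaly.
#' @param humidity_rho AR(1) coefficient of the humidity residual.
#' @param range_mean,range_sd mean/SD of the daily temperature range, degC
#'   (truncated below at `range_floor`).
#' @param range_rho AR(1) coefficient of the range series.
#' @param range_floor positive lower truncation of the range, degC.
#' @return list of class `weather_params`.
#' @export
weather_params <- function(n = 2192L, start = "2000-01-01",
                           temp_mean = 21, temp_amplitude = 5.6,
                           temp_peak_doy = 196L,
                           anomaly_rho = 0.85, anomaly_sd = 2.2,
                           anomaly_season_amp = 0.6,
                           humidity_mean = 78, humidity_sd = 7.5,
                           humidity_temp_cor = 0.3, humidity_rho = 0.7,
                           range_mean = 3.9, range_sd = 1.2,
                           range_rho = 0.5, range_floor = 0.5) {
  # defaults emulate the study's printed descriptives: minimum temperature
  # spanning ~6-29 degC with ~11% of days at or below 15, lag-1 ACF ~0.96
  # decaying to ~0.64 by lag 34, humidity ~32-97%, range ~1-12 degC
  stopifnot(anomaly_rho > 0, anomaly_rho < 1,
            anomaly_season_amp >= 0, anomaly_season_amp < 1,
            humidity_rho >= 0, humidity_rho < 1,
            range_rho >= 0, range_rho < 1,
            range_floor > 0, n >= 2L)
  structure(as.list(environment()), class = "weather_params")
}

ar1_series <- function(n, rho, stationary_sd) {
  # stationary_sd may be a vector: slowly varying local SD
  sd_t <- rep_len(stationary_sd, n)
  innov_sd <- sd_t * sqrt(1 - rho^2)
  x <- numeric(n)
  x[1L] <- stats::rnorm(1L, 0, sd_t[1L])
  eps <- stats::rnorm(n - 1L, 0, innov_sd[-1L])
  for (t in 2:n) x[t] <- rho * x[t - 1L] + eps[t - 1L]
  x
}

#' Simulate daily weather
#'
#' Daily minimum temperature is an annual sinusoid plus an AR(1) anomaly;
#' humidity loads on the temperature anomaly plus its own AR(1) residual
#' (clipped to `[0, 100]`); the temperature range is an AR(1) series
#' truncated below; `tmax = tmin + range`. Deterministic given the seed.
#'
#' @param params a [weather_params()].
#' @param seed integer seed; required.
#' @return data frame with `date`, `tmin_c`, `tmax_c`, `humidity_pct`.
#' @export
simulate_weather <- function(params = weather_params(), seed) {
  stopifnot(inherits(params, "weather_params"))
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  n <- params$n
  dates <- seq(as.Date(params$start), by = "day", length.out = n)
  doy <- as.integer(format(dates, "%j"))
  season_cos <- cos(2 * pi * (doy - params$temp_peak_doy) / 365.25)
  seasonal <- params$temp_mean + params$temp_amplitude * season_cos
  local_sd <- params$anomaly_sd *
    (1 - params$anomaly_season_amp * season_cos)
  anomaly <- ar1_series(n, params$anomaly_rho, local_sd)
  tmin <- seasonal + anomaly

  resid_sd <- params$humidity_sd *
    sqrt(max(1 - params$humidity_temp_cor^2, 0))
  loading <- params$humidity_temp_cor * params$humidity_sd /
    params$anomaly_sd
  hum <- params$humidity_mean + loading * anomaly +
    ar1_series(n, params$humidity_rho, resid_sd)
  hum <- pmin(pmax(hum, 0), 100)

  rng <- params$range_mean + ar1_series(n, params$range_rho,
                                        params$range_sd)
  rng <- pmax(rng, params$range_floor)

  data.frame(date = dates, tmin_c = tmin, tmax_c = tmin + rng,
             humidity_pct = hum)
}

#' Ground-truth parameters of a synthetic study
#'
#' Describes the generating model of the call counts: a baseline rate per
#' 10,000 subscribers; weekday and month multipliers (Sunday and January
#' at 1); a low-order polynomial secular trend in scaled time; a piecewise
#' log-linear temperature effect (rising toward cold below the threshold,
#' flat in the mid-band, mildly rising above the warm knot) applied to the
#' 7-day average minimum temperature; a linear temperature-range effect; a
#' sparse-lag autoregressive recursion; negative binomial dispersion; and
#' a smoothly growing (logistic) subscriber base. The piecewise-linear
#' temperature truth keeps the fitted polynomial model mildly misspecified
#' on purpose, so threshold recovery is a meaningful check.
#'
#' @param baseline_rate expected calls per 10,000 subscribers at reference
#'   conditions.
#' @param weekday_mult multipliers for Monday..Saturday (Sunday = 1).
#' @param month_mult multipliers for February..December (January = 1).
#' @param trend_coef polynomial coefficients of the log-scale secular
#'   trend in scaled time `u` (no intercept term).
#' @param cold_threshold true critical cold temperature, degC.
#' @param cold_slope log-rate increase per degC *decrease* below the
#'   threshold.
#' @param warm_knot temperature above which the warm rise starts, degC.
#' @param warm_slope log-rate increase per degC increase above the knot.
#' @param range_slope log-rate increase per degC of 7-day average
#'   temperature range.
#' @param range_center temperature-range value at which the range effect
#'   is zero, degC.
#' @param ar_lags,phi autoregressive lags and coefficients.
#' @param theta negative binomial shape (`Inf` for Poisson counts).
#' @param sub_start,sub_end,sub_steepness logistic subscriber growth: from
#'   about `sub_start` to about `sub_end` over the study, with the given
#'   steepness.
#' @return list of class `truth_params`.
#' @export
truth_params <- function(baseline_rate = 11.5,
                         weekday_mult = c(Monday = 1.0934,
                                          Tuesday = 1.0220,
                                          Wednesday = 1.0078,
                                          Thursday = 1.0322,
                                          Friday = 1.0103,
                                          Saturday = 0.9930),
                         month_mult = c(February = 1.0439, March = 1.0141,
                                        April = 0.9480, May = 0.9362,
                                        June = 0.8889, July = 0.9299,
                                        August = 0.9512,
                                        September = 0.9606,
                                        October = 0.9480,
                                        November = 0.9707,
                                        December = 0.9865),
                         trend_coef = c(0.12, -0.15),
                         cold_threshold = 15,
                         cold_slope = log(1.0303),
                         warm_knot = 24,
                         warm_slope = log(1.012),
                         range_slope = log(1.0224),
                         range_center = 4,
                         ar_lags = c(1L, 5L),
                         phi = c(0.10, 0.05),
                         theta = 100,
                         sub_start = 18000, sub_end = 38000,
                         sub_steepness = 6) {
  stopifnot(baseline_rate > 0, all(weekday_mult > 0), all(month_mult > 0),
            theta > 0, length(phi) == length(ar_lags))
  structure(as.list(environment()), class = "truth_params")
}

#' @rdname truth_params
#' @export
default_truth <- function() truth_params()

#' True log-scale temperature effect
#'
#' Piecewise log-linear: `cold_slope * (threshold - T)` below the
#' threshold, 0 in `[threshold, warm_knot]`, `warm_slope * (T -
#' warm_knot)` above.
#'
#' @param truth a [truth_params()].
#' @param temp temperature values, degC.
#' @return numeric log-scale effect.
#' @export
true_temp_effect <- function(truth, temp) {
  ifelse(temp < truth$cold_threshold,
         truth$cold_slope * (truth$cold_threshold - temp),
         ifelse(temp > truth$warm_knot,
                truth$warm_slope * (temp - truth$warm_knot), 0))
}

truth_subscribers <- function(truth, n) {
  u <- seq(0, 1, length.out = n)
  truth$sub_start + (truth$sub_end - truth$sub_start) /
    (1 + exp(-truth$sub_steepness * (u - 0.5)))
}

# Log-scale mean rate (per 10,000 subscribers) under the truth, using
# the same 7-day trailing averages the fitted model sees; the first six
# days use the expanding mean (they are dropped from all likelihoods
# downstream anyway).
truth_log_rate <- function(truth, weather) {
  n <- nrow(weather)
  expanding_mean <- function(x, window = 7L) {
    tm <- trailing_mean(x, window)$values
    head_idx <- seq_len(window - 1L)
    tm[head_idx] <- cumsum(x[head_idx]) / head_idx
    tm
  }
  avgtem <- expanding_mean(weather$tmin_c)
  avgrng <- expanding_mean(weather$tmax_c - weather$tmin_c)
  dates <- as.Date(weather$date)
  wday <- as.POSIXlt(dates)$wday
  mon <- as.POSIXlt(dates)$mon + 1L
  u <- seq(0, 1, length.out = n)
  wk_log <- c(0, log(truth$weekday_mult))[wday + 1L]
  mo_log <- c(0, log(truth$month_mult))[mon]
  trend <- as.numeric(outer(u, seq_along(truth$trend_coef), `^`) %*%
                        truth$trend_coef)
  log(truth$baseline_rate) + true_temp_effect(truth, avgtem) +
    truth$range_slope * (avgrng - truth$range_center) + wk_log + mo_log +
    trend
}

#' Simulate a complete synthetic study
#'
#' Composes the weather generator, the deterministic subscriber growth
#' curve and the GLARMA count recursion under the truth's mean structure
#' into a schema-complete [daily_series()]. Randomness for the weather and
#' the counts comes from sub-seeds derived from `seed` via [split_seed()].
#'
#' @param truth a [truth_params()] (default [default_truth()]).
#' @param weather either a weather data frame from [simulate_weather()] or
#'   a [weather_params()] object to simulate from (default).
#' @param seed integer master seed; required.
#' @return a validated [daily_series()]; attributes `truth` and `eta`
#'   (the generating log-mean of the counts) are attached.
#' @export
simulate_study <- function(truth = default_truth(),
                           weather = weather_params(), seed) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  stopifnot(inherits(truth, "truth_params"))
  if (inherits(weather, "weather_params")) {
    weather <- simulate_weather(weather, seed = split_seed(seed, 1L))
  }
  n <- nrow(weather)
  subs <- truth_subscribers(truth, n)
  log_rate <- truth_log_rate(truth, weather)
  eta <- log(subs / 10000) + log_rate
  family <- if (is.finite(truth$theta)) "negbin" else "poisson"
  counts <- simulate_glarma(eta, phi = truth$phi, ar_lags = truth$ar_lags,
                            family = family,
                            theta = if (is.finite(truth$theta)) truth$theta,
                            seed = split_seed(seed, 2L))
  out <- daily_series(
    dates = weather$date,
    calls = as.integer(counts),
    subscribers = subs,
    tmin_c = weather$tmin_c,
    tmax_c = weather$tmax_c,
    humidity_pct = weather$humidity_pct
  )
  attr(out, "truth") <- truth
  attr(out, "eta") <- eta
  out
}

#' Write a synthetic study with its ground-truth sidecar
#'
#' Writes the study CSV in the exact input schema plus `truth.json` with
#' every generating parameter.
#'
#' @param study a [simulate_study()] result.
#' @param path output CSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path) {
  write_daily_series(study, path)
  truth <- attr(study, "truth")
  if (!is.null(truth)) {
    jsonlite::write_json(unclass(truth),
                         file.path(dirname(path), "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
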