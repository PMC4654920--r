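#' Sample autocorrelation function with white-noise bound
#'
#' Standard mean-centered sample ACF: the lag-k cross-product over the
#' lag-0 variance, with the approximate 95% white-noise bound
#' `1.96 / sqrt(n)`.
#'
#' @param x numeric series.
#' @param max_lag largest lag (must satisfy `n > max_lag + 1`).
#' @return data frame with columns `lag` (1..max_lag) and `r`; attributes
#'   `bound` and `n`.
#' @export
acf_series <- function(x, max_lag) {
  n <- length(x)
  max_lag <- as.integer(max_lag)
  if (n <= max_lag + 1L) stop("series too short for max_lag = ", max_lag,
                              call. = FALSE)
  if (stats::var(x) == 0) stop("constant series has no autocorrelation",
                               call. = FALSE)
  if (max_lag == 0L) {
    out <- data.frame(lag = integer(0), r = numeric(0))
  } else {
    a <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)
    out <- data.frame(lag = seq_len(max_lag),
                      r = as.numeric(a$acf)[-1L])
  }
  attr(out, "bound") <- 1.96 / sqrt(n)
  attr(out, "n") <- n
  out
}

#' Detect significant autoregressive lags in residuals
#'
#' Returns the lags whose sample autocorrelation exceeds the two-sided
#' per-lag normal bound `z_{1 - alpha/2} / sqrt(n)`.
#'
#' @param residuals residual series from a fitted model.
#' @param max_lag largest lag examined (default 35).
#' @param alpha two-sided significance level (default 0.05).
#' @return sorted integer vector of significant lags (possibly empty).
#' @export
detect_ar_lags <- function(residuals, max_lag = 35L, alpha = 0.05) {
  if (max_lag == 0L) return(integer(0))
  a <- acf_series(residuals, max_lag)
  bound <- stats::qnorm(1 - alpha / 2) / sqrt(attr(a, "n"))
  sort(a$lag[abs(a$r) > bound])
}

#' Overdispersion decision from the Poisson deviance ratio
#'
#' Flags a negative binomial refit when the Poisson residual deviance per
#' residual degree of freedom reaches the threshold (a ratio exactly at
#' the threshold triggers the refit).
#'
#' @param fit a fitted `glm_fit` or `glarma_fit` (Poisson).
#' @param threshold dispersion-ratio threshold (default 1.15).
#' @return list with `decision` (`"poisson_ok"` or `"refit_negbin"`),
#'   `ratio`, `deviance`, `df_resid`, `threshold`.
#' @export
overdispersion_decision <- function(fit, threshold = 1.15) {
  ds <- deviance_stat(fit)
  list(
    decision = if (ds$ratio >= threshold) "refit_negbin" else "poisson_ok",
    ratio = ds$ratio,
    deviance = ds$deviance,
    df_resid = ds$df_resid,
    threshold = threshold
  )
}

pit_cdfs <- function(fit) {
  y <- fit$design$y
  mu <- fit$mu
  if (fit$family == "negbin") {
    list(hi = stats::pnbinom(y, size = fit$theta, mu = mu),
         lo = ifelse(y > 0, stats::pnbinom(y - 1, size = fit$theta,
                                           mu = mu), 0))
  } else {
    list(hi = stats::ppois(y, mu),
         lo = ifelse(y > 0, stats::ppois(y - 1, mu), 0))
  }
}

#' Probability integral transform diagnostics for count fits
#'
#' Computes the non-randomized PIT histogram for count data (averaging,
#' over observations, the conditional uniform mass between the predictive
#' CDF evaluated just below and at the observed count) and the randomized
#' PIT values `u_t = F_t(y_t - 1) + v_t (F_t(y_t) - F_t(y_t - 1))` with
#' `v_t` uniform under the supplied seed. Under a correctly specified
#' model the histogram is flat (heights average 1) and the randomized
#' values are standard uniform.
#'
#' @param fit a fitted `glm_fit` or `glarma_fit`.
#' @param n_bins number of equal-probability bins (default 10).
#' @param seed integer seed for the randomized PIT; required.
#' @return an object of class `pit_result`: `edges` (bin edges),
#'   `heights` (non-randomized histogram heights, mean 1), `u`
#'   (randomized PIT values in `[0, 1]`), `seed`.
#' @export
pit <- function(fit, n_bins = 10L, seed) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  n_bins <- as.integer(n_bins)
  cd <- pit_cdfs(fit)
  lo <- cd$lo
  hi <- cd$hi
  n <- length(lo)

  # conditional CDF of the PIT given y_t, averaged over t, at each edge
  edges <- seq(0, 1, length.out = n_bins + 1L)
  Fbar <- vapply(edges, function(u) {
    w <- ifelse(u >= hi, 1,
                ifelse(u <= lo, 0,
                       (u - lo) / pmax(hi - lo, .Machine$double.eps)))
    mean(w)
  }, numeric(1))
  heights <- n_bins * diff(Fbar)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  v <- stats::runif(n)
  u <- lo + v * (hi - lo)

  structure(list(edges = edges, heights = heights, u = u, seed = seed),
            class = "pit_result")
}

#' @export
print.pit_result <- function(x, ...) {
  cat("PIT diagnostic:", length(x$heights), "bins, heights",
      paste(sprintf("%.2f", x$heights), collapse = " "), "\n")
  invisible(x)
}

#' Lag-smoothed call-rate curve against a weather variable
#'
#' For each distinct value of the chosen variable at lag `lag`, averages
#' all call rates observed `lag` days later — the exploratory
#' rate-versus-weather curves used before modelling.
#'
#' @param series a [daily_series()].
#' @param variable `"tmin"`, `"humidity"` or `"trange"`.
#' @param lag non-negative integer lag in days.
#' @return data frame with `value` (sorted distinct variable values),
#'   `mean_rate`, `n_days`.
#' @export
smoothed_rate_curve <- function(series, variable = c("tmin", "humidity",
                                                     "trange"),
                                lag = 0L) {
  variable <- match.arg(variable)
  validate_daily_series(series)
  lag <- as.integer(lag)
  n <- nrow(series)
  if (lag < 0L) stop("lag must be non-negative", call. = FALSE)
  if (lag >= n) stop("lag must be smaller than the series length",
                     call. = FALSE)
  col <- switch(variable, tmin = "tmin_c", humidity = "humidity_pct",
                trange = "trange")
  v <- series[[col]][seq_len(n - lag)]
  r <- call_rate(series)[seq(lag + 1L, n)]
  agg <- stats::aggregate(r, by = list(value = v),
                          FUN = function(z) c(mean(z), length(z)))
  out <- data.frame(value = agg$value,
                    mean_rate = agg$x[, 1],
                    n_days = as.integer(agg$x[, 2]))
  out[order(out$value), , drop = FALSE]
}
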