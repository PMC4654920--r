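# Shared fixture builders. Everything is generated in code; no files.

# A tiny well-formed daily series (constructed by arithmetic, not by the
# package's own simulator, so validation tests are independent of it).
toy_series <- function(n = 30L, start = "2003-01-01", calls = NULL) {
  dates <- seq(as.Date(start), by = "day", length.out = n)
  if (is.null(calls)) calls <- rep(c(3L, 5L, 4L, 6L, 2L, 7L), length.out = n)
  daily_series(
    dates = dates,
    calls = calls,
    subscribers = rep(20000, n),
    tmin_c = 15 + 5 * sin(seq_len(n) / 5),
    tmax_c = 19 + 5 * sin(seq_len(n) / 5) + cos(seq_len(n) / 3),
    humidity_pct = 75 + 10 * cos(seq_len(n) / 7)
  )
}

# Small design matrix with arbitrary covariates for fitter tests.
toy_design <- function(n = 50L, p = 3L, seed = 1L, offset = TRUE) {
  set.seed(seed)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (p > 0) {
    X <- cbind(X, matrix(stats::rnorm(n * p), n, p,
                         dimnames = list(NULL, paste0("x", seq_len(p)))))
  }
  off <- if (offset) log(stats::runif(n, 0.8, 1.25)) else rep(0, n)
  beta <- c(1.2, stats::rnorm(p, 0, 0.3))
  mu <- exp(as.numeric(X %*% beta) + off)
  y <- stats::rpois(n, mu)
  structure(
    list(y = y, X = X, offset = off,
         groups = c("intercept", paste0("x", seq_len(p))),
         bases = list(), rows = seq_len(n),
         spec = model_spec("poisson"),
         data = as.data.frame(X[, -1, drop = FALSE])),
    class = "design_matrix"
  )
}

# Independent straight-line GLARMA log-likelihood: no shared code with
# glarma_loglik (plain double loop, library densities).
naive_glarma_loglik <- function(beta, phi, design, ar_lags, family,
                                theta = NULL) {
  X <- design$X; y <- design$y; off <- design$offset
  n <- length(y)
  e <- numeric(n)
  ll <- 0
  for (t in seq_len(n)) {
    w <- off[t] + sum(X[t, ] * beta)
    for (j in seq_along(ar_lags)) {
      if (t - ar_lags[j] >= 1) w <- w + phi[j] * e[t - ar_lags[j]]
    }
    mu <- exp(w)
    if (family == "poisson") {
      ll <- ll + stats::dpois(y[t], mu, log = TRUE)
      e[t] <- (y[t] - mu) / sqrt(mu)
    } else {
      ll <- ll + stats::dnbinom(y[t], size = theta, mu = mu, log = TRUE)
      e[t] <- (y[t] - mu) / sqrt(mu + mu^2 / theta)
    }
  }
  ll
}

# Design + truth used by parameter-recovery experiments: exposure held at
# 10,000 subscribers so the spec'd phi values sit inside the stability
# region of the Pearson-residual feedback.
recovery_design <- function(seed) {
  w <- simulate_weather(weather_params(), seed = seed)
  n <- nrow(w)
  ser <- daily_series(w$date, rep(0L, n), rep(10000, n), w$tmin_c,
                      w$tmax_c, w$humidity_pct)
  f <- engineer_features(ser)
  spec <- model_spec("negbin", deg_tem = 2, deg_rng = 1, deg_time = 2,
                     include_weekday = TRUE)
  build_design(f, spec)
}

# U-shaped mean via a positive quadratic coefficient on the orthonormal
# temperature basis (basis columns have unit norm, hence the sqrt(n) scale).
recovery_beta <- function(design) {
  stats::setNames(
    c(log(11), 2.0, 1.2, 0.6, 0.8, -0.5,
      0.089, 0.022, 0.008, 0.032, 0.010, -0.007),
    colnames(design$X)
  )
}

# Study with a known quadratic temperature effect and no feedback, for
# degree-selection tests.
quadratic_study <- function(seed, n = 1100L) {
  w <- simulate_weather(weather_params(n = n), seed = seed)
  subs <- rep(20000, n)
  avgtem <- trailing_mean(w$tmin_c, 7)$values
  avgtem[1:6] <- cumsum(w$tmin_c[1:6]) / (1:6)
  eta <- log(subs / 10000) + log(10) + 0.012 * (avgtem - 21)^2
  y <- simulate_glarma(eta, family = "poisson", seed = seed + 1)
  daily_series(w$date, as.integer(y), subs, w$tmin_c, w$tmax_c,
               w$humidity_pct)
}

simulate_on_design <- function(design, beta, phi, ar_lags, family, theta,
                               seed) {
  eta <- as.numeric(design$X %*% beta) + design$offset
  y <- simulate_glarma(eta, phi = phi, ar_lags = ar_lags, family = family,
                       theta = theta, seed = seed)
  design$y <- as.integer(y)
  design
}
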