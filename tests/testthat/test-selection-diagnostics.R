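test_that("a singleton grid returns its only spec with a one-row trace", {
  f <- engineer_features(quadratic_study(1))
  sr <- select_degrees(f, grid = list(tem = 1, hum = 1, rng = 1, time = 1),
                       strategy = "coordinate", include_month = FALSE)
  expect_equal(nrow(sr$aic_trace), 1L)
  expect_equal(c(sr$best_spec$deg_tem, sr$best_spec$deg_hum,
                 sr$best_spec$deg_rng, sr$best_spec$deg_time),
               c(1L, 1L, 1L, 1L))
})

test_that("coordinate search finds the quadratic temperature effect", {
  hits <- 0
  for (s in 1:5) {
    f <- engineer_features(quadratic_study(100 + s))
    sr <- select_degrees(
      f, grid = list(tem = 1:6, hum = 1:3, rng = 1:3, time = 1:6),
      strategy = "coordinate", include_month = FALSE)
    if (sr$best_spec$deg_tem %in% c(2L, 3L)) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("coordinate and exhaustive strategies agree on a tiny grid", {
  f <- engineer_features(quadratic_study(7, n = 700L))
  grid <- list(tem = 1:3, hum = 1, rng = 1, time = 1:3)
  sr_c <- select_degrees(f, grid, strategy = "coordinate",
                         include_month = FALSE, include_weekday = FALSE)
  sr_e <- select_degrees(f, grid, strategy = "exhaustive",
                         include_month = FALSE, include_weekday = FALSE)
  expect_equal(min(sr_c$aic_trace$aic, na.rm = TRUE),
               min(sr_e$aic_trace$aic, na.rm = TRUE), tolerance = 1e-8)
})

test_that("pruning drops a pure-noise group and keeps informative ones", {
  set.seed(31)
  st <- quadratic_study(41)   # humidity has no effect on the counts
  f <- engineer_features(st)
  spec <- model_spec("poisson", deg_tem = 2, deg_hum = 2, deg_rng = 1,
                     deg_time = 1, include_weekday = FALSE)
  pruned <- prune_terms(f, spec)
  expect_equal(pruned$deg_hum, 0L)
  expect_equal(pruned$deg_tem, 2L)
  expect_true("avghum" %in% attr(pruned, "pruned"))

  # nothing removable: intercept-only spec is a fixed point
  s0 <- model_spec("poisson")
  expect_equal(length(attr(prune_terms(f, s0), "pruned")), 0L)
})

test_that("sample ACF matches known analytic cases", {
  set.seed(32)
  # i.i.d. noise: everything inside 3/sqrt(n)
  x <- stats::rnorm(2000)
  a <- acf_series(x, 34)
  expect_lte(sum(abs(a$r) > 3 / sqrt(2000)), 1)
  expect_equal(attr(a, "bound"), 1.96 / sqrt(2000))

  # AR(1) rho = 0.95
  n <- 5000
  ar <- as.numeric(stats::arima.sim(list(ar = 0.95), n))
  a2 <- acf_series(ar, 5)
  expect_lt(abs(a2$r[1] - 0.95), 0.02)

  # alternating series: r1 = -1 up to the 1/n edge term
  alt <- rep(c(1, -1), 100)
  a3 <- acf_series(alt, 2)
  expect_lt(abs(a3$r[1] - (-1)), 2 / 200 + 1e-9)

  expect_error(acf_series(rep(1, 50), 5), "constant")
})

test_that("lag detection flags true feedback lags and little else", {
  # residuals of a GLM fitted to feedback-generated counts contain {1, 5}
  d <- recovery_design(seed = 501)
  d <- simulate_on_design(d, recovery_beta(d), phi = c(0.15, 0.10),
                          ar_lags = c(1, 5), family = "negbin",
                          theta = 30, seed = 502)
  g <- fit_glm(d, "poisson")
  lags <- detect_ar_lags(g$pearson_resid, max_lag = 35)
  expect_true(all(c(1L, 5L) %in% lags))

  # white noise: about alpha * max_lag false positives
  set.seed(33)
  wn_lags <- detect_ar_lags(stats::rnorm(3000), max_lag = 35)
  expect_lte(length(wn_lags), ceiling(0.05 * 35) + 1)

  expect_identical(detect_ar_lags(stats::rnorm(100), max_lag = 0),
                   integer(0))
  # invariant to affine rescaling
  r <- stats::rnorm(500) + stats::arima.sim(list(ar = 0.3), 500)
  expect_identical(detect_ar_lags(as.numeric(r), 20),
                   detect_ar_lags(as.numeric(100 - 7 * r), 20))
})

test_that("overdispersion decision follows the deviance ratio", {
  # the study's printed figures: deviance 2741.1 on 2109 df
  expect_gt(2741.1 / 2109, 1.15)   # -> the default rule triggers the NB refit

  d <- toy_design(n = 400, p = 1, seed = 34)
  fit <- fit_glm(d, "poisson")
  od <- overdispersion_decision(fit)
  expect_lt(abs(od$ratio - 1), 0.25)
  expect_equal(od$decision, if (od$ratio >= 1.15) "refit_negbin"
               else "poisson_ok")
  # boundary convention: ratio exactly at the threshold refits
  od2 <- overdispersion_decision(fit, threshold = od$ratio)
  expect_equal(od2$decision, "refit_negbin")
  od3 <- overdispersion_decision(fit, threshold = od$ratio + 1e-9)
  expect_equal(od3$decision, "poisson_ok")
})

test_that("PIT histogram is flat under the true model, U-shaped under misspecification", {
  set.seed(35)
  n <- 2186
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  make_design <- function(y, fam) structure(
    list(y = y, X = X, offset = rep(0, n), groups = "intercept",
         bases = list(), rows = 1:n, spec = model_spec(fam),
         data = data.frame(i = 1:n)),
    class = "design_matrix")

  # correctly specified NB fit: randomized PIT is uniform
  y_nb <- stats::rnbinom(n, size = 3, mu = 12)
  fit_nb <- fit_glm(make_design(y_nb, "negbin"), "negbin")
  p_ok <- pit(fit_nb, n_bins = 10, seed = 1)
  expect_equal(mean(p_ok$heights), 1, tolerance = 1e-10)
  expect_true(all(p_ok$u >= 0 & p_ok$u <= 1))
  ks <- stats::ks.test(p_ok$u, "punif")
  expect_gt(ks$p.value, 0.01)

  # Poisson fit on the same NB data: extreme bins overloaded
  fit_p <- fit_glm(make_design(y_nb, "poisson"), "poisson")
  p_bad <- pit(fit_p, n_bins = 10, seed = 1)
  expect_gt(p_bad$heights[1], 1.3)
  expect_gt(p_bad$heights[10], 1.3)

  # histogram always integrates to one
  expect_equal(sum(p_bad$heights) / 10, 1, tolerance = 1e-12)
})

test_that("randomized PIT reduces to the lower CDF bound when v = 0", {
  set.seed(36)
  n <- 50
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  y <- stats::rpois(n, 5)
  d <- structure(
    list(y = y, X = X, offset = rep(0, n), groups = "intercept",
         bases = list(), rows = 1:n, spec = model_spec("poisson"),
         data = data.frame(i = 1:n)),
    class = "design_matrix")
  fit <- fit_glm(d, "poisson")
  p <- pit(fit, seed = 4)
  lo <- ifelse(y > 0, stats::ppois(y - 1, fit$mu), 0)
  hi <- stats::ppois(y, fit$mu)
  expect_true(all(p$u >= lo - 1e-12 & p$u <= hi + 1e-12))
  # same seed reproduces the randomization
  expect_identical(p$u, pit(fit, seed = 4)$u)
})

test_that("lag-smoothed rate curves equal hand-computed group means", {
  ser <- toy_series(6)
  ser$tmin_c <- c(10, 20, 10, 20, 10, 20)
  ser$tmax_c <- ser$tmin_c + 4
  ser$calls <- c(2L, 4L, 6L, 8L, 10L, 12L)
  ser$subscribers <- rep(10000, 6)
  sc <- smoothed_rate_curve(ser, "tmin", lag = 0)
  expect_equal(sc$value, c(10, 20))
  expect_equal(sc$mean_rate, c(mean(c(2, 6, 10)), mean(c(4, 8, 12))))

  # constant rate: flat curve at that constant for any lag
  ser2 <- toy_series(15)
  ser2$calls <- rep(5L, 15)
  sc2 <- smoothed_rate_curve(ser2, "trange", lag = 3)
  expect_true(all(abs(sc2$mean_rate - 2.5) < 1e-12))

  # shift equivariance: lag 0 vs lag 1 on a shifted copy
  ser3 <- toy_series(30)
  base <- smoothed_rate_curve(ser3, "tmin", lag = 1)
  shifted <- daily_series(ser3$date[-1], ser3$calls[-1],
                          ser3$subscribers[-1], ser3$tmin_c[-30],
                          ser3$tmax_c[-30] , ser3$humidity_pct[-30])
  # variable at day t-1 paired with rate at day t == lag-0 on shifted copy
  sc3 <- smoothed_rate_curve(shifted, "tmin", lag = 0)
  expect_equal(sc3$mean_rate, base$mean_rate, tolerance = 1e-12)

  expect_error(smoothed_rate_curve(ser, "tmin", lag = 6), "lag")
})
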