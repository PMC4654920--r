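# One moderate fitted model shared across the effect tests.
effects_fit <- local({
  d <- recovery_design(seed = 601)
  simulate_on_design(d, recovery_beta(d), phi = c(0.1, 0.05),
                     ar_lags = c(1, 5), family = "negbin", theta = 30,
                     seed = 602)
})

test_that("percent-change transforms are mutual inverses", {
  for (s in c(-0.2, -0.01, 0, 0.0303, 0.5)) {
    expect_equal(log_slope(percent_change(s)), s, tolerance = 1e-12)
  }
  for (p in c(-15, -2.24, 0, 2.24, 9.34)) {
    expect_equal(percent_change(log_slope(p)), p, tolerance = 1e-12)
  }
  # the study's printed conversions
  expect_equal(percent_change(0.089304), 9.34, tolerance = 0.005)
  expect_equal(percent_change(log(1.0224)), 2.24, tolerance = 1e-9)
})

test_that("effect curves are centered with bands that contain the estimate", {
  fit <- fit_glarma(effects_fit, c(1, 5), "negbin")
  cv <- effect_curve(fit, "avgtem")
  expect_equal(mean(cv$curve$g), 0, tolerance = 1e-10)
  expect_true(all(cv$curve$lo <= cv$curve$g & cv$curve$g <= cv$curve$hi))
  expect_false(any(cv$curve$extrapolated))
  expect_error(effect_curve(fit, "avghum"), "not in the fitted model")
})

test_that("a degree-1 block gives a straight line consistent with the average effect", {
  d <- effects_fit
  fit <- fit_glm(d, "poisson")
  cv <- effect_curve(fit, "avgrng")
  # straight line: second differences vanish
  expect_lt(max(abs(diff(diff(cv$curve$g)))), 1e-10)
  slope <- diff(range(cv$curve$g)) / diff(range(cv$curve$x))
  ae <- average_unit_effect(fit, "avgrng",
                            range(d$data$avgrng) + c(0.1, -0.1))
  expect_equal(ae$percent, percent_change(sign(diff(cv$curve$g[1:2])) *
                                            slope), tolerance = 1e-8)

  # interval independence for the linear block (exact)
  ae2 <- average_unit_effect(fit, "avgrng",
                             quantile(d$data$avgrng, c(0.3, 0.6)))
  expect_equal(ae$percent, ae2$percent, tolerance = 1e-10)
  expect_equal(ae$se, ae2$se, tolerance = 1e-10)
})

test_that("a zero coefficient block yields a flat curve and a 0% effect", {
  fit <- fit_glm(effects_fit, "poisson")
  fit$beta[fit$groups == "avgtem"] <- 0
  cv <- effect_curve(fit, "avgtem")
  expect_true(all(abs(cv$curve$g) < 1e-12))
  expect_equal(cv$curve$hi, -cv$curve$lo, tolerance = 1e-10)
  ae <- average_unit_effect(fit, "avgtem", c(15, 20))
  expect_equal(ae$percent, 0, tolerance = 1e-10)
  expect_lt(ae$ci[1], 0)
  expect_gt(ae$ci[2], 0)
})

test_that("the percent formula inverts a known slope exactly", {
  # a slope of log(1.0224) per unit must report 2.24% per unit
  fit <- fit_glm(effects_fit, "poisson")
  idx <- which(fit$groups == "avgrng")
  b <- effects_fit$bases$avgrng
  col_slope <- diff(as.numeric(eval_poly_basis(b, c(0, 1))))
  fit$beta[idx] <- log(1.0224) / col_slope
  ae <- average_unit_effect(fit, "avgrng",
                            range(effects_fit$data$avgrng) + c(0.05, -0.05))
  expect_equal(ae$percent, 2.24, tolerance = 1e-8)
})

test_that("effect-curve bands achieve near-nominal pointwise coverage", {
  # independence Poisson fits; true curve known on the orthonormal basis
  set.seed(61)
  n <- 400
  x <- stats::runif(n, 10, 30)
  b <- stats::poly(x, 2)
  beta_true <- c(2.5, 1.0, 0.8)
  X <- cbind(`(Intercept)` = 1, avgtem.1 = b[, 1], avgtem.2 = b[, 2])
  grid_x <- seq(12, 28, length.out = 5)
  covered <- matrix(NA, 100, 5)
  basis <- fit_poly_basis(x, 2)
  Bg <- eval_poly_basis(basis, grid_x)
  g_true <- as.numeric(Bg %*% beta_true[2:3])
  g_true <- g_true - mean(g_true)
  for (r in 1:100) {
    y <- stats::rpois(n, exp(as.numeric(X %*% beta_true)))
    d <- structure(
      list(y = y, X = X, offset = rep(0, n),
           groups = c("intercept", "avgtem", "avgtem"),
           bases = list(avgtem = basis), rows = 1:n,
           spec = model_spec("poisson"), data = data.frame(avgtem = x)),
      class = "design_matrix")
    cv <- effect_curve(fit_glm(d, "poisson"), "avgtem", grid = grid_x)
    covered[r, ] <- cv$curve$lo <= g_true & g_true <= cv$curve$hi
  }
  cover <- colMeans(covered)
  expect_true(all(cover >= 0.90 & cover <= 0.99))
})

test_that("group Wald test reduces to the squared z test for one column", {
  fit <- fit_glm(effects_fit, "poisson")
  idx <- which(fit$groups == "avgrng")
  expect_length(idx, 1L)
  z <- fit$beta[idx] / sqrt(diag(fit$cov_beta))[idx]
  wt <- wald_group_test(fit, "avgrng")
  expect_equal(wt$chisq, unname(z^2), tolerance = 1e-10)
  expect_equal(wt$df, 1L)
})

test_that("threshold scan logic: flat-zero and monotone curves return none", {
  fit <- fit_glm(effects_fit, "poisson")

  # globally flat zero temperature block
  flat <- fit
  flat$beta[flat$groups == "avgtem"] <- 0
  th <- find_cold_threshold(flat, method = "scan")
  expect_false(th$found)
  expect_false(th$monotone)
  expect_true(is.na(th$critical))

  # strictly monotone decline: strong negative loading on the linear column
  mono <- fit
  idx <- which(mono$groups == "avgtem")
  mono$beta[idx] <- 0
  b <- effects_fit$bases$avgtem
  lin_slope <- diff(as.numeric(eval_poly_basis(b, c(0, 1))[, 1]))
  mono$beta[idx[1]] <- -abs(log(1.06) / lin_slope)
  mono$cov_beta <- mono$cov_beta * 1e-4   # make it decisively significant
  th2 <- find_cold_threshold(mono, method = "scan")
  expect_false(th2$found)
  expect_true(th2$monotone)
})

test_that("profile threshold detection recovers a strong known kink", {
  # strong-signal synthetic: cold slope 8% below 15, flat above
  w <- simulate_weather(weather_params(), seed = 71)
  n <- nrow(w)
  ser0 <- daily_series(w$date, rep(0L, n), rep(30000, n), w$tmin_c,
                       w$tmax_c, w$humidity_pct)
  f <- engineer_features(ser0)
  vf <- attr(f, "valid_from")
  avgtem <- f$avgtem
  avgtem[1:6] <- cumsum(w$tmin_c[1:6]) / (1:6)
  eta <- log(30000 / 10000) + log(11) + log(1.08) * pmax(15 - avgtem, 0)
  y <- simulate_glarma(eta, family = "negbin", theta = 100, seed = 72)
  ser <- ser0
  ser$calls <- as.integer(y)
  f2 <- engineer_features(ser)
  spec <- model_spec("negbin", deg_tem = 5, deg_rng = 1, deg_time = 2,
                     include_weekday = TRUE, include_month = TRUE)
  d <- build_design(f2, spec)
  fit <- fit_glm(d, "negbin")
  th <- find_cold_threshold(fit, method = "profile")
  expect_true(th$found)
  expect_lte(abs(th$critical - 15), 1)
  expect_true(th$ci_excludes_zero)
})

test_that("report tables group coefficients and convert dummy percents", {
  fit <- fit_glarma(effects_fit, c(1, 5), "negbin")
  tab <- coefficient_table(fit)
  expect_equal(sum(tab$group == "avgtem"), 2L)
  expect_equal(sum(tab$group == "weekday"), 6L)
  expect_equal(sum(tab$group == "ar"), 2L)
  expect_equal(sum(tab$group == "dispersion"), 1L)
  mon <- tab[tab$term == "weekdayMonday", ]
  expect_equal(mon$percent, percent_change(mon$estimate))

  rep_ <- report(fit, curves = list(avgtem = effect_curve(fit, "avgtem")),
                 threshold = NULL, decisions = list())
  expect_false("month" %in% rep_$group_tests$group)  # month not in model
  dir <- withr::local_tempdir()
  write_report(rep_, dir)
  expect_true(file.exists(file.path(dir, "coefficients.json")))
  expect_true(file.exists(file.path(dir, "effects_avgtem.csv")))
  expect_true(file.exists(file.path(dir, "report.md")))
})
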