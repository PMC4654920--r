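test_that("with phi = 0 the GLARMA likelihood equals the GLM likelihood", {
  d <- toy_design(n = 60, p = 2, seed = 21)
  glm_fit_ <- fit_glm(d, "poisson")
  gl <- glarma_loglik(glm_fit_$beta, phi = c(0, 0), design = d,
                      ar_lags = c(1, 5), family = "poisson")
  expect_equal(gl$loglik, glm_fit_$loglik, tolerance = 1e-10)
  expect_equal(gl$mu, glm_fit_$mu, tolerance = 1e-10)
})

test_that("a length-5 series matches the hand-unrolled recursion", {
  X <- matrix(1, 5, 1, dimnames = list(NULL, "(Intercept)"))
  y <- c(2L, 0L, 3L, 1L, 4L)
  d <- structure(
    list(y = y, X = X, offset = rep(0.1, 5), groups = "intercept",
         bases = list(), rows = 1:5, spec = model_spec("poisson"),
         data = data.frame(row = 1:5)),
    class = "design_matrix"
  )
  beta <- 0.7; phi <- 0.3
  # hand forward pass, lag 1: W1 = .8; e_t = (y - e^W)/sqrt(e^W)
  W <- e <- mu <- numeric(5)
  for (t in 1:5) {
    W[t] <- 0.7 + 0.1 + if (t > 1) phi * e[t - 1] else 0
    mu[t] <- exp(W[t])
    e[t] <- (y[t] - mu[t]) / sqrt(mu[t])
  }
  expected <- sum(stats::dpois(y, mu, log = TRUE))
  got <- glarma_loglik(beta, phi, d, ar_lags = 1L, family = "poisson")
  expect_equal(got$loglik, expected, tolerance = 1e-12)
  expect_equal(got$e, e, tolerance = 1e-12)
  expect_equal(got$W, W, tolerance = 1e-12)
})

test_that("likelihood agrees with a naive reimplementation on random instances", {
  set.seed(22)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    p <- sample(1:3, 1)
    d <- toy_design(n = n, p = p, seed = 1000 + i)
    lags <- sort(sample(1:6, sample(1:3, 1)))
    phi <- stats::runif(length(lags), -0.15, 0.15)
    beta <- stats::rnorm(p + 1, c(1, rep(0, p)), 0.2)
    fam <- if (i %% 2 == 0) "negbin" else "poisson"
    theta <- if (fam == "negbin") stats::runif(1, 2, 50) else NULL
    mine <- glarma_loglik(beta, phi, d, lags, fam, theta = theta)$loglik
    oracle <- naive_glarma_loglik(beta, phi, d, lags, fam, theta = theta)
    expect_equal(mine, oracle, tolerance = 1e-10)
  }
})

test_that("negative binomial with huge theta matches the Poisson likelihood", {
  d <- toy_design(n = 50, p = 2, seed = 23)
  beta <- c(1, 0.1, -0.1)
  phi <- 0.1
  ll_nb <- glarma_loglik(beta, phi, d, 1L, "negbin", theta = 1e8)$loglik
  ll_p <- glarma_loglik(beta, phi, d, 1L, "poisson")$loglik
  expect_lt(abs(ll_nb - ll_p), 1e-4)
})

test_that("the analytic score vanishes at the fitted optimum", {
  d <- recovery_design(seed = 301)
  d <- simulate_on_design(d, recovery_beta(d), phi = c(0.15, 0.10),
                          ar_lags = c(1, 5), family = "negbin",
                          theta = 30, seed = 302)
  fit <- fit_glarma(d, c(1, 5), "negbin")
  expect_true(fit$converged)
  pars <- c(fit$beta, fit$phi, log(fit$theta))
  g <- coldcalls:::glarma_forward(pars, d, c(1L, 5L), "negbin",
                                  want_grad = TRUE)$grad
  expect_lt(max(abs(g)), 1e-2)
  # GLARMA nests the GLM: likelihood can only improve
  expect_gte(fit$loglik, fit_glm(d, "negbin")$loglik - 1e-8)
  # covariance is symmetric positive semidefinite
  ev <- eigen(fit$cov_params, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
})

test_that("parameters are recovered within 3 SE on simulated data", {
  d <- recovery_design(seed = 303)
  beta_true <- recovery_beta(d)
  d <- simulate_on_design(d, beta_true, phi = c(0.15, 0.10),
                          ar_lags = c(1, 5), family = "negbin",
                          theta = 30, seed = 304)
  fit <- fit_glarma(d, c(1, 5), "negbin")
  z <- c((fit$beta - beta_true) / fit$se_beta,
         (fit$phi - c(0.15, 0.10)) / fit$se_phi,
         (log(fit$theta) - log(30)) / fit$se_log_theta)
  expect_true(all(abs(z) < 3))
  # residuals from the correctly specified fit look like white noise
  a <- acf_series(fit$e, 30)
  n_out <- sum(abs(a$r) > 1.96 / sqrt(attr(a, "n")))
  expect_lte(n_out, ceiling(0.05 * 30) + 1)
})

test_that("fitting data generated without feedback gives phi near zero", {
  d <- recovery_design(seed = 305)
  beta_true <- recovery_beta(d)
  d <- simulate_on_design(d, beta_true, phi = c(0, 0),
                          ar_lags = c(1, 5), family = "negbin",
                          theta = 30, seed = 306)
  fit <- fit_glarma(d, c(1, 5), "negbin")
  expect_true(all(abs(fit$phi / fit$se_phi) < 3))
})

test_that("simulation is deterministic given the seed and has the right moments", {
  eta <- rep(log(20), 5000)
  y1 <- simulate_glarma(eta, seed = 9)
  y2 <- simulate_glarma(eta, seed = 9)
  expect_identical(as.integer(y1), as.integer(y2))

  # phi = 0 Poisson: variance/mean ratio near 1
  expect_lt(abs(stats::var(as.numeric(y1)) / mean(y1) - 1), 0.1)

  # phi = 0 NB theta = 2 at constant mu: variance near mu + mu^2/2
  y3 <- simulate_glarma(eta, family = "negbin", theta = 2, seed = 10)
  mu <- 20
  expect_lt(abs(stats::var(as.numeric(y3)) / (mu + mu^2 / 2) - 1), 0.15)

  # different seeds differ
  expect_false(identical(as.integer(y1),
                         as.integer(simulate_glarma(eta, seed = 11))))
})

test_that("simulating with feedback induces serial correlation in counts", {
  eta <- rep(log(15), 3000)
  y <- simulate_glarma(eta, phi = 0.2, ar_lags = 1L, seed = 12)
  r1 <- stats::acf(as.numeric(y), lag.max = 1, plot = FALSE)$acf[2]
  expect_gt(r1, 0.3)
})

test_that("degenerate requests fail loudly", {
  d <- toy_design(n = 30, p = 1, seed = 24)
  expect_error(fit_glarma(d, integer(0)), "non-empty")
  expect_error(fit_glarma(d, c(2, 2)), "distinct")
  expect_error(glarma_loglik(c(1, 0), 0.1, d, 1L, "negbin", theta = -1),
               "theta > 0")
  expect_error(simulate_glarma(rep(100, 10), seed = 1), "overflow")
  expect_error(simulate_glarma(rep(1, 10)), "seed")
})
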