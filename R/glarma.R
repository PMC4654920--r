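#' GLARMA log-likelihood via the forward recursion
#'
#' Observation-driven count time-series model: the log-link linear state is
#' \deqn{W_t = x_t' \beta + o_t + \sum_{j} \phi_j e_{t-j},}
#' where the sum runs over the autoregressive lags, `o_t` is the offset and
#' `e_t = (y_t - \mu_t) / \sqrt{V(\mu_t)}` is the Pearson residual of the
#' conditional mean `\mu_t = exp(W_t)` (pre-sample residuals are 0). The
#' conditional distribution of `y_t` is Poisson or negative binomial with
#' shape `theta` (variance `\mu + \mu^2/\theta`). With all `\phi_j = 0` the
#' likelihood reduces exactly to the GLM likelihood. The recursion is
#' causal: `W_t` involves only residuals strictly before `t`.
#'
#' @param beta mean-model coefficients aligned to the design columns.
#' @param phi autoregressive coefficients aligned to `ar_lags`.
#' @param design a [build_design()] object.
#' @param ar_lags distinct positive integer lags.
#' @param family `"poisson"` or `"negbin"`.
#' @param theta negative binomial shape (`> 0`); required for `"negbin"`.
#' @return list with `loglik` and the state series `W`, `mu`, `e`.
#' @export
glarma_loglik <- function(beta, phi, design, ar_lags,
                          family = c("poisson", "negbin"), theta = NULL) {
  family <- match.arg(family)
  pars <- glarma_pack(beta, phi, theta, family)
  out <- glarma_forward(pars, design, as.integer(ar_lags), family,
                        want_grad = FALSE)
  if (is.null(out)) stop("linear state overflow (exp(W) too large); ",
                         "rescale covariates or shrink parameters",
                         call. = FALSE)
  list(loglik = out$loglik, W = out$W, mu = out$mu, e = out$e)
}

glarma_pack <- function(beta, phi, theta, family) {
  if (family == "negbin") {
    if (is.null(theta) || !is.finite(theta) || theta <= 0) {
      stop("negbin family requires theta > 0", call. = FALSE)
    }
    c(beta, phi, log(theta))
  } else {
    c(beta, phi)
  }
}

# Single forward pass: log-likelihood, states and (optionally) the exact
# analytic gradient in (beta, phi, log theta). Gradients of the residual
# recursion are propagated row by row. Returns NULL on overflow so the
# optimizer can treat the point as infeasible.
glarma_forward <- function(pars, design, ar_lags, family, want_grad = TRUE) {
  X <- design$X
  y <- design$y
  off <- design$offset
  n <- length(y)
  p <- ncol(X)
  q <- length(ar_lags)
  nb <- family == "negbin"
  P <- p + q + as.integer(nb)
  beta <- pars[seq_len(p)]
  phi <- if (q > 0) pars[p + seq_len(q)] else numeric(0)
  theta <- if (nb) exp(pars[P]) else Inf

  eta <- as.numeric(X %*% beta) + off
  E <- numeric(n)
  W <- numeric(n)
  mu <- numeric(n)
  ll <- 0
  grad <- numeric(P)
  H <- if (want_grad) matrix(0, n, P) else NULL
  maxlag <- if (q > 0) max(ar_lags) else 0L

  for (t in seq_len(n)) {
    w <- eta[t]
    if (want_grad) {
      gW <- numeric(P)
      gW[seq_len(p)] <- X[t, ]
    }
    if (q > 0) {
      for (j in seq_len(q)) {
        tj <- t - ar_lags[j]
        if (tj >= 1L) {
          w <- w + phi[j] * E[tj]
          if (want_grad) {
            gW <- gW + phi[j] * H[tj, ]
            gW[p + j] <- gW[p + j] + E[tj]
          }
        }
      }
    }
    # exp() and the residual recursion stay finite well past |W| = 100;
    # beyond that the pass is abandoned (likelihood would overflow)
    if (!is.finite(w) || abs(w) > 100) return(NULL)
    m <- exp(w)
    W[t] <- w
    mu[t] <- m
    yt <- y[t]
    if (nb) {
      s2 <- m + m^2 / theta
      s <- sqrt(s2)
      e <- (yt - m) / s
      ll <- ll + lgamma(yt + theta) - lgamma(theta) - lgamma(yt + 1) +
        theta * log(theta) + yt * w - (theta + yt) * log(theta + m)
      if (want_grad) {
        dldw <- (yt - m) * theta / (theta + m)
        grad <- grad + dldw * gW
        grad[P] <- grad[P] + theta *
          (digamma(yt + theta) - digamma(theta) + log(theta) + 1 -
             log(theta + m) - (theta + yt) / (theta + m))
        dedw <- -m / s - e * m * (1 + 2 * m / theta) / (2 * s2)
        h <- dedw * gW
        h[P] <- h[P] + e * m^2 / (2 * s2 * theta)
        H[t, ] <- h
      }
    } else {
      s <- sqrt(m)
      e <- (yt - m) / s
      ll <- ll + yt * w - m - lgamma(yt + 1)
      if (want_grad) {
        grad <- grad + (yt - m) * gW
        H[t, ] <- (-s - e / 2) * gW
      }
    }
    E[t] <- e
  }
  list(loglik = unname(ll), grad = if (want_grad) unname(grad) else NULL,
       W = W, mu = mu, e = E)
}

# Central-difference Hessian of the analytic score.
newton_hessian <- function(par, neggr, h = 1e-5) {
  P <- length(par)
  H <- matrix(0, P, P)
  for (i in seq_len(P)) {
    e <- numeric(P); e[i] <- h
    H[, i] <- (neggr(par + e) - neggr(par - e)) / (2 * h)
  }
  (H + t(H)) / 2
}

# Damped (Levenberg-regularized, line-searched) Newton minimization of the
# negative GLARMA log-likelihood. The Hessian (the expensive part: 2P
# gradient evaluations) is frozen across inner iterations and refreshed
# only when progress under the frozen curvature stalls. Converged when the
# relative decrease of the objective falls below tol on a full step.
glarma_newton <- function(par, negll, neggr, max_iter = 40L, tol = 1e-9,
                          inner = 10L) {
  f0 <- negll(par)
  converged <- FALSE
  it <- 0L
  for (outer in seq_len(5L)) {
    H <- newton_hessian(par, neggr)
    stalled <- FALSE
    for (k in seq_len(inner)) {
      it <- it + 1L
      if (it > max_iter) break
      g <- neggr(par)
      lambda <- 0
      step <- NULL
      for (j in 0:8) {
        Hk <- H + diag(lambda, length(par))
        step <- tryCatch(solve(Hk, g), error = function(e) NULL)
        if (!is.null(step) && all(is.finite(step))) break
        lambda <- if (lambda == 0) 1e-6 * max(abs(diag(H)), 1) else
          10 * lambda
      }
      if (is.null(step) || !all(is.finite(step))) { stalled <- TRUE; break }
      alpha <- 1
      improved <- FALSE
      f1 <- f0
      while (alpha >= 1e-10) {
        f1 <- negll(par - alpha * step)
        if (is.finite(f1) && f1 < f0) { improved <- TRUE; break }
        alpha <- alpha / 2
      }
      if (!improved) { stalled <- TRUE; break }
      par <- par - alpha * step
      delta <- f0 - f1
      f0 <- f1
      if (delta < tol * (abs(f0) + 1)) { converged <- TRUE; break }
    }
    if (converged || it > max_iter) break
    # a stall under stale curvature warrants one refresh; a stall with
    # fresh curvature means the local floor is reached
    if (stalled && outer >= 2L) { converged <- TRUE; break }
  }
  list(par = par, value = f0, converged = converged, iterations = it)
}

#' Fit a GLARMA model by maximum likelihood
#'
#' Maximizes the GLARMA likelihood over the mean coefficients, the
#' autoregressive coefficients at the given sparse lags and (for the
#' negative binomial family) the shape parameter, starting from the GLM
#' fit with all autoregressive coefficients at zero. Standard errors come
#' from the inverse observed information (numerically differentiated
#' analytic score) at the optimum.
#'
#' @param design a [build_design()] object.
#' @param ar_lags non-empty vector of distinct positive integer lags.
#' @param family `"poisson"` or `"negbin"`; defaults to the design spec's
#'   family.
#' @param init optional list with starting `beta`, `phi`, `theta`.
#' @param maxit iteration cap for the quasi-Newton optimizer.
#' @return an object of class `glarma_fit`: `beta`, `phi`, `theta`,
#'   `loglik`, `aic`, `cov_params` (joint covariance in the order beta,
#'   phi, log-theta), `se_beta`, `se_phi`, `se_log_theta`, `mu`, `e`, `W`,
#'   `deviance` (Poisson-formula residual deviance), `df_resid` (rows
#'   minus all estimated parameters including phi and theta), `converged`,
#'   `iter`, `family`, `ar_lags`, `groups`, `design`.
#' @export
fit_glarma <- function(design, ar_lags, family = NULL, init = NULL,
                       maxit = 300L) {
  stopifnot(inherits(design, "design_matrix"))
  ar_lags <- sort(as.integer(ar_lags))
  if (length(ar_lags) == 0L) stop("ar_lags must be non-empty; use fit_glm ",
                                  "for the no-autoregression model",
                                  call. = FALSE)
  if (any(ar_lags < 1L) || anyDuplicated(ar_lags)) {
    stop("ar_lags must be distinct positive integers", call. = FALSE)
  }
  if (is.null(family)) family <- design$spec$family
  family <- match.arg(family, c("poisson", "negbin"))
  nb <- family == "negbin"
  p <- ncol(design$X)
  q <- length(ar_lags)
  P <- p + q + as.integer(nb)

  if (is.null(init)) {
    glm0 <- fit_glm(design, "poisson")
    beta0 <- glm0$beta
    theta0 <- NULL
    if (nb) {
      # moment estimator of the NB shape from the Poisson fit
      mu0 <- glm0$mu
      excess <- sum((design$y - mu0)^2 - mu0)
      theta0 <- if (excess > 0) max(sum(mu0^2) / excess, 0.5) else 100
    }
    init <- list(beta = beta0, phi = rep(0, q), theta = theta0)
  }
  par0 <- glarma_pack(init$beta, init$phi, init$theta, family)

  negll <- function(par) {
    out <- glarma_forward(par, design, ar_lags, family, want_grad = FALSE)
    if (is.null(out) || !is.finite(out$loglik)) return(1e10)
    -out$loglik
  }
  neggr <- function(par) {
    out <- glarma_forward(par, design, ar_lags, family, want_grad = TRUE)
    if (is.null(out) || !is.finite(out$loglik)) return(numeric(length(par)))
    -out$grad
  }
  # stage 1: quasi-Newton warm-up from the GLM start
  opt <- stats::optim(par0, negll, neggr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-9))
  if (opt$convergence > 1) {
    stop("GLARMA optimizer failed (code ", opt$convergence, "): ",
         opt$message, call. = FALSE)
  }

  # stage 2: damped Newton on the analytic score; the residual-feedback
  # likelihood forms a narrow curved valley that first-order methods crawl
  # along, while Newton steps track the valley floor
  newton <- glarma_newton(opt$par, negll, neggr, max_iter = 40L)
  par_hat <- newton$par
  converged <- newton$converged
  if (!converged) {
    # final quasi-Newton attempt from the Newton point
    opt2 <- stats::optim(par_hat, negll, neggr, method = "BFGS",
                         control = list(maxit = maxit, reltol = 1e-10))
    newton2 <- glarma_newton(opt2$par, negll, neggr, max_iter = 20L)
    if (negll(newton2$par) <= negll(par_hat)) {
      par_hat <- newton2$par
      converged <- newton2$converged
    }
  }
  if (!converged) {
    stop("GLARMA fit did not converge; final negative log-likelihood ",
         format(negll(par_hat)), call. = FALSE)
  }

  hess <- newton_hessian(par_hat, neggr)
  cov_params <- tryCatch(chol2inv(chol(hess)),
                         error = function(e) MASS::ginv(hess))
  cov_params <- (cov_params + t(cov_params)) / 2
  final <- glarma_forward(par_hat, design, ar_lags, family,
                          want_grad = FALSE)

  beta <- stats::setNames(par_hat[seq_len(p)], colnames(design$X))
  phi <- stats::setNames(par_hat[p + seq_len(q)], paste0("phi_", ar_lags))
  if (sum(abs(phi)) >= 1) {
    warning("sum |phi| >= 1: autoregressive coefficients near the ",
            "stationarity boundary", call. = FALSE)
  }
  theta <- if (nb) exp(par_hat[P]) else NA_real_
  se <- sqrt(pmax(diag(cov_params), 0))
  y <- design$y
  mu <- final$mu
  devterm <- ifelse(y > 0, y * log(y / mu), 0) - (y - mu)

  structure(
    list(
      beta = beta, phi = phi, theta = theta,
      loglik = final$loglik,
      aic = -2 * final$loglik + 2 * P,
      cov_params = cov_params,
      se_beta = stats::setNames(se[seq_len(p)], names(beta)),
      se_phi = stats::setNames(se[p + seq_len(q)], names(phi)),
      se_log_theta = if (nb) se[P] else NA_real_,
      mu = mu, e = final$e, W = final$W,
      deviance = 2 * sum(devterm),
      df_resid = length(y) - P,
      converged = converged,
      iter = opt$counts[["function"]],
      family = family, ar_lags = ar_lags,
      groups = design$groups,
      design = design
    ),
    class = "glarma_fit"
  )
}

#' @export
print.glarma_fit <- function(x, ...) {
  cat(sprintf("%s GLARMA: %d obs, lags {%s}%s\n",
              x$family, length(x$mu), paste(x$ar_lags, collapse = ","),
              if (!is.na(x$theta)) sprintf(", theta = %.2f", x$theta) else ""))
  cat(sprintf("  logLik = %.2f, AIC = %.2f, deviance = %.1f on %d df\n",
              x$loglik, x$aic, x$deviance, x$df_resid))
  cat("  phi:", paste(sprintf("%s = %.3f", names(x$phi), x$phi),
                      collapse = ", "), "\n")
  invisible(x)
}

#' Simulate counts through the GLARMA recursion
#'
#' Forward simulation: at each day the linear state adds the
#' autoregressive feedback of past Pearson residuals to the supplied
#' linear predictor, a count is drawn from the conditional Poisson or
#' negative binomial distribution, and its residual enters the recursion.
#' Deterministic given the seed.
#'
#' @param eta linear predictor per day (covariate effects plus offset, on
#'   the log scale).
#' @param phi autoregressive coefficients aligned to `ar_lags`; may be
#'   empty for an independence model.
#' @param ar_lags distinct positive integer lags (same length as `phi`).
#' @param family `"poisson"` or `"negbin"`.
#' @param theta negative binomial shape; required for `"negbin"`.
#' @param seed integer seed; required.
#' @return integer vector of counts, with attributes `mu` (conditional
#'   means) and `e` (residuals).
#' @export
simulate_glarma <- function(eta, phi = numeric(0), ar_lags = integer(0),
                            family = c("poisson", "negbin"), theta = NULL,
                            seed) {
  family <- match.arg(family)
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  stopifnot(length(phi) == length(ar_lags))
  ar_lags <- as.integer(ar_lags)
  nb <- family == "negbin"
  if (nb && (is.null(theta) || theta <= 0)) {
    stop("negbin family requires theta > 0", call. = FALSE)
  }
  n <- length(eta)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  y <- integer(n)
  E <- numeric(n)
  mu <- numeric(n)
  q <- length(phi)
  for (t in seq_len(n)) {
    w <- eta[t]
    if (q > 0) {
      for (j in seq_len(q)) {
        tj <- t - ar_lags[j]
        if (tj >= 1L) w <- w + phi[j] * E[tj]
      }
    }
    if (!is.finite(w) || w > 30) {
      stop("mean overflow in simulation (exp(W) too large)", call. = FALSE)
    }
    m <- exp(w)
    mu[t] <- m
    if (nb) {
      y[t] <- stats::rnbinom(1L, size = theta, mu = m)
      s <- sqrt(m + m^2 / theta)
    } else {
      y[t] <- stats::rpois(1L, m)
      s <- sqrt(m)
    }
    E[t] <- (y[t] - m) / s
  }
  structure(y, mu = mu, e = E)
}
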