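#' Fit a log-link count GLM to a design matrix
#'
#' Maximum-likelihood Poisson or negative binomial regression with log link
#' and the design's offset. This is the pipeline's first-pass fitter and
#' the no-autoregression special case of the GLARMA model.
#'
#' @param design a [build_design()] object.
#' @param family `"poisson"` or `"negbin"`; defaults to the design spec's
#'   family.
#' @return an object of class `glm_fit`: list with `beta` (named
#'   coefficients aligned to design columns), `theta` (NB shape, `NA` for
#'   Poisson), `loglik`, `aic`, `deviance` (family deviance), `df_resid`
#'   (rows minus mean parameters), `mu` (fitted means), `pearson_resid`,
#'   `cov_beta`, `converged`, `iter`, plus the `design`, `groups` and
#'   `family`.
#' @export
fit_glm <- function(design, family = NULL) {
  stopifnot(inherits(design, "design_matrix"))
  if (is.null(family)) family <- design$spec$family
  family <- match.arg(family, c("poisson", "negbin"))
  y <- design$y
  X <- design$X
  off <- design$offset
  if (any(y < 0) || any(y != round(y))) {
    stop("response must be non-negative integers", call. = FALSE)
  }

  if (family == "poisson") {
    fit <- suppressWarnings(
      stats::glm.fit(x = X, y = y, offset = off, family = stats::poisson(),
                     control = stats::glm.control(epsilon = 1e-10,
                                                  maxit = 100))
    )
    if (!fit$converged) stop("Poisson GLM did not converge", call. = FALSE)
    beta <- fit$coefficients
    mu <- fit$fitted.values
    ll <- sum(stats::dpois(y, mu, log = TRUE))
    npar <- ncol(X)
    theta <- NA_real_
    dev <- fit$deviance
    # expected information for the Poisson log link: X' diag(mu) X
    cov_beta <- chol2inv(chol(crossprod(X, X * mu)))
    iter <- fit$iter
    vfun <- mu
  } else {
    df <- data.frame(.y = y)
    fit <- suppressWarnings(
      MASS::glm.nb(.y ~ X - 1 + offset(off), data = df,
                   control = stats::glm.control(epsilon = 1e-10,
                                                maxit = 100))
    )
    if (!fit$converged) stop("negative binomial GLM did not converge",
                             call. = FALSE)
    beta <- stats::coef(fit)
    names(beta) <- colnames(X)
    mu <- fit$fitted.values
    theta <- fit$theta
    ll <- as.numeric(stats::logLik(fit))
    npar <- ncol(X) + 1L
    dev <- fit$deviance
    cov_beta <- stats::vcov(fit)
    dimnames(cov_beta) <- list(colnames(X), colnames(X))
    iter <- fit$iter
    vfun <- mu + mu^2 / theta
  }

  structure(
    list(
      beta = stats::setNames(as.numeric(beta), colnames(X)),
      theta = theta,
      loglik = ll,
      aic = -2 * ll + 2 * npar,
      deviance = dev,
      df_resid = length(y) - ncol(X),
      mu = as.numeric(mu),
      pearson_resid = as.numeric((y - mu) / sqrt(vfun)),
      cov_beta = cov_beta,
      converged = TRUE,
      iter = iter,
      family = family,
      groups = design$groups,
      design = design
    ),
    class = "glm_fit"
  )
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("%s GLM: %d obs, %d mean parameters%s\n",
              x$family, length(x$mu), length(x$beta),
              if (!is.na(x$theta)) sprintf(", theta = %.3f", x$theta) else ""))
  cat(sprintf("  logLik = %.2f, AIC = %.2f, deviance = %.1f on %d df\n",
              x$loglik, x$aic, x$deviance, x$df_resid))
  invisible(x)
}

#' Poisson deviance statistic of a fitted count model
#'
#' Computes the Poisson residual deviance `2 * sum(y log(y / mu) - (y -
#' mu))` (with `0 log 0 = 0`) of the fitted means against the observed
#' counts, the residual degrees of freedom, and their ratio — the
#' overdispersion diagnostic.
#'
#' @param fit a `glm_fit` or `glarma_fit`.
#' @return list with `deviance`, `df_resid`, `ratio`.
#' @export
deviance_stat <- function(fit) {
  y <- fit$design$y
  mu <- fit$mu
  if (fit$df_resid <= 0) stop("non-positive residual degrees of freedom",
                              call. = FALSE)
  term <- ifelse(y > 0, y * log(y / mu), 0) - (y - mu)
  dev <- 2 * sum(term)
  list(deviance = dev, df_resid = fit$df_resid,
       ratio = dev / fit$df_resid)
}
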