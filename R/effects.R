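#' Percent-change transforms of log-scale slopes
#'
#' `percent_change(s)` converts a log-scale slope into the percent change
#' in the expected rate per unit, `(e^s - 1) * 100`; `log_slope(p)` is its
#' inverse `log(1 + p/100)`.
#'
#' @param s log-scale slope.
#' @param p percent change.
#' @return numeric.
#' @export
percent_change <- function(s) (exp(s) - 1) * 100

#' @rdname percent_change
#' @export
log_slope <- function(p) log(1 + p / 100)

beta_block_idx <- function(fit, variable) {
  idx <- which(fit$groups == variable)
  if (length(idx) == 0L) {
    stop("variable '", variable, "' is not in the fitted model",
         call. = FALSE)
  }
  idx
}

param_cov <- function(fit) {
  if (inherits(fit, "glarma_fit")) fit$cov_params else fit$cov_beta
}

#' Estimated effect curve of a fitted smooth term
#'
#' The centered contribution of one polynomial block to the log rate:
#' `g(x) = b(x)' beta_block`, centered to mean zero over the evaluation
#' grid, with pointwise 95% delta-method bands from the block covariance.
#'
#' @param fit a `glm_fit` or `glarma_fit`.
#' @param variable one of the fitted smooth terms (`"avgtem"`,
#'   `"avghum"`, `"avgrng"`, `"time"`).
#' @param grid evaluation points; default 101 points across the training
#'   range. Points outside the training range are flagged.
#' @param level confidence level for the bands (default 0.95).
#' @return an object of class `effect_curve`: data frame `curve` with
#'   columns `x`, `g`, `lo`, `hi`, `extrapolated`; plus `variable`,
#'   `center_constant` (the grid mean removed from the raw block
#'   contribution) and `level`.
#' @export
effect_curve <- function(fit, variable, grid = NULL, level = 0.95) {
  basis <- fit$design$bases[[variable]]
  if (is.null(basis)) {
    stop("variable '", variable, "' is not in the fitted model",
         call. = FALSE)
  }
  if (is.null(grid)) {
    grid <- seq(basis$range[1L], basis$range[2L], length.out = 101L)
  }
  idx <- beta_block_idx(fit, variable)
  B <- eval_poly_basis(basis, grid)
  extrapolated <- attr(B, "extrapolated")
  beta_block <- fit$beta[idx]
  Sigma <- param_cov(fit)[idx, idx, drop = FALSE]

  g_raw <- as.numeric(B %*% beta_block)
  centering <- mean(g_raw)
  g <- g_raw - centering
  Bc <- sweep(B, 2L, colMeans(B))      # centered contrast rows
  se <- sqrt(pmax(rowSums((Bc %*% Sigma) * Bc), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)

  structure(
    list(
      curve = data.frame(x = grid, g = g, lo = g - z * se, hi = g + z * se,
                         extrapolated = extrapolated),
      variable = variable,
      center_constant = centering,
      level = level
    ),
    class = "effect_curve"
  )
}

#' @export
print.effect_curve <- function(x, ...) {
  cat(sprintf("effect curve for %s on [%.2f, %.2f] (%d points, %.0f%% bands)\n",
              x$variable, min(x$curve$x), max(x$curve$x), nrow(x$curve),
              100 * x$level))
  invisible(x)
}

#' Average per-unit effect of a variable over an interval
#'
#' The secant slope of the estimated log-scale effect over `[a, b]`,
#' `s = (g(b) - g(a)) / (b - a)`, converted to the percent change in the
#' expected rate per one-unit change, with a delta-method confidence
#' interval from the basis-difference contrast. For a linear (degree-1)
#' block the result does not depend on the interval.
#'
#' @param fit a `glm_fit` or `glarma_fit`.
#' @param variable fitted smooth term name.
#' @param interval numeric `c(a, b)` with `a < b`, inside the training
#'   range.
#' @param direction `"increase"` (percent per +1 unit, default) or
#'   `"decrease"` (percent per -1 unit: the negated slope).
#' @param level confidence level (default 0.95).
#' @return an object of class `average_effect`: `percent`, `ci` (percent
#'   scale), `slope` (log scale, signed per `direction`), `se`,
#'   `interval`, `direction`, `level`.
#' @export
average_unit_effect <- function(fit, variable, interval,
                                direction = c("increase", "decrease"),
                                level = 0.95) {
  direction <- match.arg(direction)
  stopifnot(length(interval) == 2L)
  a <- interval[1L]; b <- interval[2L]
  if (!(a < b)) stop("interval must satisfy a < b", call. = FALSE)
  basis <- fit$design$bases[[variable]]
  if (is.null(basis)) {
    stop("variable '", variable, "' is not in the fitted model",
         call. = FALSE)
  }
  if (a < basis$range[1L] - 1e-8 || b > basis$range[2L] + 1e-8) {
    stop("interval [", a, ", ", b, "] outside the training range [",
         signif(basis$range[1L], 4), ", ", signif(basis$range[2L], 4), "]",
         call. = FALSE)
  }
  idx <- beta_block_idx(fit, variable)
  Bab <- eval_poly_basis(basis, c(a, b))
  contrast <- (Bab[2L, ] - Bab[1L, ]) / (b - a)
  s <- sum(contrast * fit$beta[idx])
  Sigma <- param_cov(fit)[idx, idx, drop = FALSE]
  se <- sqrt(max(as.numeric(contrast %*% Sigma %*% contrast), 0))
  if (direction == "decrease") s <- -s
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(
    list(
      percent = percent_change(s),
      ci = percent_change(c(s - z * se, s + z * se)),
      slope = s, se = se,
      interval = c(a, b), direction = direction, level = level,
      variable = variable
    ),
    class = "average_effect"
  )
}

#' @export
print.average_effect <- function(x, ...) {
  cat(sprintf(
    "%s: %+.2f%% per unit %s over [%.2f, %.2f] (%.0f%% CI [%.2f%%, %.2f%%])\n",
    x$variable, x$percent, x$direction, x$interval[1], x$interval[2],
    100 * x$level, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Detect a critical cold-temperature threshold
#'
#' Operationalizes the visual identification of a cold threshold on the
#' temperature effect curve. Two methods are available:
#'
#' `"profile"` (default): candidate thresholds `c` are scanned on a grid
#' of step `step`; for each, the fitted model's temperature block is
#' replaced by a segmented (hinge) term — log-linear decline toward cold
#' below `c`, flat mid-band, and a free warm rise above `c + flat_width` —
#' and the resulting Poisson GLM profile AIC is minimized over `c`. The
#' estimate is declared `found` when the cold hinge slope at the best `c`
#' is significantly positive (two-sided level `alpha`) and the supplied
#' fit's average effect over the mid-band `[c, c + flat_width]` has a
#' confidence interval containing zero (no residual trend above the
#' threshold). A strictly monotone effect fails the flat-band validation
#' and returns no threshold with the `monotone` flag set.
#'
#' `"scan"`: a curve-only criterion; the estimate is the smallest `c` such
#' that (i) the average per-degree-decrease effect on `[min, c]` is
#' positive with its confidence interval excluding zero and (ii) the
#' average effect on `[c, c + flat_width]` has a confidence interval
#' containing zero. Lower-powered, since (i) anchors at the sparse cold
#' extreme of the polynomial.
#'
#' Absence of a qualifying threshold is a valid result for both methods.
#'
#' @param fit a `glm_fit` or `glarma_fit` containing the temperature term.
#' @param variable smooth term to scan (default `"avgtem"`).
#' @param step scan step in degrees C (default 0.5).
#' @param alpha two-sided level for the significance conditions (default
#'   0.05).
#' @param flat_width width of the flat band above the candidate threshold,
#'   degrees C (default 9).
#' @param method `"profile"` or `"scan"`.
#' @param min_tail minimum number of days required below a candidate
#'   threshold (profile method), to keep the hinge identifiable.
#' @return an object of class `threshold_estimate`: `critical` (numeric,
#'   `NA` if none found), `found`, `monotone` (`TRUE` when a cold decline
#'   is detected but no flat band exists above it), `below_effect` (the
#'   supplied fit's average per-degree-decrease effect below the
#'   threshold, with CI), `ci_excludes_zero`, `scan` (per-candidate
#'   table), plus the criterion parameters.
#' @export
find_cold_threshold <- function(fit, variable = "avgtem", step = 0.5,
                                alpha = 0.05, flat_width = 9,
                                method = c("profile", "scan"),
                                min_tail = 15L) {
  method <- match.arg(method)
  basis <- fit$design$bases[[variable]]
  if (is.null(basis)) {
    stop("variable '", variable, "' is not in the fitted model",
         call. = FALSE)
  }
  lo <- basis$range[1L]
  hi <- basis$range[2L]
  level <- 1 - alpha

  flat_check <- function(cc) {
    flat_hi <- min(cc + flat_width, hi)
    if (flat_hi - cc < 2 * step) return(list(ok = NA, eff = NULL))
    eff <- average_unit_effect(fit, variable, c(cc, flat_hi),
                               direction = "increase", level = level)
    list(ok = eff$ci[1L] <= 0 && eff$ci[2L] >= 0, eff = eff)
  }

  if (method == "profile") {
    res <- threshold_profile(fit, variable, step, alpha, flat_width,
                             min_tail)
    scan <- res$scan
    c_best <- res$c_best
    cold_ok <- res$cold_ok
    fc <- flat_check(c_best)
    found <- isTRUE(cold_ok) && isTRUE(fc$ok)
    monotone <- isTRUE(cold_ok) && !isTRUE(fc$ok)
  } else {
    candidates <- seq(lo + step, hi - step, by = step)
    rows <- lapply(candidates, function(cc) {
      cold <- average_unit_effect(fit, variable, c(lo, cc),
                                  direction = "decrease", level = level)
      fc <- flat_check(cc)
      data.frame(
        c = cc,
        cold_pct = cold$percent, cold_lo = cold$ci[1L],
        cold_hi = cold$ci[2L], cold_ok = cold$ci[1L] > 0,
        flat_ok = fc$ok
      )
    })
    scan <- do.call(rbind, rows)
    qualifies <- scan$cold_ok & !is.na(scan$flat_ok) & scan$flat_ok
    found <- any(qualifies)
    monotone <- !found && any(scan$cold_ok)
    c_best <- if (found) min(scan$c[qualifies]) else NA_real_
  }

  below_effect <- NULL
  ci_excludes_zero <- NA
  if (is.finite(c_best) && c_best > lo + step) {
    below_effect <- average_unit_effect(fit, variable, c(lo, c_best),
                                        direction = "decrease",
                                        level = level)
    ci_excludes_zero <- below_effect$ci[1L] > 0
  }

  structure(
    list(
      critical = if (found) c_best else NA_real_,
      found = found,
      monotone = monotone,
      below_effect = below_effect,
      ci_excludes_zero = ci_excludes_zero,
      scan = scan,
      method = method,
      step = step, alpha = alpha, flat_width = flat_width,
      range = c(lo, hi), variable = variable
    ),
    class = "threshold_estimate"
  )
}

# Segmented-temperature profile: replace the fitted temperature block by
# {hinge below c, hinge above w} with a flat mid-band, and minimize the
# Poisson GLM AIC jointly over the cold knot c (scanned at `step`) and a
# free warm knot w (coarse grid), so warm-end misfit cannot contaminate
# the cold-knot profile. Returns the per-candidate table (profiled over
# w), the AIC-best c and whether its cold hinge slope is significantly
# positive.
threshold_profile <- function(fit, variable, step, alpha, flat_width,
                              min_tail) {
  design <- fit$design
  x <- design$data[[variable]]
  if (is.null(x)) stop("design does not carry the '", variable,
                       "' values", call. = FALSE)
  keep <- design$groups != variable
  X0 <- design$X[, keep, drop = FALSE]
  y <- design$y
  off <- design$offset
  if (inherits(fit, "glarma_fit")) {
    # absorb the fitted autoregressive feedback so serial noise does not
    # contaminate the knot profile
    off <- off + (fit$W - as.numeric(design$X %*% fit$beta) -
                    design$offset)
  }
  lo <- min(x); hi <- max(x)
  xs <- sort(x)
  n <- length(xs)
  c_lo <- max(lo + step, xs[min(min_tail, n)])
  c_hi <- min(stats::median(x), hi - 2 * step)
  candidates <- seq(ceiling(c_lo / step) * step, c_hi, by = step)
  if (length(candidates) == 0L) {
    stop("no feasible threshold candidates in the training range",
         call. = FALSE)
  }
  w_hi <- xs[n - min(min_tail, n) + 1L]
  fit_one <- function(cc, ww) {
    cold <- pmax(cc - x, 0)
    Xc <- cbind(X0, cold_hinge = cold)
    if (is.finite(ww)) Xc <- cbind(Xc, warm_hinge = pmax(x - ww, 0))
    g <- suppressWarnings(
      stats::glm.fit(x = Xc, y = y, offset = off,
                     family = stats::poisson())
    )
    ll <- sum(stats::dpois(y, g$fitted.values, log = TRUE))
    info <- crossprod(Xc, Xc * g$fitted.values)
    se <- tryCatch(sqrt(diag(chol2inv(chol(info)))[ncol(X0) + 1L]),
                   error = function(e) NA_real_)
    list(aic = -2 * ll + 2 * ncol(Xc),
         slope = g$coefficients[["cold_hinge"]], se = se)
  }
  rows <- lapply(candidates, function(cc) {
    warm_knots <- seq(max(cc + 2, stats::median(x)), w_hi, by = 1)
    fits <- lapply(c(as.list(warm_knots), Inf), function(ww) fit_one(cc, ww))
    aics <- vapply(fits, `[[`, numeric(1), "aic")
    best <- fits[[which.min(aics)]]
    data.frame(c = cc, aic = best$aic,
               warm_knot = c(warm_knots, Inf)[which.min(aics)],
               cold_slope = best$slope, cold_se = best$se,
               cold_z = best$slope / best$se)
  })
  scan <- do.call(rbind, rows)
  best <- which.min(scan$aic)
  zcrit <- stats::qnorm(1 - alpha / 2)
  list(scan = scan, c_best = scan$c[best],
       cold_ok = is.finite(scan$cold_z[best]) && scan$cold_z[best] > zcrit)
}

#' @export
print.threshold_estimate <- function(x, ...) {
  if (x$found) {
    cat(sprintf("critical cold threshold: %.1f degC (%s, step %.2f)\n",
                x$critical, x$method, x$step))
  } else if (x$monotone) {
    cat("no threshold: cold effect significant but no flat band",
        "(monotone curve)\n")
  } else {
    cat("no threshold found\n")
  }
  invisible(x)
}

#' Wald chi-square test for a whole term group
#'
#' @param fit a `glm_fit` or `glarma_fit`.
#' @param group group label (e.g. `"avgtem"`, `"weekday"`).
#' @return list with `chisq`, `df`, `p`.
#' @export
wald_group_test <- function(fit, group) {
  idx <- beta_block_idx(fit, group)
  b <- fit$beta[idx]
  Sigma <- param_cov(fit)[idx, idx, drop = FALSE]
  chisq <- as.numeric(b %*% solve(Sigma, b))
  df <- length(idx)
  list(chisq = chisq, df = df, p = stats::pchisq(chisq, df,
                                                 lower.tail = FALSE))
}
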