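#' Fit a centered orthonormal polynomial basis
#'
#' Builds the orthogonal-polynomial basis of the given degree on the
#' training values: columns are mutually orthogonal with unit norm and
#' orthogonal to the constant, and the stored three-term recurrence
#' coefficients allow exact evaluation at arbitrary new points.
#'
#' @param x numeric training values; must have more than `degree` distinct
#'   values.
#' @param degree polynomial degree, integer `>= 1`.
#' @return an object of class `poly_basis` with fields `degree`, `coefs`
#'   (recurrence centers `alpha` and squared norms `norm2`), `center`
#'   (mean of training x), `range` (training range) and `training_n`.
#' @export
fit_poly_basis <- function(x, degree) {
  degree <- as.integer(degree)
  if (degree < 1L) stop("degree must be >= 1", call. = FALSE)
  n_distinct <- length(unique(x))
  if (n_distinct <= degree) {
    stop("degree ", degree, " requires more than ", degree,
         " distinct values; got ", n_distinct, call. = FALSE)
  }
  p <- stats::poly(x, degree = degree)
  structure(
    list(
      degree = degree,
      coefs = attr(p, "coefs"),
      center = mean(x),
      range = range(x),
      training_n = length(x)
    ),
    class = "poly_basis"
  )
}

#' Evaluate a polynomial basis at new points
#'
#' Deterministic evaluation through the stored recurrence; at the training
#' values this reproduces the training columns. Points outside the training
#' range are allowed but flagged.
#'
#' @param basis a [fit_poly_basis()] object.
#' @param x_new numeric values at which to evaluate.
#' @return numeric matrix with `degree` columns; attribute `extrapolated`
#'   is a logical vector marking points outside the training range.
#' @export
eval_poly_basis <- function(basis, x_new) {
  stopifnot(inherits(basis, "poly_basis"))
  m <- stats::poly(x_new, degree = basis$degree, coefs = basis$coefs)
  m <- unclass(m)
  attributes(m) <- list(dim = dim(m))
  attr(m, "extrapolated") <- x_new < basis$range[1L] | x_new > basis$range[2L]
  m
}

#' Declarative specification of one candidate model
#'
#' Describes a single model of the daily call counts: the count family,
#' polynomial degrees of the four smooth terms (0 excludes a term), which
#' dummy blocks are present, the autoregressive lags of the GLARMA
#' recursion (empty for a plain GLM) and whether the subscriber offset is
#' used. Sunday and January are the dummy reference levels.
#'
#' @param family `"poisson"` or `"negbin"`.
#' @param deg_tem,deg_hum,deg_rng,deg_time polynomial degrees (integers
#'   `>= 0`) of the smoothed minimum temperature, smoothed humidity,
#'   smoothed temperature range and scaled-time terms; 0 excludes the term.
#' @param include_weekday,include_month,include_window_indicator logical
#'   switches for the dummy blocks and the date-window indicator.
#' @param ar_lags sorted distinct positive integers; autoregressive lags.
#' @param use_offset include the offset `log(subscribers / 10000)`
#'   (default `TRUE`), so coefficients act on the rate per 10,000
#'   subscribers.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(family = c("poisson", "negbin"),
                       deg_tem = 0L, deg_hum = 0L, deg_rng = 0L,
                       deg_time = 0L,
                       include_weekday = FALSE, include_month = FALSE,
                       include_window_indicator = FALSE,
                       ar_lags = integer(0), use_offset = TRUE) {
  family <- match.arg(family)
  degs <- c(deg_tem = deg_tem, deg_hum = deg_hum, deg_rng = deg_rng,
            deg_time = deg_time)
  if (any(degs < 0) || any(degs != round(degs))) {
    stop("degrees must be non-negative integers", call. = FALSE)
  }
  ar_lags <- as.integer(ar_lags)
  if (length(ar_lags) > 0L) {
    if (any(ar_lags < 1L) || anyDuplicated(ar_lags)) {
      stop("ar_lags must be distinct positive integers", call. = FALSE)
    }
    ar_lags <- sort(ar_lags)
  }
  structure(
    list(
      family = family,
      deg_tem = as.integer(deg_tem), deg_hum = as.integer(deg_hum),
      deg_rng = as.integer(deg_rng), deg_time = as.integer(deg_time),
      include_weekday = isTRUE(include_weekday),
      include_month = isTRUE(include_month),
      include_window_indicator = isTRUE(include_window_indicator),
      ar_lags = ar_lags,
      use_offset = isTRUE(use_offset)
    ),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", x$family,
      sprintf("| degrees tem=%d hum=%d rng=%d time=%d",
              x$deg_tem, x$deg_hum, x$deg_rng, x$deg_time),
      "\n  weekday:", x$include_weekday, " month:", x$include_month,
      " window:", x$include_window_indicator,
      "\n  ar_lags:", if (length(x$ar_lags)) paste(x$ar_lags, collapse = ",")
      else "(none)",
      " offset:", x$use_offset, "\n")
  invisible(x)
}

#' Serialize / deserialize a model spec
#'
#' @param spec a [model_spec()].
#' @param path file path (JSON).
#' @return `read_model_spec` returns a [model_spec()].
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "model_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_spec(
    family = x$family,
    deg_tem = x$deg_tem, deg_hum = x$deg_hum, deg_rng = x$deg_rng,
    deg_time = x$deg_time,
    include_weekday = x$include_weekday, include_month = x$include_month,
    include_window_indicator = x$include_window_indicator,
    ar_lags = if (is.null(x$ar_lags)) integer(0) else x$ar_lags,
    use_offset = x$use_offset
  )
}

weekday_labels <- c("Sunday", "Monday", "Tuesday", "Wednesday", "Thursday",
                    "Friday", "Saturday")
month_labels <- c("January", "February", "March", "April", "May", "June",
                  "July", "August", "September", "October", "November",
                  "December")

#' Assemble the design matrix for a model spec
#'
#' Restricts to rows with a full smoothing window, builds the orthonormal
#' polynomial blocks for each smooth term, the weekday dummies (Sunday
#' reference), month dummies (January reference) and the optional window
#' indicator, and attaches the offset `log(subscribers / 10000)` when the
#' spec uses it.
#'
#' @param features an engineered frame from [engineer_features()].
#' @param spec a [model_spec()].
#' @return an object of class `design_matrix`: list with `y` (counts), `X`
#'   (numeric matrix including the intercept), `offset` (numeric vector,
#'   zeros when the spec has no offset), `groups` (character vector mapping
#'   columns to term groups), `bases` (named list of `poly_basis` objects),
#'   `rows` (row indices of `features` used) and `spec`.
#' @export
build_design <- function(features, spec) {
  stopifnot(inherits(spec, "model_spec"))
  valid_from <- attr(features, "valid_from")
  if (is.null(valid_from)) valid_from <- 1L
  rows <- seq(valid_from, nrow(features))
  f <- features[rows, , drop = FALSE]

  n <- nrow(f)
  cols <- list(`(Intercept)` = rep(1, n))
  groups <- "intercept"
  bases <- list()

  add_poly <- function(name, x, degree) {
    b <- fit_poly_basis(x, degree)
    m <- eval_poly_basis(b, x)
    colnames(m) <- paste0(name, ".", seq_len(degree))
    bases[[name]] <<- b
    for (j in seq_len(degree)) cols[[colnames(m)[j]]] <<- m[, j]
    groups <<- c(groups, rep(name, degree))
  }
  if (spec$deg_tem > 0L) add_poly("avgtem", f$avgtem, spec$deg_tem)
  if (spec$deg_hum > 0L) add_poly("avghum", f$avghum, spec$deg_hum)
  if (spec$deg_rng > 0L) add_poly("avgrng", f$avgrng, spec$deg_rng)
  if (spec$deg_time > 0L) add_poly("time", f$u, spec$deg_time)

  if (spec$include_weekday) {
    for (w in 1:6) {
      cols[[paste0("weekday", weekday_labels[w + 1L])]] <-
        as.numeric(f$weekday == w)
    }
    groups <- c(groups, rep("weekday", 6L))
  }
  if (spec$include_month) {
    for (m in 2:12) {
      cols[[paste0("month", month_labels[m])]] <- as.numeric(f$month == m)
    }
    groups <- c(groups, rep("month", 11L))
  }
  if (spec$include_window_indicator) {
    cols[["window_indicator"]] <- as.numeric(f$window_indicator)
    groups <- c(groups, "window")
  }

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    bad_groups <- unique(groups[match(dropped, colnames(X))])
    stop("design matrix is rank deficient; collinear group(s): ",
         paste(bad_groups, collapse = ", "), call. = FALSE)
  }

  offset <- if (spec$use_offset) log(f$subscribers / 10000) else rep(0, n)
  structure(
    list(y = f$calls, X = X, offset = offset, groups = groups,
         bases = bases, rows = rows, spec = spec, data = f),
    class = "design_matrix"
  )
}

#' Number of mean-model columns implied by a spec
#'
#' @param spec a [model_spec()].
#' @return integer count of design columns (including the intercept).
#' @export
n_design_columns <- function(spec) {
  1L + spec$deg_tem + spec$deg_hum + spec$deg_rng + spec$deg_time +
    6L * spec$include_weekday + 11L * spec$include_month +
    1L * spec$include_window_indicator
}
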