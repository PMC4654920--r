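#' Construct and validate a daily call/weather series
#'
#' A `daily_series` is a data frame with one row per calendar day and the
#' six study columns: `date`, `calls` (non-negative integer counts of calls
#' leading to hospital admission), `subscribers` (active service
#' subscribers, positive), `tmin_c` and `tmax_c` (daily minimum and maximum
#' temperature, degrees Celsius) and `humidity_pct` (relative humidity,
#' percent). Dates must be strictly consecutive calendar days. A derived
#' column `trange = tmax_c - tmin_c` is always attached.
#'
#' @param dates `Date` vector, strictly consecutive days.
#' @param calls non-negative integer counts.
#' @param subscribers positive numbers of active subscribers.
#' @param tmin_c,tmax_c daily minimum/maximum temperature in degrees C.
#' @param humidity_pct relative humidity in percent, in `[0, 100]`.
#' @return A data frame of class `daily_series` with the columns above plus
#'   `trange`.
#' @export
daily_series <- function(dates, calls, subscribers, tmin_c, tmax_c,
                         humidity_pct) {
  df <- data.frame(
    date = as.Date(dates),
    calls = calls,
    subscribers = subscribers,
    tmin_c = tmin_c,
    tmax_c = tmax_c,
    humidity_pct = humidity_pct
  )
  df$trange <- df$tmax_c - df$tmin_c
  class(df) <- c("daily_series", "data.frame")
  validate_daily_series(df)
  df
}

#' Validate a daily series against its invariants
#'
#' Checks contiguity of dates, integrality and non-negativity of counts,
#' positivity of subscribers, `tmax_c >= tmin_c` and the humidity range.
#' Errors name the first offending row.
#'
#' @param x object to validate.
#' @return `x`, invisibly, if valid.
#' @export
validate_daily_series <- function(x) {
  required <- c("date", "calls", "subscribers", "tmin_c", "tmax_c",
                "humidity_pct")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0L) {
    stop("daily series is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(x) < 1L) stop("daily series has no rows", call. = FALSE)
  if (anyNA(x[required])) {
    bad <- which(rowSums(is.na(x[required])) > 0)[1L]
    stop("missing value in row ", bad, call. = FALSE)
  }
  d <- as.Date(x$date)
  if (nrow(x) > 1L) {
    step <- diff(as.integer(d))
    if (any(step != 1L)) {
      bad <- which(step != 1L)[1L] + 1L
      stop("dates must be consecutive calendar days; gap or duplicate at row ",
           bad, " (", d[bad - 1L], " -> ", d[bad], ")", call. = FALSE)
    }
  }
  if (any(x$calls < 0)) {
    stop("negative call count at row ", which(x$calls < 0)[1L], call. = FALSE)
  }
  if (any(x$calls != round(x$calls))) {
    stop("non-integer call count at row ",
         which(x$calls != round(x$calls))[1L], call. = FALSE)
  }
  if (any(x$subscribers <= 0)) {
    stop("non-positive subscriber count at row ",
         which(x$subscribers <= 0)[1L], call. = FALSE)
  }
  if (any(x$tmax_c < x$tmin_c)) {
    stop("tmax_c < tmin_c at row ", which(x$tmax_c < x$tmin_c)[1L],
         call. = FALSE)
  }
  if (any(x$humidity_pct < 0 | x$humidity_pct > 100)) {
    stop("humidity_pct outside [0, 100] at row ",
         which(x$humidity_pct < 0 | x$humidity_pct > 100)[1L], call. = FALSE)
  }
  invisible(x)
}

#' Read a daily series from CSV
#'
#' The file must contain (at least) the columns `date, calls, subscribers,
#' tmin_c, tmax_c, humidity_pct`, with ISO-8601 dates. The returned series
#' is validated; the derived `trange` column is added.
#'
#' @param path path to a CSV file.
#' @return a validated [daily_series()].
#' @export
load_daily_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("date", "calls", "subscribers", "tmin_c", "tmax_c",
                "humidity_pct")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("CSV is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  daily_series(
    dates = as.Date(raw$date),
    calls = raw$calls,
    subscribers = raw$subscribers,
    tmin_c = raw$tmin_c,
    tmax_c = raw$tmax_c,
    humidity_pct = raw$humidity_pct
  )
}

#' Write a daily series to CSV
#'
#' Writes the six schema columns (not the derived `trange`) with ISO-8601
#' dates, so that [load_daily_series()] round-trips the numeric content.
#'
#' @param series a [daily_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_daily_series <- function(series, path) {
  validate_daily_series(series)
  out <- series[c("date", "calls", "subscribers", "tmin_c", "tmax_c",
                  "humidity_pct")]
  out$date <- format(as.Date(out$date), "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Trailing moving average
#'
#' The value at day `t` is the arithmetic mean of the current day and the
#' previous `window - 1` days. Days before the first full window are
#' returned as `NA` and reported through `valid_from`, never imputed.
#'
#' @param x numeric vector of daily values.
#' @param window window length in days (default 7: the current day and the
#'   six preceding days).
#' @return list with `values` (same length as `x`, `NA` before the first
#'   full window) and `valid_from`, the 1-based index of the first usable
#'   day (`window`).
#' @export
trailing_mean <- function(x, window = 7L) {
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  n <- length(x)
  if (n < window) {
    stop("series of length ", n, " is shorter than window ", window,
         call. = FALSE)
  }
  cs <- cumsum(as.numeric(x))
  values <- rep(NA_real_, n)
  idx <- window:n
  values[idx] <- (cs[idx] - c(0, cs)[idx - window + 1L]) / window
  list(values = values, valid_from = window)
}

#' Call rate per 10,000 subscribers
#'
#' @param series a [daily_series()].
#' @return numeric vector `10000 * calls / subscribers`.
#' @export
call_rate <- function(series) {
  validate_daily_series(series)
  10000 * series$calls / series$subscribers
}

#' Calendar features of a daily series
#'
#' Computes the weekday index (0 = Sunday .. 6 = Saturday), month index
#' (1..12), scaled time `u in [0, 1]` and an indicator for a configurable
#' closed date window (used in the study for an epidemic period; off by
#' default).
#'
#' @param series a [daily_series()].
#' @param window_start,window_end optional `Date`s delimiting a closed
#'   interval on which the indicator is 1. Both `NULL` (default) turns the
#'   indicator off (all zeros).
#' @return data frame with columns `weekday`, `month`, `u`,
#'   `window_indicator`.
#' @export
calendar_features <- function(series, window_start = NULL, window_end = NULL) {
  validate_daily_series(series)
  n <- nrow(series)
  if (n < 2L) stop("scaled time is undefined for a single-day series",
                   call. = FALSE)
  d <- as.Date(series$date)
  # POSIXlt wday is already 0 = Sunday .. 6 = Saturday
  weekday <- as.POSIXlt(d)$wday
  month <- as.POSIXlt(d)$mon + 1L
  u <- as.numeric(d - d[1L]) / as.numeric(d[n] - d[1L])
  indicator <- rep(0L, n)
  if (!is.null(window_start) || !is.null(window_end)) {
    if (is.null(window_start) || is.null(window_end)) {
      stop("window_start and window_end must both be given", call. = FALSE)
    }
    ws <- as.Date(window_start); we <- as.Date(window_end)
    if (we < ws) stop("window_end precedes window_start", call. = FALSE)
    indicator[d >= ws & d <= we] <- 1L
  }
  data.frame(weekday = weekday, month = month, u = u,
             window_indicator = indicator)
}

#' Engineered covariate frame
#'
#' Combines 7-day trailing averages of the weather variables, the call rate
#' per 10,000 subscribers and the calendar features into one tidy frame.
#' Rows before the first full smoothing window carry `NA` in the smoothed
#' columns and are excluded from model likelihoods downstream.
#'
#' @param series a [daily_series()].
#' @param window smoothing window in days (default 7).
#' @param window_start,window_end optional closed date window for the
#'   indicator, passed to [calendar_features()].
#' @return data frame with columns `date`, `calls`, `subscribers`,
#'   `avgtem`, `avghum`, `avgrng`, `rate`, `weekday`, `month`, `u`,
#'   `window_indicator`, plus attribute `valid_from` (1-based index of the
#'   first row with a full smoothing window).
#' @export
engineer_features <- function(series, window = 7L, window_start = NULL,
                              window_end = NULL) {
  validate_daily_series(series)
  tm <- trailing_mean(series$tmin_c, window)
  hm <- trailing_mean(series$humidity_pct, window)
  rm_ <- trailing_mean(series$tmax_c - series$tmin_c, window)
  cal <- calendar_features(series, window_start, window_end)
  out <- data.frame(
    date = as.Date(series$date),
    calls = series$calls,
    subscribers = series$subscribers,
    avgtem = tm$values,
    avghum = hm$values,
    avgrng = rm_$values,
    rate = call_rate(series),
    weekday = cal$weekday,
    month = cal$month,
    u = cal$u,
    window_indicator = cal$window_indicator
  )
  attr(out, "valid_from") <- tm$valid_from
  out
}
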