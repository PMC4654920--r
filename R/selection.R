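#' AIC search over polynomial degrees
#'
#' Selects the degrees of the four smooth terms (smoothed minimum
#' temperature, smoothed humidity, smoothed temperature range, secular
#' time trend) by minimizing the AIC of Poisson GLM fits. The default
#' search space is degrees 1..20 for temperature, 1..10 for humidity,
#' 1..5 for temperature range and 1..20 for the time trend. The default
#' strategy is cyclic coordinate descent from (3, 1, 1, 5), iterating to a
#' fixed point with ties broken toward the lower degree; `"exhaustive"`
#' fits the full grid.
#'
#' @param features engineered frame from [engineer_features()].
#' @param grid named list with integer vectors `tem`, `hum`, `rng`, `time`.
#' @param strategy `"coordinate"` or `"exhaustive"`.
#' @param include_weekday,include_month,include_window_indicator dummy
#'   blocks held fixed during the search.
#' @param use_offset passed through to the candidate specs.
#' @return an object of class `search_result`: `best_spec` (a
#'   [model_spec()]), `aic_trace` (data frame of visited degree
#'   combinations and their AIC), `strategy`, `grid`.
#' @export
select_degrees <- function(features,
                           grid = list(tem = 1:20, hum = 1:10, rng = 1:5,
                                       time = 1:20),
                           strategy = c("coordinate", "exhaustive"),
                           include_weekday = TRUE, include_month = TRUE,
                           include_window_indicator = FALSE,
                           use_offset = TRUE) {
  strategy <- match.arg(strategy)
  for (nm in c("tem", "hum", "rng", "time")) {
    if (is.null(grid[[nm]]) || length(grid[[nm]]) == 0L) {
      stop("grid must contain non-empty ranges tem, hum, rng, time",
           call. = FALSE)
    }
    grid[[nm]] <- sort(as.integer(grid[[nm]]))
  }

  cache <- new.env(parent = emptyenv())
  failures <- list()
  trace <- list()
  spec_for <- function(d) {
    model_spec("poisson", deg_tem = d[1], deg_hum = d[2], deg_rng = d[3],
               deg_time = d[4],
               include_weekday = include_weekday,
               include_month = include_month,
               include_window_indicator = include_window_indicator,
               use_offset = use_offset)
  }
  aic_of <- function(d) {
    key <- paste(d, collapse = "-")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- tryCatch({
      fit_glm(build_design(features, spec_for(d)), "poisson")$aic
    }, error = function(e) {
      failures[[key]] <<- conditionMessage(e)
      NA_real_
    })
    cache[[key]] <- val
    trace[[length(trace) + 1L]] <<- c(d, aic = val)
    val
  }

  if (strategy == "exhaustive") {
    combos <- expand.grid(tem = grid$tem, hum = grid$hum, rng = grid$rng,
                          time = grid$time)
    aics <- apply(combos, 1L, function(r) aic_of(as.integer(r)))
    if (all(is.na(aics))) {
      stop("all candidate fits failed; first failure: ",
           failures[[1L]], call. = FALSE)
    }
    best <- as.integer(combos[which.min(aics), ])
  } else {
    start <- c(3L, 1L, 1L, 5L)
    clamp <- function(v, rng) rng[which.min(abs(rng - v))]
    cur <- c(clamp(start[1], grid$tem), clamp(start[2], grid$hum),
             clamp(start[3], grid$rng), clamp(start[4], grid$time))
    ranges <- list(grid$tem, grid$hum, grid$rng, grid$time)
    repeat {
      prev <- cur
      for (k in 1:4) {
        cand <- cur
        best_aic <- Inf
        best_deg <- cur[k]
        for (d in ranges[[k]]) {      # ascending: ties keep lower degree
          cand[k] <- d
          a <- aic_of(cand)
          if (!is.na(a) && a < best_aic - 1e-12) {
            best_aic <- a
            best_deg <- d
          }
        }
        if (!is.finite(best_aic)) {
          stop("all candidate fits failed along coordinate ", k,
               call. = FALSE)
        }
        cur[k] <- best_deg
      }
      if (identical(cur, prev)) break
    }
    best <- cur
  }

  trace_df <- as.data.frame(do.call(rbind, trace))
  names(trace_df) <- c("deg_tem", "deg_hum", "deg_rng", "deg_time", "aic")
  structure(
    list(best_spec = spec_for(best), aic_trace = trace_df,
         strategy = strategy, grid = grid, failures = failures),
    class = "search_result"
  )
}

#' @export
print.search_result <- function(x, ...) {
  s <- x$best_spec
  cat(sprintf(
    "degree search (%s, %d fits): tem=%d hum=%d rng=%d time=%d, AIC=%.2f\n",
    x$strategy, nrow(x$aic_trace), s$deg_tem, s$deg_hum, s$deg_rng,
    s$deg_time, min(x$aic_trace$aic, na.rm = TRUE)))
  invisible(x)
}

#' Greedy AIC pruning of whole term groups
#'
#' Starting from a fitted spec, repeatedly removes the term group
#' (temperature, humidity, temperature-range or time polynomial; weekday,
#' month or window-indicator block) whose removal most reduces the Poisson
#' GLM AIC, until no removal lowers it.
#'
#' @param features engineered frame from [engineer_features()].
#' @param spec starting [model_spec()].
#' @return the reduced [model_spec()], with attribute `pruned` listing the
#'   removed groups.
#' @export
prune_terms <- function(features, spec) {
  stopifnot(inherits(spec, "model_spec"))
  aic_of <- function(s) {
    tryCatch(fit_glm(build_design(features, s), "poisson")$aic,
             error = function(e) NA_real_)
  }
  drop_group <- function(s, g) {
    switch(g,
           avgtem = { s$deg_tem <- 0L; s },
           avghum = { s$deg_hum <- 0L; s },
           avgrng = { s$deg_rng <- 0L; s },
           time = { s$deg_time <- 0L; s },
           weekday = { s$include_weekday <- FALSE; s },
           month = { s$include_month <- FALSE; s },
           window = { s$include_window_indicator <- FALSE; s })
  }
  present_groups <- function(s) {
    c(if (s$deg_tem > 0) "avgtem", if (s$deg_hum > 0) "avghum",
      if (s$deg_rng > 0) "avgrng", if (s$deg_time > 0) "time",
      if (s$include_weekday) "weekday", if (s$include_month) "month",
      if (s$include_window_indicator) "window")
  }
  current <- spec
  current_aic <- aic_of(current)
  if (is.na(current_aic)) stop("starting spec failed to fit", call. = FALSE)
  removed <- character(0)
  repeat {
    groups <- present_groups(current)
    if (length(groups) == 0L) break
    aics <- vapply(groups, function(g) aic_of(drop_group(current, g)),
                   numeric(1))
    if (all(is.na(aics)) || min(aics, na.rm = TRUE) >= current_aic) break
    g <- groups[which.min(aics)]
    current <- drop_group(current, g)
    current_aic <- min(aics, na.rm = TRUE)
    removed <- c(removed, g)
  }
  attr(current, "pruned") <- removed
  current
}
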