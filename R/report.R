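#' Grouped coefficient table of a fitted model
#'
#' One row per estimated parameter (mean coefficients, autoregressive
#' coefficients, NB shape), with standard errors, z statistics, two-sided
#' normal p-values and, for dummy coefficients, the implied percent change
#' versus the reference level `(e^beta - 1) * 100`.
#'
#' @param fit a `glm_fit` or `glarma_fit`.
#' @return data frame with columns `group`, `term`, `estimate`, `se`,
#'   `z`, `p`, `percent`.
#' @export
coefficient_table <- function(fit) {
  if (inherits(fit, "glarma_fit")) {
    se_beta <- fit$se_beta
  } else {
    se_beta <- sqrt(pmax(diag(fit$cov_beta), 0))
  }
  est <- fit$beta
  z <- est / se_beta
  tab <- data.frame(
    group = fit$groups,
    term = names(est),
    estimate = as.numeric(est),
    se = as.numeric(se_beta),
    z = as.numeric(z),
    p = 2 * stats::pnorm(-abs(as.numeric(z))),
    stringsAsFactors = FALSE
  )
  tab$percent <- ifelse(tab$group %in% c("weekday", "month", "window"),
                        percent_change(tab$estimate), NA_real_)
  if (inherits(fit, "glarma_fit")) {
    phi_tab <- data.frame(
      group = "ar", term = names(fit$phi), estimate = as.numeric(fit$phi),
      se = as.numeric(fit$se_phi),
      z = as.numeric(fit$phi / fit$se_phi),
      p = 2 * stats::pnorm(-abs(as.numeric(fit$phi / fit$se_phi))),
      percent = NA_real_, stringsAsFactors = FALSE
    )
    tab <- rbind(tab, phi_tab)
    if (!is.na(fit$theta)) {
      tab <- rbind(tab, data.frame(
        group = "dispersion", term = "theta", estimate = fit$theta,
        se = fit$theta * fit$se_log_theta, z = NA_real_, p = NA_real_,
        percent = NA_real_, stringsAsFactors = FALSE
      ))
    }
  }
  rownames(tab) <- NULL
  tab
}

#' Assemble a model report
#'
#' Collects the grouped coefficient table, Wald group tests for every
#' multi-column term group, the supplied effect curves, the threshold
#' estimate and the pipeline decision log into one object that can be
#' written to disk with [write_report()].
#'
#' @param fit final fitted model.
#' @param curves named list of [effect_curve()] objects.
#' @param threshold optional [find_cold_threshold()] result.
#' @param decisions optional list of decision records.
#' @return an object of class `call_report`.
#' @export
report <- function(fit, curves = list(), threshold = NULL,
                   decisions = list()) {
  groups <- setdiff(unique(fit$groups), "intercept")
  gtests <- do.call(rbind, lapply(groups, function(g) {
    wt <- wald_group_test(fit, g)
    data.frame(group = g, chisq = wt$chisq, df = wt$df, p = wt$p,
               stringsAsFactors = FALSE)
  }))
  structure(
    list(
      table = coefficient_table(fit),
      group_tests = gtests,
      fit_stats = list(
        family = fit$family,
        loglik = fit$loglik, aic = fit$aic,
        deviance = fit$deviance, df_resid = fit$df_resid,
        theta = fit$theta,
        ar_lags = if (inherits(fit, "glarma_fit")) fit$ar_lags
        else integer(0)
      ),
      curves = curves,
      threshold = threshold,
      decisions = decisions
    ),
    class = "call_report"
  )
}

#' Write a model report to a directory
#'
#' Emits `coefficients.json` (table, group tests and fit statistics),
#' `effects_<variable>.csv` per effect curve, `threshold.json` and a
#' human-readable `report.md`, plus `decisions.json` when decisions were
#' recorded.
#'
#' @param rep a [report()] object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(rep, dir) {
  stopifnot(inherits(rep, "call_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(coefficients = rep$table, group_tests = rep$group_tests,
         fit = rep$fit_stats),
    file.path(dir, "coefficients.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  for (nm in names(rep$curves)) {
    utils::write.csv(rep$curves[[nm]]$curve,
                     file.path(dir, paste0("effects_", nm, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(rep$threshold)) {
    th <- rep$threshold
    jsonlite::write_json(
      list(critical = th$critical, found = th$found,
           monotone = th$monotone, method = th$method,
           ci_excludes_zero = th$ci_excludes_zero,
           step = th$step, alpha = th$alpha,
           flat_width = th$flat_width, range = th$range),
      file.path(dir, "threshold.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
  }
  if (length(rep$decisions) > 0) {
    jsonlite::write_json(rep$decisions, file.path(dir, "decisions.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  writeLines(format_report_md(rep), file.path(dir, "report.md"))
  invisible(dir)
}

format_report_md <- function(rep) {
  fs <- rep$fit_stats
  lines <- c(
    "# Model report",
    "",
    sprintf("Final family: **%s**%s; AIC %.2f; deviance %.1f on %d df.",
            fs$family,
            if (length(fs$ar_lags)) sprintf(" GLARMA, lags {%s}",
                                            paste(fs$ar_lags,
                                                  collapse = ", "))
            else " GLM",
            fs$aic, fs$deviance, fs$df_resid),
    ""
  )
  if (!is.null(rep$threshold)) {
    th <- rep$threshold
    lines <- c(lines,
               if (th$found)
                 sprintf("Critical cold-temperature threshold: **%.1f degC**.",
                         th$critical)
               else "No critical cold-temperature threshold detected.",
               "")
  }
  lines <- c(lines, "## Term groups", "",
             "| group | chi-square | df | p |", "|---|---|---|---|")
  for (i in seq_len(nrow(rep$group_tests))) {
    g <- rep$group_tests[i, ]
    lines <- c(lines, sprintf("| %s | %.2f | %d | %.3g |",
                              g$group, g$chisq, g$df, g$p))
  }
  lines <- c(lines, "", "## Coefficients", "",
             "| group | term | estimate | se | z | p | percent |",
             "|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(rep$table))) {
    r <- rep$table[i, ]
    lines <- c(lines, sprintf(
      "| %s | %s | %.5f | %.5f | %s | %s | %s |",
      r$group, r$term, r$estimate, r$se,
      if (is.na(r$z)) "" else sprintf("%.2f", r$z),
      if (is.na(r$p)) "" else sprintf("%.3g", r$p),
      if (is.na(r$percent)) "" else sprintf("%+.2f%%", r$percent)))
  }
  lines
}
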