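#' Fit every subject of a cohort
#'
#' Applies the saturating-curve fit per subject and collects parameters,
#' status and goodness of fit. Per-subject failures are data, not errors:
#' they appear as rows with \code{NA} parameters and never abort the run.
#'
#' @param cohort a cohort data frame (one measure), or a CSV path readable
#'   by \code{\link{load_cohort}}.
#' @param measure passed to \code{\link{load_cohort}} when \code{cohort} is
#'   a path; also selects starting values.
#' @param control fit control.
#' @param out optional CSV path for the per-subject table.
#' @param json_summary optional JSON path for the aggregate summary.
#' @return list with \code{table} (subject_id, status, a1, b1, c1, rmse,
#'   n_obs) and \code{summary} (RMSE summary over converged subjects plus
#'   failure counts and rate).
#' @export
run_fit <- function(cohort, measure = c("weight", "height"),
                    control = mm_control(), out = NULL, json_summary = NULL) {
  measure <- match.arg(measure)
  if (is.character(cohort)) cohort <- load_cohort(cohort, measure = measure)
  series <- split_series(cohort)
  rows <- lapply(names(series), function(id) {
    s <- series[[id]]
    fit <- tryCatch(
      fit_mm(s$age_days, s$value, measure = measure, control = control),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(subject_id = id, status = "too_few_points",
                        a1 = NA_real_, b1 = NA_real_, c1 = NA_real_,
                        rmse = NA_real_, n_obs = nrow(s)))
    }
    p <- if (fit$status == "converged") fit$params else
      c(a1 = NA_real_, b1 = NA_real_, c1 = NA_real_)
    data.frame(subject_id = id, status = fit$status,
               a1 = p[["a1"]], b1 = p[["b1"]], c1 = p[["c1"]],
               rmse = fit$rmse, n_obs = nrow(s))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  conv <- tab$status == "converged"
  summary <- list(
    n_subjects = nrow(tab),
    n_converged = sum(conv),
    n_failures = sum(!conv),
    failure_rate = mean(!conv),
    rmse = if (any(conv)) summarize_rmse(tab$rmse[conv],
                                         n_failures = sum(!conv)) else NULL
  )
  if (!is.null(out)) utils::write.csv(tab, out, row.names = FALSE)
  if (!is.null(json_summary)) {
    js <- summary
    js$rmse <- unclass(js$rmse)
    jsonlite::write_json(js, json_summary, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  list(table = tab, summary = summary)
}

#' Render experiment summaries as population-table rows
#'
#' Formats one or more RMSE summaries in the conventional reporting shape:
#' mean (sd), median (IQR), the 90th percentile and the range per row.
#' Accepts a single \code{\link{summarize_rmse}} result, a named list of
#' them (e.g. \code{holdout_experiment()$summaries}), or a
#' \code{\link{prediction_table}} data frame.
#'
#' @param x the experiment output to report.
#' @param digits significant digits.
#' @return the formatted data frame, invisibly; printed as a side effect.
#' @export
run_report <- function(x, digits = 3L) {
  if (inherits(x, "rmse_summary")) x <- list(RMSE = x)
  if (is.data.frame(x)) {
    stopifnot(all(c("mean", "sd", "median", "iqr") %in% names(x)))
    lab <- if (all(c("fit_window", "eval_window") %in% names(x)))
      paste(x$fit_window, x$eval_window, sep = ", ") else rownames(x)
    out <- data.frame(
      row = lab,
      `mean (sd)` = sprintf("%s (%s)", signif(x$mean, digits),
                            signif(x$sd, digits)),
      `median (IQR)` = sprintf("%s (%s)", signif(x$median, digits),
                               signif(x$iqr, digits)),
      range = sprintf("%s-%s", signif(x$min, digits), signif(x$max, digits)),
      n = x$n_subjects, failures = x$n_failures,
      check.names = FALSE)
  } else if (is.list(x) && length(x) &&
             all(vapply(x, inherits, logical(1), "rmse_summary"))) {
    out <- data.frame(
      row = names(x),
      `mean (sd)` = vapply(x, function(s)
        sprintf("%s (%s)", signif(s$mean, digits), signif(s$sd, digits)),
        character(1)),
      `median (IQR)` = vapply(x, function(s)
        sprintf("%s (%s)", signif(s$median, digits), signif(s$iqr, digits)),
        character(1)),
      `90% <` = vapply(x, function(s) format(signif(s$p90, digits)),
                       character(1)),
      range = vapply(x, function(s)
        sprintf("%s-%s", signif(s$min, digits), signif(s$max, digits)),
        character(1)),
      n = vapply(x, `[[`, integer(1), "n_subjects"),
      failures = vapply(x, `[[`, integer(1), "n_failures"),
      check.names = FALSE, row.names = NULL)
  } else {
    stop("don't know how to report an object of class ",
         paste(class(x), collapse = "/"))
  }
  print(out, row.names = FALSE)
  invisible(out)
}
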