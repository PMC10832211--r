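#' Summarize a vector of per-subject RMSE values
#'
#' The summary reported for every experiment: mean, sd (denominator n-1),
#' median, IQR (p75 - p25), the 90th percentile ("90% of subjects below"),
#' and range. Quantiles use linear interpolation between order statistics.
#'
#' @param x non-empty numeric vector of per-subject RMSE values (kg or cm).
#' @param n_failures count of subjects excluded for fit failure (carried
#'   through for reporting).
#' @return a list of class \code{"rmse_summary"} with fields \code{mean},
#'   \code{sd}, \code{median}, \code{iqr}, \code{p90}, \code{min},
#'   \code{max}, \code{n_subjects}, \code{n_failures}.
#' @export
summarize_rmse <- function(x, n_failures = 0L) {
  if (length(x) == 0L) stop("empty RMSE vector")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  structure(list(
    mean = mean(x), sd = stats::sd(x),
    median = q[2L], iqr = q[3L] - q[1L], p90 = q[4L],
    min = min(x), max = max(x),
    n_subjects = length(x), n_failures = as.integer(n_failures)
  ), class = "rmse_summary")
}

#' @export
print.rmse_summary <- function(x, digits = 3L, ...) {
  cat(sprintf(
    "RMSE over %d subjects (%d failures): mean %s (sd %s), median %s (IQR %s), 90%% < %s, range %s-%s\n",
    x$n_subjects, x$n_failures,
    signif(x$mean, digits), signif(x$sd, digits), signif(x$median, digits),
    signif(x$iqr, digits), signif(x$p90, digits), signif(x$min, digits),
    signif(x$max, digits)))
  invisible(x)
}

#' Spearman correlation between fitted intercepts and birth size
#'
#' The model intercept c1 empirically approximates birth weight / birth
#' length; this quantifies that association by Spearman's rank correlation
#' (average ranks for ties).
#'
#' @param c1 fitted c1 values, one per subject.
#' @param birth_size observed birth weights (kg) or lengths (cm), paired.
#' @return Spearman's rho.
#' @export
c1_birth_correlation <- function(c1, birth_size) {
  if (length(c1) != length(birth_size)) stop("inputs must be paired")
  ok <- is.finite(c1) & is.finite(birth_size)
  c1 <- c1[ok]; birth_size <- birth_size[ok]
  if (length(c1) < 3L) stop("need at least 3 paired subjects")
  if (stats::sd(c1) == 0 || stats::sd(birth_size) == 0)
    stop("zero variance in c1 or birth size")
  stats::cor(c1, birth_size, method = "spearman")
}

# Fit one subject's assigned-visit values; returns RMSE of that fit
# evaluated against ALL of the subject's subset visits (so a fit to reduced
# data is scored on how well it imputes the dropped visits too), or NA on
# fit failure.
.imputation_rmse <- function(assign, keep_visits, eval_idx, measure, control) {
  idx <- which(assign$visit %in% keep_visits & !is.na(assign$value))
  if (length(idx) < 3L) return(structure(NA_real_, degenerate = TRUE))
  fit <- fit_mm(assign$age_days[idx], assign$value[idx],
                measure = measure, control = control)
  if (fit$status != "converged") return(NA_real_)
  pred <- mm_value(fit$params, assign$age_days[eval_idx])
  rmse(assign$value[eval_idx] - pred)
}

#' Visit-dropping imputation study
#'
#' Restricted to subjects with every scheduled visit through visit
#' \code{subset} (7 = first-year complete, 12 = all three years), the model
#' is first fitted to all subset visits (the baseline). Then every single
#' visit and every combination of up to \code{max_drop} visits is dropped,
#' the model refitted to the remaining visits, and each refit scored by its
#' RMSE over \emph{all} subset measurements — dropped visits included — so
#' the score measures how well the reduced data still impute the missing
#' visits. The result reports, per combination, the mean change in RMSE
#' versus baseline over subjects whose refit converged, and the failure
#' count.
#'
#' @param cohort a cohort data frame (one measure).
#' @param schedule visit windows, see \code{\link{visit_schedule}}.
#' @param subset 7 or 12.
#' @param max_drop largest combination size dropped (the full protocol uses
#'   5).
#' @param control fit control.
#' @return data frame with one row per drop combination (including the empty
#'   combination, whose delta is exactly 0): \code{dropped} (e.g.
#'   \code{"1+3"}), \code{n_dropped}, \code{delta_rmse}, \code{n_failures},
#'   \code{n_degenerate}, \code{n_subjects}. Attribute
#'   \code{"n_subjects_in"} records the eligible-subject count.
#' @export
imputation_experiment <- function(cohort, schedule = visit_schedule(),
                                  subset = 12, max_drop = 5,
                                  control = mm_control()) {
  if (!subset %in% c(7L, 12L)) stop("'subset' must be 7 or 12")
  measure <- cohort$measure[1L]
  visits <- seq_len(subset)
  series <- split_series(cohort)
  assigns <- lapply(series, assign_visits, schedule = schedule)
  complete <- vapply(assigns, has_complete_visits, logical(1),
                     through_visit = subset)
  assigns <- assigns[complete]
  if (length(assigns) == 0L) stop("no subject has complete visits")
  eval_rows <- lapply(assigns, function(a) which(a$visit %in% visits))

  baseline <- as.numeric(mapply(function(a, ev)
    .imputation_rmse(a, visits, ev, measure, control),
    assigns, eval_rows, SIMPLIFY = FALSE))

  combos <- list(integer(0))
  for (k in seq_len(max_drop))
    combos <- c(combos, utils::combn(visits, k, simplify = FALSE))

  rows <- lapply(combos, function(drop) {
    keep <- setdiff(visits, drop)
    r_list <- mapply(function(a, ev)
      .imputation_rmse(a, keep, ev, measure, control), assigns, eval_rows,
      SIMPLIFY = FALSE)
    degen <- vapply(r_list, function(x) isTRUE(attr(x, "degenerate")),
                    logical(1))
    r <- as.numeric(unlist(r_list))
    ok <- !is.na(r) & !is.na(baseline)
    data.frame(
      dropped = paste(drop, collapse = "+"),
      n_dropped = length(drop),
      delta_rmse = if (any(ok)) mean(r[ok] - baseline[ok]) else NA_real_,
      # a subject whose baseline fit failed can never be reported either
      n_failures = sum((is.na(r) | is.na(baseline)) & !degen),
      n_degenerate = sum(degen),
      n_subjects = sum(ok)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_subjects_in") <- length(assigns)
  out
}

#' Single-point holdout comparison of interpolation methods
#'
#' From each eligible subject one measurement other than the birth record is
#' removed uniformly at random (seeded; the selection depends only on the
#' cohort and the seed, never on the method list). Every method fits the
#' remaining points and predicts at the holdout age; the per-subject score
#' is the absolute prediction error — the single-point RMSE — and each
#' method's scores are summarized over subjects. Subjects whose
#' saturating-curve refit fails are dropped from \emph{all} methods, keeping
#' the comparison paired.
#'
#' @param cohort a cohort data frame (one measure).
#' @param methods character vector naming built-in methods (\code{"mm"},
#'   \code{"locf"}, \code{"linear"}, \code{"loess"}, \code{"spline"}) or a
#'   named list of functions \code{f(age, value, at)} for pluggable external
#'   models.
#' @param seed integer seed for the holdout draw (default follows the
#'   original analysis convention).
#' @param min_obs eligibility: minimum measurements per subject.
#' @return list with \code{summaries} (named list of
#'   \code{\link{summarize_rmse}} results per method), \code{per_subject}
#'   (long data frame of absolute errors), \code{holdouts} (subject, age,
#'   value held out), and counts \code{n_ineligible}, \code{n_failures}.
#' @export
holdout_experiment <- function(cohort,
                               methods = c("mm", "locf", "linear",
                                           "loess", "spline"),
                               seed = 1234, min_obs = 5) {
  measure <- cohort$measure[1L]
  if (is.character(methods)) {
    registry <- holdout_methods(measure)
    unknown <- setdiff(methods, names(registry))
    if (length(unknown))
      stop("unknown method(s): ", paste(unknown, collapse = ", "))
    methods <- registry[methods]
  }
  stopifnot(is.list(methods), !is.null(names(methods)))

  series <- split_series(cohort)
  ids <- sort(names(series))
  eligible <- vapply(ids, function(id) {
    s <- series[[id]]
    nrow(s) >= min_obs && sum(s$age_days > 1) >= 2
  }, logical(1))
  n_inelig <- sum(!eligible)
  ids <- ids[eligible]

  # seeded, method-independent holdout choice; per-subject streams so that
  # extending the cohort never reshuffles earlier subjects
  hold <- do.call(rbind, lapply(seq_along(ids), function(i) {
    s <- series[[ids[i]]]
    cand <- which(s$age_days > 1)
    j <- with_seed(subject_seed(seed, i),
                   cand[sample.int(length(cand), 1L)])
    data.frame(subject_id = ids[i], row = j,
               age_days = s$age_days[j], value = s$value[j])
  }))

  errs <- lapply(names(methods), function(m) numeric(0))
  names(errs) <- names(methods)
  kept <- logical(nrow(hold))
  per <- vector("list", nrow(hold))
  for (i in seq_len(nrow(hold))) {
    s <- series[[hold$subject_id[i]]]
    j <- hold$row[i]
    age_r <- s$age_days[-j]; val_r <- s$value[-j]
    preds <- vapply(methods, function(f)
      tryCatch(suppressWarnings(f(age_r, val_r, hold$age_days[i])),
               error = function(e) NA_real_),
      numeric(1))
    if (any(is.na(preds))) next  # paired: drop subject from every method
    kept[i] <- TRUE
    per[[i]] <- data.frame(subject_id = hold$subject_id[i],
                           method = names(methods),
                           abs_error = abs(preds - hold$value[i]))
  }
  n_fail <- sum(!kept)
  per_subject <- do.call(rbind, per[kept])
  if (is.null(per_subject)) stop("no subject survived holdout fitting")
  summaries <- lapply(split(per_subject$abs_error, per_subject$method),
                      summarize_rmse, n_failures = n_fail)
  summaries <- summaries[names(methods)]
  list(summaries = summaries, per_subject = per_subject,
       holdouts = hold[kept, c("subject_id", "age_days", "value")],
       n_ineligible = n_inelig, n_failures = n_fail)
}

# Year windows in days (closed intervals); the protocol's 36-month cutoff.
year_window <- function(which) {
  switch(which,
         "Y1" = c(0, 365), "Y2" = c(366, 730), "Y3" = c(731, 1125),
         "Y1+Y2" = c(0, 730), "Y1-2" = c(0, 730), "Y1-3" = c(0, 1125),
         "Y2-3" = c(366, 1125),
         stop("unknown window '", which, "'"))
}

#' Last-value prediction experiment
#'
#' Can early growth predict size at 36 months? Subjects need at least 5
#' measurements in year 1 (days 0-365) and at least 2 in each of year 2
#' (366-730) and year 3 (731-1125). The curve is fitted to the
#' \code{fit_window} measurements only, and scored by the RMSE of its
#' predictions at the subject's actual later measurement ages: year-1 fits
#' are scored on years 2-3, year-1+2 fits on year 3, and the full-data
#' baseline fit on all measurements (plus any windows requested via
#' \code{eval_windows}). Subjects whose restricted fit fails are dropped and
#' counted.
#'
#' @param cohort a cohort data frame (one measure).
#' @param fit_window \code{"Y1"}, \code{"Y1+Y2"}, or \code{"Y1-3"} (the
#'   baseline fit to all data).
#' @param eval_windows character vector of evaluation windows; default picks
#'   the protocol pairing for the fit window.
#' @param control fit control.
#' @return data frame with one row per (subject, eval window):
#'   \code{subject_id}, \code{fit_window}, \code{eval_window}, \code{rmse},
#'   \code{n_eval}. Attributes \code{"n_ineligible"} and
#'   \code{"n_failures"} carry the conservation counts.
#' @export
prediction_experiment <- function(cohort,
                                  fit_window = c("Y1", "Y1+Y2", "Y1-3"),
                                  eval_windows = NULL,
                                  control = mm_control()) {
  fit_window <- match.arg(fit_window)
  if (is.null(eval_windows)) {
    eval_windows <- switch(fit_window,
                           "Y1" = "Y2-3", "Y1+Y2" = "Y3", "Y1-3" = "Y1-3")
  }
  measure <- cohort$measure[1L]
  series <- split_series(cohort)
  in_win <- function(a, w) a >= w[1L] & a <= w[2L]
  eligible <- vapply(series, function(s) {
    a <- s$age_days
    sum(in_win(a, year_window("Y1"))) >= 5 &&
      sum(in_win(a, year_window("Y2"))) >= 2 &&
      sum(in_win(a, year_window("Y3"))) >= 2
  }, logical(1))
  n_inelig <- sum(!eligible)
  series <- series[eligible]
  if (length(series) == 0L) stop("no eligible subject")

  fw <- year_window(fit_window)
  n_fail <- 0L
  rows <- list()
  for (id in names(series)) {
    s <- series[[id]]
    idx <- which(in_win(s$age_days, fw))
    fit <- fit_mm(s$age_days[idx], s$value[idx], measure = measure,
                  control = control)
    if (fit$status != "converged") { n_fail <- n_fail + 1L; next }
    for (ew in eval_windows) {
      w <- year_window(ew)
      e_idx <- which(in_win(s$age_days, w))
      if (length(e_idx) == 0L) next
      pred <- mm_value(fit$params, s$age_days[e_idx])
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = id, fit_window = fit_window, eval_window = ew,
        rmse = rmse(s$value[e_idx] - pred), n_eval = length(e_idx))
    }
  }
  if (length(rows) == 0L) stop("all restricted fits failed")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_ineligible") <- n_inelig
  attr(out, "n_failures") <- n_fail
  out
}

#' Full prediction summary table
#'
#' Runs \code{\link{prediction_experiment}} for the standard five
#' (fit window, evaluation window) pairings — baseline fit scored on all
#' data, on year 3 and on years 2-3; the year-1+2 fit scored on year 3; and
#' the year-1 fit scored on years 2-3 — and summarizes per-subject RMSE for
#' each row.
#'
#' @param cohort a cohort data frame.
#' @param control fit control.
#' @return data frame with one row per pairing: \code{fit_window},
#'   \code{eval_window}, \code{mean}, \code{sd}, \code{median}, \code{iqr},
#'   \code{min}, \code{max}, \code{n_subjects}, \code{n_failures}.
#' @export
prediction_table <- function(cohort, control = mm_control()) {
  base <- prediction_experiment(cohort, "Y1-3",
                                eval_windows = c("Y1-3", "Y3", "Y2-3"),
                                control = control)
  y12 <- prediction_experiment(cohort, "Y1+Y2", control = control)
  y1 <- prediction_experiment(cohort, "Y1", control = control)
  all <- rbind(base, y12, y1)
  fails <- c("Y1-3" = attr(base, "n_failures"),
             "Y1+Y2" = attr(y12, "n_failures"),
             "Y1" = attr(y1, "n_failures"))
  pairs <- unique(all[c("fit_window", "eval_window")])
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    sub <- all[all$fit_window == pairs$fit_window[i] &
               all$eval_window == pairs$eval_window[i], ]
    s <- summarize_rmse(sub$rmse, n_failures = fails[[pairs$fit_window[i]]])
    data.frame(fit_window = pairs$fit_window[i],
               eval_window = pairs$eval_window[i],
               mean = s$mean, sd = s$sd, median = s$median, iqr = s$iqr,
               min = s$min, max = s$max, n_subjects = s$n_subjects,
               n_failures = s$n_failures)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
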