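#' Apply the protocol cleaning rules to one measurement series
#'
#' Three rules, applied in order:
#' \enumerate{
#'   \item measurements beyond \code{max_age} days (~36 months) are dropped;
#'   \item for weight only, measurements between \code{neonatal_low} and
#'     \code{neonatal_high} days are dropped — most newborns lose weight
#'     after birth and only regain it by about day 19 — except the birth
#'     record itself (the earliest measurement at day 0 or 1), which is kept;
#'   \item a subject retaining fewer than \code{min_obs} measurements is
#'     excluded outright.
#' }
#' Exclusion is a value, not an error: the returned list always reports the
#' per-rule drop counts so that retained + dropped equals the input count.
#'
#' @param series one subject's series data frame (\code{age_days},
#'   \code{value}, \code{measure}).
#' @param max_age oldest retained age, days.
#' @param neonatal_low,neonatal_high the dropped early-weight age range,
#'   days (closed interval).
#' @param min_obs minimum retained measurements for inclusion.
#' @return list with \code{series} (cleaned data frame, or \code{NULL} when
#'   excluded), \code{excluded} flag, and counts \code{n_input},
#'   \code{n_retained}, \code{n_dropped_age}, \code{n_dropped_neonatal}.
#' @export
clean_series <- function(series, max_age = 1125, neonatal_low = 1,
                         neonatal_high = 19, min_obs = 5) {
  stopifnot(all(c("age_days", "value") %in% names(series)))
  s <- series[order(series$age_days), , drop = FALSE]
  n_in <- nrow(s)
  old <- s$age_days > max_age
  s <- s[!old, , drop = FALSE]
  n_neo <- 0L
  is_weight <- "measure" %in% names(s) &&
    nrow(s) > 0 && s$measure[1L] == "weight"
  if (is_weight && nrow(s) > 0) {
    neo <- s$age_days >= neonatal_low & s$age_days <= neonatal_high
    birth <- which(s$age_days <= 1)
    if (length(birth)) neo[birth[1L]] <- FALSE  # birth record is exempt
    n_neo <- sum(neo)
    s <- s[!neo, , drop = FALSE]
  }
  excluded <- nrow(s) < min_obs
  rownames(s) <- NULL
  list(series = if (excluded) NULL else s,
       excluded = excluded,
       n_input = n_in,
       n_retained = nrow(s),
       n_dropped_age = sum(old),
       n_dropped_neonatal = n_neo)
}

#' Clean every subject of a cohort
#'
#' Applies \code{\link{clean_series}} per subject and assembles a cleaning
#' report.
#'
#' @param cohort a cohort data frame.
#' @param ... passed to \code{\link{clean_series}}.
#' @return list with \code{cohort} (retained rows of included subjects) and
#'   \code{report} (one row per input subject: drop counts and the
#'   \code{excluded} flag).
#' @export
clean_cohort <- function(cohort, ...) {
  series <- split_series(cohort)
  cleaned <- lapply(series, clean_series, ...)
  report <- data.frame(
    subject_id = names(series),
    n_input = vapply(cleaned, `[[`, integer(1), "n_input"),
    n_retained = vapply(cleaned, `[[`, integer(1), "n_retained"),
    n_dropped_age = vapply(cleaned, function(x) as.integer(x$n_dropped_age),
                           integer(1)),
    n_dropped_neonatal = vapply(cleaned,
                                function(x) as.integer(x$n_dropped_neonatal),
                                integer(1)),
    excluded = vapply(cleaned, `[[`, logical(1), "excluded"),
    row.names = NULL
  )
  kept <- do.call(rbind, lapply(cleaned, `[[`, "series"))
  rownames(kept) <- NULL
  list(cohort = kept, report = report)
}

#' Flag implausible measurements in a series
#'
#' An automated, advisory screen replacing manual review: flags (i) height
#' values lower than any earlier height by more than
#' \code{height_decrease_tol} cm (children do not shrink), and (ii) values
#' whose robust z-score — computed from the median and MAD of the residuals
#' about a running median of the series — exceeds \code{robust_z_cut}
#' (marked outliers). Removal is a downstream configuration choice; this
#' function only flags.
#'
#' @param series one subject's series data frame, sorted by age.
#' @param height_decrease_tol tolerated height decrease, cm.
#' @param robust_z_cut robust z-score cutoff.
#' @return integer vector of flagged row indices (possibly empty), with a
#'   \code{"reason"} character attribute parallel to it.
#' @export
flag_implausible <- function(series, height_decrease_tol = 0.5,
                             robust_z_cut = 5) {
  s <- series[order(series$age_days), , drop = FALSE]
  n <- nrow(s)
  flags <- integer(0)
  reasons <- character(0)
  is_height <- "measure" %in% names(s) && n > 0 && s$measure[1L] == "height"
  if (is_height && n >= 2) {
    cummax_prev <- cummax(s$value)
    drop_idx <- which(s$value < c(-Inf, cummax_prev[-n]) - height_decrease_tol)
    flags <- c(flags, drop_idx)
    reasons <- c(reasons, rep("height_decrease", length(drop_idx)))
  }
  if (n >= 5) {
    med <- stats::runmed(s$value, k = min(5L, n - (1 - n %% 2)))
    resid <- s$value - med
    scale <- stats::mad(resid)
    if (scale == 0) scale <- stats::IQR(resid) / 1.349
    # exact-fit series leave most residuals at zero; fall back to the mean
    # absolute deviation so a gross outlier is still detectable
    if (scale == 0) scale <- mean(abs(resid - stats::median(resid)))
    if (scale > 0) {
      z <- abs(resid - stats::median(resid)) / scale
      out_idx <- setdiff(which(z > robust_z_cut), flags)
      flags <- c(flags, out_idx)
      reasons <- c(reasons, rep("robust_outlier", length(out_idx)))
    }
  }
  ord <- order(flags)
  structure(flags[ord], reason = reasons[ord])
}
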