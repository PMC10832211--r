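# Baseline interpolators for the single-point holdout comparison. Each takes
# the holdout-filtered series (ages, values) and the holdout age, and returns
# one predicted value. The saturating-curve interpolator and any externally
# registered growth model share the same signature, so the holdout harness is
# method-agnostic.

#' Last-observation-carried-forward interpolation
#'
#' @param age,value the remaining (holdout-filtered) measurements.
#' @param at the holdout age, days.
#' @return value of the latest observation strictly before \code{at}.
#' @export
interpolate_locf <- function(age, value, at) {
  prior <- which(age < at)
  if (length(prior) == 0L) stop("no observation before the holdout age")
  value[prior[which.max(age[prior])]]
}

#' Simple linear interpolation by ordinary least squares
#'
#' Fits one straight line to all remaining points and evaluates it at the
#' holdout age.
#'
#' @inheritParams interpolate_locf
#' @return the fitted line's value at \code{at}.
#' @export
interpolate_linear <- function(age, value, at) {
  if (length(age) < 2L) stop("need at least 2 observations")
  if (stats::var(age) == 0) stop("zero age variance")
  fit <- stats::lm.fit(cbind(1, age), value)
  sum(fit$coefficients * c(1, at))
}

#' Smoother-based interpolation (LOESS or smoothing spline)
#'
#' Local quadratic regression (\code{loess}, default span 0.75) or a cubic
#' smoothing spline with generalized cross-validated penalty
#' (\code{smooth.spline}), evaluated at the holdout age. With fewer than 4
#' points the smoother is not identified and the function falls back to the
#' least-squares line with a warning.
#'
#' @inheritParams interpolate_locf
#' @param method \code{"loess"} or \code{"spline"}.
#' @param span loess span (ignored for splines).
#' @return predicted value at \code{at}.
#' @export
interpolate_smooth <- function(age, value, at,
                               method = c("loess", "spline"), span = 0.75) {
  method <- match.arg(method)
  if (length(unique(age)) < 4L) {
    warning("fewer than 4 distinct ages; falling back to linear interpolation")
    return(interpolate_linear(age, value, at))
  }
  if (method == "loess") {
    fit <- suppressWarnings(stats::loess(
      value ~ age, data.frame(age = age, value = value),
      span = span, degree = 2,
      control = stats::loess.control(surface = "direct")
    ))
    as.numeric(stats::predict(fit, data.frame(age = at)))
  } else {
    fit <- suppressWarnings(stats::smooth.spline(age, value, cv = FALSE))
    as.numeric(stats::predict(fit, at)$y)
  }
}

# Saturating-curve interpolator: refit on the remaining points, predict at
# the holdout age. Returns NA when the fit fails so the harness can drop the
# subject from every method's summary (paired comparison).
interpolate_mm <- function(age, value, at, measure = "weight",
                           control = mm_control()) {
  fit <- fit_mm(age, value, measure = measure, control = control)
  if (fit$status != "converged") return(NA_real_)
  mm_value(fit$params, at)
}

# The built-in method registry for holdout_experiment().
holdout_methods <- function(measure = "weight") {
  list(
    mm = function(age, value, at) interpolate_mm(age, value, at, measure),
    locf = interpolate_locf,
    linear = interpolate_linear,
    loess = function(age, value, at)
      interpolate_smooth(age, value, at, method = "loess"),
    spline = function(age, value, at)
      interpolate_smooth(age, value, at, method = "spline")
  )
}
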