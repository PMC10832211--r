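#' Fit the modified Michaelis-Menten curve to one measurement series
#'
#' Nonlinear least squares by plain Gauss-Newton with step-halving: at each
#' iteration the normal equations \eqn{J'J \delta = J'r} are solved and the
#' step is halved (up to \code{control$max_halvings} times) until the sum of
#' squared residuals does not increase. The objective is not convex and the
#' fit can fail in characteristic ways, each reported in \code{status}:
#' \describe{
#'   \item{\code{converged}}{relative SSE improvement or relative parameter
#'     step fell below tolerance; \code{params} present.}
#'   \item{\code{diverged_unbounded}}{\code{|a1|} or \code{|b1|} exceeded
#'     \code{control$divergence_bound} (or the SSE became non-finite); the
#'     signature of near-linear growth, where the saturating curve has no
#'     finite optimum.}
#'   \item{\code{singular}}{the normal equations could not be solved, or the
#'     iterations settled on a non-physical optimum (\code{a1 <= 0} or
#'     \code{b1 <= 0}).}
#'   \item{\code{max_iter}}{iteration budget exhausted without meeting a
#'     convergence test.}
#' }
#' Parameters are unconstrained during iteration; positivity of \code{a1} and
#' \code{b1} is checked after convergence only.
#'
#' @param age integer ages in days; at least 3 distinct values (protocol runs
#'   require 5 or more measurements). Duplicate ages are allowed and all
#'   enter the fit.
#' @param value positive sizes (kg or cm), same length as \code{age}.
#' @param start starting \code{c(a1, b1, c1)}; default taken from
#'   \code{\link{default_start}} for \code{measure}.
#' @param measure \code{"weight"} or \code{"height"}; selects the default
#'   start only.
#' @param control a \code{\link{mm_control}} list.
#' @param rescue if \code{TRUE} and the fit from the standard start fails,
#'   retry once from the higher rescue start
#'   (\code{default_start(measure, rescue = TRUE)}), which can salvage
#'   series lacking a birth record. Off by default.
#' @return an object of class \code{"mm_growth"}: a list with
#'   \code{params} (named triple, \code{NULL} unless converged),
#'   \code{status}, \code{iterations}, \code{sse}, \code{rmse},
#'   \code{residuals} (observed minus fitted), \code{fitted}, and the input
#'   \code{age}/\code{value}. The fit is deterministic for fixed input and
#'   control.
#' @seealso \code{\link{mm_growth}} for the formula interface,
#'   \code{\link{residual_profile}}, \code{\link{mm_value}}.
#' @examples
#' ages <- c(1, 60, 120, 240, 365, 545, 730, 1095)
#' fit <- fit_mm(ages, mm_value(c(a1 = 15, b1 = 400, c1 = 3.3), ages))
#' coef(fit)
#' @export
fit_mm <- function(age, value, start = NULL,
                   measure = c("weight", "height"), control = mm_control(),
                   rescue = FALSE) {
  measure <- match.arg(measure)
  if (rescue) {
    fit <- fit_mm(age, value, start = start, measure = measure,
                  control = control, rescue = FALSE)
    if (fit$status == "converged") return(fit)
    return(fit_mm(age, value, start = default_start(measure, rescue = TRUE),
                  measure = measure, control = control, rescue = FALSE))
  }
  age <- as.numeric(age)
  value <- as.numeric(value)
  if (length(age) != length(value)) stop("'age' and 'value' lengths differ")
  if (any(!is.finite(age)) || any(!is.finite(value)))
    stop("ages and values must be finite")
  if (any(value <= 0)) stop("values must be positive")
  if (length(unique(age)) < 3L)
    stop("at least 3 distinct ages are required to fit 3 parameters")
  if (is.null(start)) start <- default_start(measure)
  p <- as_mm_params(start)

  sse_at <- function(p) {
    r <- value - (p[3L] + p[1L] * age / (p[2L] + age))
    sum(r * r)
  }

  sse <- sse_at(p)
  status <- "max_iter"
  iter <- 0L
  bound <- control$divergence_bound

  for (iter in seq_len(control$max_iter)) {
    den <- p[2L] + age
    if (any(den == 0) || !is.finite(sse)) {
      status <- "diverged_unbounded"
      break
    }
    f <- age / den
    r <- value - (p[3L] + p[1L] * f)
    J <- cbind(f, -p[1L] * age / den^2, 1)
    # keep a very low tolerance: near-linear series make J'J ill-conditioned
    # long before the parameters blow up, and the unbounded growth must be
    # allowed to express itself rather than abort as a solve error
    step <- tryCatch(
      solve(crossprod(J), crossprod(J, r), tol = 1e-300),
      error = function(e) NULL
    )
    if (is.null(step) || any(!is.finite(step))) {
      status <- "singular"
      break
    }
    step <- as.numeric(step)

    lam <- 1
    accepted <- FALSE
    for (h in 0:control$max_halvings) {
      p_try <- p + lam * step
      sse_try <- sse_at(p_try)
      if (is.finite(sse_try) && sse_try <= sse) {
        accepted <- TRUE
        break
      }
      lam <- lam / 2
    }
    if (!accepted) {
      # no descent along the Gauss-Newton direction: stationary point
      status <- "converged"
      break
    }

    rel_impr <- (sse - sse_try) / max(sse, .Machine$double.xmin)
    rel_step <- max(abs(lam * step) / pmax(abs(p_try), 1e-8))
    p <- p_try
    sse <- sse_try
    if (abs(p[1L]) > bound || abs(p[2L]) > bound || !is.finite(sse)) {
      status <- "diverged_unbounded"
      break
    }
    if (rel_impr < control$tol_sse || rel_step < control$tol_step) {
      status <- "converged"
      break
    }
  }

  names(p) <- c("a1", "b1", "c1")
  if (status == "converged" &&
      (p[["a1"]] <= 0 || p[["b1"]] <= 0 || !is.finite(p[["c1"]]))) {
    # converged to a non-physical optimum; treat like a singular failure
    status <- "singular"
  }

  out <- list(
    params = NULL, status = status, iterations = iter,
    sse = NA_real_, rmse = NA_real_, residuals = NULL, fitted = NULL,
    age = age, value = value, measure = measure,
    start = as_mm_params(start), control = control,
    call = match.call()
  )
  if (status == "converged") {
    fitted <- mm_value(p, age)
    out$params <- p
    out$sse <- sse
    out$residuals <- value - fitted
    out$fitted <- fitted
    out$rmse <- rmse(out$residuals)
  }
  class(out) <- "mm_growth"
  out
}

#' Formula interface for the modified Michaelis-Menten growth fit
#'
#' A thin wrapper around \code{\link{fit_mm}} in the style of classical R
#' model fitters: \code{mm_growth(value ~ age_days, data = baby)}.
#'
#' @param formula a two-sided formula, size on the left and age in days on
#'   the right.
#' @param data a data frame containing the formula variables.
#' @param ... passed on to \code{\link{fit_mm}} (\code{start},
#'   \code{measure}, \code{control}).
#' @return an object of class \code{"mm_growth"}; see \code{\link{fit_mm}}.
#' @examples
#' d <- data.frame(age_days = c(1, 60, 180, 365, 730, 1095),
#'                 weight_kg = c(3.4, 6.1, 8.0, 9.7, 11.7, 13.1))
#' fit <- mm_growth(weight_kg ~ age_days, d)
#' summary(fit)
#' @export
mm_growth <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  if (ncol(mf) != 2L) stop("formula must be of the form value ~ age")
  fit <- fit_mm(age = mf[[2L]], value = mf[[1L]], ...)
  fit$call <- match.call()
  fit
}

#' Per-measurement residual profile of a converged fit
#'
#' Returns one \code{(age, residual)} row per measurement (residual =
#' observed - predicted), optionally aggregated into age bins as the RMSE of
#' each bin, for RMSE-versus-age displays.
#'
#' @param fit a converged \code{"mm_growth"} object.
#' @param bins optional numeric vector of age-bin breakpoints (days); when
#'   supplied the result also carries a \code{"by_bin"} attribute with one
#'   RMSE per non-empty bin.
#' @return a data frame with columns \code{age} and \code{residual}, ordered
#'   by age.
#' @export
residual_profile <- function(fit, bins = NULL) {
  stopifnot(inherits(fit, "mm_growth"))
  if (fit$status != "converged") stop("fit did not converge; no residuals")
  ord <- order(fit$age)
  out <- data.frame(age = fit$age[ord], residual = fit$residuals[ord])
  if (!is.null(bins)) {
    grp <- cut(out$age, breaks = bins, include.lowest = TRUE)
    by_bin <- vapply(split(out$residual, grp, drop = TRUE), rmse, numeric(1))
    attr(out, "by_bin") <- by_bin
  }
  out
}
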