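#' The modified Michaelis-Menten growth curve
#'
#' Evaluates the saturating growth curve
#' \deqn{P(t) = c_1 + a_1 \frac{t}{b_1 + t}}{P(t) = c1 + a1 * t / (b1 + t)}
#' at ages \code{age} (days since birth). \code{c1} is the curve's value at
#' age 0 and empirically approximates birth weight (kg) or birth length (cm);
#' \code{a1} is the asymptotic gain above birth size, so the curve saturates
#' at \code{a1 + c1}; \code{b1} is the half-saturation age, the age in days
#' at which half of \code{a1} has been attained.
#'
#' @param params named numeric vector (or list) with elements \code{a1},
#'   \code{b1}, \code{c1}. An unnamed length-3 vector is taken in that order.
#' @param age numeric vector of ages in days, all \code{>= 0}.
#' @return numeric vector of predicted sizes, in the units of \code{a1}/
#'   \code{c1} (kg for weight, cm for height).
#' @examples
#' mm_value(c(a1 = 14.1, b1 = 393, c1 = 3.40), age = c(0, 365))
#' @export
mm_value <- function(params, age) {
  p <- as_mm_params(params)
  if (any(age < 0)) stop("'age' must be non-negative")
  den <- p[["b1"]] + age
  if (any(den == 0)) stop("curve undefined at age = -b1")
  p[["c1"]] + p[["a1"]] * age / den
}

# Coerce list/vector input to a named (a1, b1, c1) numeric triple.
as_mm_params <- function(params) {
  p <- unlist(params, use.names = TRUE)
  if (length(p) != 3L) stop("'params' must supply exactly a1, b1, c1")
  if (is.null(names(p)) || !all(c("a1", "b1", "c1") %in% names(p))) {
    names(p) <- c("a1", "b1", "c1")
  }
  storage.mode(p) <- "double"
  p[c("a1", "b1", "c1")]
}

#' Default nonlinear least-squares starting values
#'
#' The starting triples used for curve fitting: \code{(a1 = 5, b1 = 20,
#' c1 = 2.5)} for weight and \code{(a1 = 60, b1 = 530, c1 = 50)} for height.
#' These were tuned (on real cohort data, in the original analyses) to
#' minimise fit failures; higher starts give similar parameter estimates but
#' fail more often on near-linear series.
#'
#' When a series lacks a birth record the fit can sometimes be rescued by
#' starting closer to typical population values; \code{rescue = TRUE} returns
#' \code{(a1 = 15, b1 = 500)} with the default weight intercept. No rescue
#' variant is defined for height, where the standard start is returned.
#'
#' @param measure \code{"weight"} or \code{"height"}.
#' @param rescue logical; use the higher rescue start (weight only).
#' @return named numeric vector \code{c(a1, b1, c1)}.
#' @export
default_start <- function(measure = c("weight", "height"), rescue = FALSE) {
  measure <- match.arg(measure)
  if (measure == "weight") {
    if (rescue) c(a1 = 15, b1 = 500, c1 = 2.5) else c(a1 = 5, b1 = 20, c1 = 2.5)
  } else {
    c(a1 = 60, b1 = 530, c1 = 50)
  }
}

#' Root-mean-squared error
#'
#' \code{sqrt(mean(x^2))}, with denominator \code{n} (no degrees-of-freedom
#' correction). Units are those of the residuals (kg or cm).
#'
#' @param residuals non-empty numeric vector of residuals.
#' @return a single number.
#' @export
rmse <- function(residuals) {
  if (length(residuals) == 0L) stop("'residuals' must be non-empty")
  if (any(!is.finite(residuals))) stop("'residuals' must be finite")
  sqrt(mean(residuals^2))
}

#' Control parameters for the Gauss-Newton fitter
#'
#' @param max_iter maximum Gauss-Newton iterations.
#' @param tol_sse convergence when the relative sum-of-squares improvement in
#'   one accepted step falls below this.
#' @param tol_step convergence when the largest relative parameter change in
#'   one accepted step falls below this.
#' @param divergence_bound magnitude of \code{a1} or \code{b1} (fit units /
#'   days) beyond which the fit is declared unbounded; near-linear series
#'   drive both parameters jointly to infinity.
#' @param max_halvings step-halving attempts per iteration before the search
#'   gives up on descending.
#' @return a list of class \code{"mm_control"}.
#' @export
mm_control <- function(max_iter = 50L, tol_sse = 1e-10, tol_step = 1e-8,
                       divergence_bound = 1e7, max_halvings = 10L) {
  stopifnot(max_iter >= 1L, tol_sse > 0, tol_step > 0, divergence_bound > 0,
            max_halvings >= 0L)
  structure(list(max_iter = as.integer(max_iter), tol_sse = tol_sse,
                 tol_step = tol_step, divergence_bound = divergence_bound,
                 max_halvings = as.integer(max_halvings)),
            class = "mm_control")
}
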