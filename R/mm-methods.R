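#' @export
print.mm_growth <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat("Modified Michaelis-Menten growth fit (", x$measure, ")\n", sep = "")
  cat("Status:", x$status, "after", x$iterations, "iterations\n")
  if (x$status == "converged") {
    cat("Parameters:\n")
    print(signif(x$params, digits))
    cat("RMSE:", signif(x$rmse, digits), "on", length(x$value),
        "measurements\n")
  } else {
    cat("No parameters (fit failed)\n")
  }
  invisible(x)
}

#' @export
coef.mm_growth <- function(object, ...) object$params

#' @export
fitted.mm_growth <- function(object, ...) object$fitted

#' @export
residuals.mm_growth <- function(object, ...) object$residuals

#' Predict size at new ages from a fitted growth curve
#'
#' @param object a converged \code{"mm_growth"} fit.
#' @param newdata data frame holding an age column (first numeric column
#'   used), or \code{NULL} for the fitted ages.
#' @param ages numeric vector of ages in days; overrides \code{newdata}.
#' @param ... unused.
#' @return numeric vector of predicted sizes (kg or cm).
#' @export
predict.mm_growth <- function(object, newdata = NULL, ages = NULL, ...) {
  if (object$status != "converged")
    stop("cannot predict from a fit with status '", object$status, "'")
  if (is.null(ages)) {
    ages <- if (is.null(newdata)) object$age else {
      num <- vapply(newdata, is.numeric, logical(1))
      if (!any(num)) stop("'newdata' has no numeric age column")
      newdata[[which(num)[1L]]]
    }
  }
  mm_value(object$params, ages)
}

#' @export
summary.mm_growth <- function(object, ...) {
  out <- list(
    call = object$call, status = object$status,
    iterations = object$iterations, params = object$params,
    n = length(object$value), rmse = object$rmse, sse = object$sse,
    asymptote = if (!is.null(object$params))
      unname(object$params["a1"] + object$params["c1"]) else NA_real_,
    resid_summary = if (!is.null(object$residuals))
      summary(object$residuals) else NULL,
    measure = object$measure
  )
  class(out) <- "summary.mm_growth"
  out
}

#' @export
print.summary.mm_growth <- function(x, digits = 4L, ...) {
  cat("Call:\n"); print(x$call)
  cat("\nStatus:", x$status, "(", x$iterations, "iterations, n =", x$n, ")\n")
  if (x$status == "converged") {
    cat("\nParameters (", if (x$measure == "weight") "kg / days" else "cm / days",
        "):\n", sep = "")
    print(signif(x$params, digits))
    cat("Predicted birth size (c1):", signif(x$params[["c1"]], digits), "\n")
    cat("Predicted adult-asymptote (a1 + c1):", signif(x$asymptote, digits), "\n")
    cat("RMSE:", signif(x$rmse, digits), "\n")
    cat("\nResiduals:\n"); print(signif(x$resid_summary, digits))
  }
  invisible(x)
}

#' Plot a fitted growth curve over the observations
#'
#' @param x a \code{"mm_growth"} object (converged or not; observations are
#'   always shown).
#' @param ... passed to \code{plot}.
#' @export
plot.mm_growth <- function(x, ...) {
  ylab <- if (x$measure == "weight") "weight (kg)" else "height (cm)"
  graphics::plot(x$age, x$value, xlab = "age (days)", ylab = ylab, ...)
  if (x$status == "converged") {
    grid <- seq(min(x$age), max(x$age), length.out = 200)
    graphics::lines(grid, mm_value(x$params, grid), col = "red")
  }
  invisible(x)
}

#' Simulate replicate measurement series from a fitted curve
#'
#' Draws \code{nsim} noisy replicates of the fitted series: curve values at
#' the original ages plus iid Gaussian noise with standard deviation
#' \code{noise_sd} (defaulting to the fit's RMSE), floored at 0.1 units.
#'
#' @param object a converged \code{"mm_growth"} fit.
#' @param nsim number of replicate series.
#' @param seed optional integer seed (restores the RNG state afterwards).
#' @param noise_sd measurement noise sd, kg or cm.
#' @param ... unused.
#' @return a data frame with one column per replicate, ages as row attribute
#'   \code{"age"}.
#' @export
simulate.mm_growth <- function(object, nsim = 1, seed = NULL,
                               noise_sd = object$rmse, ...) {
  if (object$status != "converged") stop("fit did not converge")
  sim <- function() {
    mu <- mm_value(object$params, object$age)
    data.frame(replicate(nsim, pmax(mu + stats::rnorm(length(mu), 0, noise_sd), 0.1)))
  }
  out <- if (is.null(seed)) sim() else with_seed(seed, sim())
  names(out) <- paste0("sim_", seq_len(nsim))
  attr(out, "age") <- object$age
  out
}
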