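# Shared fixtures and the brute-force SSE oracle, independent of the
# package's Gauss-Newton path.

# A 12-point age grid resembling the well-baby schedule.
fixture_ages <- function() c(1, 32, 61, 120, 190, 274, 365, 450, 550, 720, 912, 1075)

# Noise-free series on the saturating curve.
exact_series <- function(params, ages = fixture_ages()) {
  data.frame(age_days = ages, value = mm_value(params, ages))
}

# Noisy series from known parameters under a local seed.
noisy_series <- function(params, sd = 0.2, ages = fixture_ages(), seed = 1) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  data.frame(age_days = ages,
             value = pmax(mm_value(params, ages) + rnorm(length(ages), 0, sd),
                          0.1))
}

# Brute-force SSE minimum: dense (a1, b1) grid with c1 profiled out by
# linear least squares (for fixed a1, b1 the model is linear in c1), then a
# local polish with stats::optim from the best grid point. Never touches
# the package's fitter.
oracle_sse <- function(age, value,
                       a1_grid = seq(0.5, 45, length.out = 70),
                       b1_grid = exp(seq(log(10), log(8000), length.out = 70))) {
  prof <- function(a1, b1) {
    f <- age / (b1 + age)
    c1 <- mean(value - a1 * f)
    sum((value - a1 * f - c1)^2)
  }
  best <- c(NA, NA, Inf)
  for (a1 in a1_grid) for (b1 in b1_grid) {
    s <- prof(a1, b1)
    if (s < best[3L]) best <- c(a1, b1, s)
  }
  obj <- function(p) prof(p[1L], p[2L])
  pol <- stats::optim(best[1:2], obj,
                      control = list(reltol = 1e-15, maxit = 5000))
  pol <- stats::optim(pol$par, obj, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 1000))
  pol$value
}

# Small cohort data frame assembled by hand.
toy_cohort <- function() {
  mk <- function(id, sex, ages, vals)
    data.frame(subject_id = id, sex = sex, measure = "weight",
               age_days = ages, value = vals)
  p1 <- c(a1 = 14, b1 = 380, c1 = 3.4)
  p2 <- c(a1 = 16, b1 = 450, c1 = 3.1)
  p3 <- c(a1 = 12, b1 = 300, c1 = 3.7)
  rbind(
    mk("A", "male", fixture_ages(), mm_value(p1, fixture_ages())),
    mk("B", "female", fixture_ages(), mm_value(p2, fixture_ages())),
    mk("C", "male", fixture_ages(), mm_value(p3, fixture_ages()))
  )
}
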