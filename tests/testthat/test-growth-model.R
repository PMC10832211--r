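test_that("the saturating curve evaluates, saturates and stays monotone", {
  p <- c(a1 = 14.1, b1 = 393, c1 = 3.40)
  expect_identical(mm_value(p, 0), 3.40)
  expect_equal(mm_value(p, 365), 14.1 * 365 / (393 + 365) + 3.40)
  expect_equal(mm_value(p, 365), 10.1895778364116, tolerance = 1e-12)
  # asymptote a1 + c1
  ph <- c(a1 = 62.0, b1 = 502, c1 = 51.0)
  expect_equal(mm_value(ph, 1e12), 113.0, tolerance = 1e-6)
  expect_lt(mm_value(ph, 1e5), 113.0)
  # monotone nondecreasing in age for positive a1, b1, on random draws
  set.seed(11)
  for (i in 1:20) {
    pr <- c(a1 = runif(1, 1, 60), b1 = runif(1, 10, 2000),
            c1 = runif(1, 2, 55))
    v <- mm_value(pr, sort(runif(50, 0, 1200)))
    expect_true(all(diff(v) >= 0))
    expect_true(all(v <= pr[["a1"]] + pr[["c1"]]))
  }
  expect_error(mm_value(c(a1 = 5, b1 = -100, c1 = 2), 100), "undefined")
  expect_error(mm_value(p, -1), "non-negative")
})

test_that("default starting values match the published triples", {
  expect_equal(default_start("weight"), c(a1 = 5, b1 = 20, c1 = 2.5))
  expect_equal(default_start("height"), c(a1 = 60, b1 = 530, c1 = 50))
  expect_equal(default_start("weight", rescue = TRUE),
               c(a1 = 15, b1 = 500, c1 = 2.5))
  expect_error(default_start("bmi"))
})

test_that("rmse is the plain root-mean-square with denominator n", {
  expect_identical(rmse(c(0, 0, 0)), 0)
  expect_equal(rmse(c(3, 4)), sqrt(12.5))
  expect_identical(rmse(-2), 2)
  expect_error(rmse(numeric(0)), "non-empty")
})

test_that("noise-free series are recovered to near machine precision", {
  truth <- c(a1 = 15, b1 = 400, c1 = 3.3)
  ages <- c(1, 60, 120, 240, 365, 545, 730, 1095)
  fit <- fit_mm(ages, mm_value(truth, ages))
  expect_identical(fit$status, "converged")
  expect_lt(max(abs(fit$params - truth) / truth), 1e-6)
  expect_lt(fit$rmse, 1e-8)
  expect_true(all(abs(residuals(fit)) < 1e-8))
})

test_that("pure linear growth drives the parameters out of bounds", {
  ages <- c(1, 60, 120, 240, 365, 545, 730, 1095)
  fit <- fit_mm(ages, 3.3 + 0.01 * ages)
  expect_identical(fit$status, "diverged_unbounded")
  expect_null(fit$params)
  expect_null(coef(fit))
})

test_that("fits are deterministic and converge to stationary points", {
  truth <- c(a1 = 14, b1 = 420, c1 = 3.4)
  d <- noisy_series(truth, sd = 0.2, seed = 5)
  f1 <- fit_mm(d$age_days, d$value)
  f2 <- fit_mm(d$age_days, d$value)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$iterations, f2$iterations)
  # gradient condition J'r ~ 0 at the optimum, across several instances
  for (seed in 1:10) {
    d <- noisy_series(truth, sd = 0.2, seed = seed)
    f <- fit_mm(d$age_days, d$value)
    expect_identical(f$status, "converged")
    p <- f$params
    den <- p[["b1"]] + d$age_days
    J <- cbind(d$age_days / den, -p[["a1"]] * d$age_days / den^2, 1)
    g <- abs(crossprod(J, f$residuals))
    expect_lt(max(g), 1e-6 * sqrt(sum(f$residuals^2)))
  }
})

test_that("converged SSE matches the grid+polish brute-force oracle", {
  set.seed(21)
  for (i in 1:5) {
    n <- sample(5:12, 1)
    truth <- c(a1 = runif(1, 8, 25), b1 = runif(1, 100, 900),
               c1 = runif(1, 2.5, 4.5))
    ages <- sort(c(1, sample(20:1125, n - 1)))
    value <- pmax(mm_value(truth, ages) + rnorm(n, 0, 0.2), 0.1)
    fit <- fit_mm(ages, value)
    expect_identical(fit$status, "converged")
    expect_equal(fit$sse, oracle_sse(ages, value), tolerance = 1e-6)
  }
})

test_that("the fit agrees with nls on a well-behaved noisy series", {
  d <- noisy_series(c(a1 = 14, b1 = 400, c1 = 3.4), sd = 0.15, seed = 9)
  fit <- fit_mm(d$age_days, d$value)
  ref <- nls(value ~ c1 + a1 * age_days / (b1 + age_days), data = d,
             start = list(a1 = 5, b1 = 20, c1 = 2.5))
  expect_equal(fit$sse, sum(resid(ref)^2), tolerance = 1e-8)
  expect_equal(unname(fit$params), unname(coef(ref)[c("a1", "b1", "c1")]),
               tolerance = 1e-4)
})

test_that("rescaling the values rescales a1, c1 and RMSE but not b1", {
  truth <- c(a1 = 15, b1 = 400, c1 = 3.3)
  d <- exact_series(truth)
  f1 <- fit_mm(d$age_days, d$value)
  k <- 2.2
  f2 <- fit_mm(d$age_days, k * d$value)
  expect_equal(f2$params[["a1"]], k * f1$params[["a1"]], tolerance = 1e-6)
  expect_equal(f2$params[["c1"]], k * f1$params[["c1"]], tolerance = 1e-6)
  expect_equal(f2$params[["b1"]], f1$params[["b1"]], tolerance = 1e-6)
})

test_that("input validation rejects degenerate series", {
  expect_error(fit_mm(c(1, 1, 1), c(3, 3.1, 3.2)), "distinct ages")
  expect_error(fit_mm(c(1, 2, NA), c(3, 3, 3)), "finite")
  expect_error(fit_mm(c(1, 60, 365), c(3, -1, 9)), "positive")
})

test_that("residual profile has one entry per point and is order-invariant", {
  truth <- c(a1 = 15, b1 = 400, c1 = 3.3)
  d <- exact_series(truth)
  f <- fit_mm(d$age_days, d$value)
  prof <- residual_profile(f)
  expect_identical(nrow(prof), nrow(d))
  expect_true(all(abs(prof$residual) < 1e-8))
  # a single perturbed observation dominates the profile
  d2 <- d
  j <- 6
  d2$value[j] <- d2$value[j] + 0.5
  f2 <- fit_mm(d2$age_days, d2$value)
  prof2 <- residual_profile(f2)
  expect_identical(prof2$age[which.max(abs(prof2$residual))], d$age_days[j])
  # permuting the inputs leaves the age-indexed profile unchanged
  perm <- sample(nrow(d2))
  f3 <- fit_mm(d2$age_days[perm], d2$value[perm])
  prof3 <- residual_profile(f3)
  expect_equal(prof3, prof2, tolerance = 1e-9)
  # binned aggregation returns an RMSE per non-empty bin
  prof_b <- residual_profile(f2, bins = c(0, 365, 730, 1125))
  expect_length(attr(prof_b, "by_bin"), 3L)
  # profile requires convergence
  flin <- fit_mm(d$age_days, 3 + 0.01 * d$age_days)
  expect_error(residual_profile(flin), "converge")
})

test_that("rescue start can salvage a series lacking its birth record", {
  # drop the birth record: the standard low start must fail, the rescue
  # start (tried automatically with rescue = TRUE) recovers the subject
  truth <- c(a1 = 16, b1 = 650, c1 = 3.2)
  set.seed(33)
  found <- FALSE
  for (i in 1:50) {
    ages <- sort(sample(150:1125, 8))
    value <- pmax(mm_value(truth, ages) + rnorm(8, 0, 0.2), 0.1)
    f0 <- fit_mm(ages, value)
    if (f0$status != "converged") {
      f1 <- fit_mm(ages, value, rescue = TRUE)
      expect_identical(f1$start, default_start("weight", rescue = TRUE))
      found <- TRUE
      break
    }
  }
  expect_true(found)
})
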