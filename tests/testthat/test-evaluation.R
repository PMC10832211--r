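test_that("LOCF returns the latest prior observation", {
  expect_identical(interpolate_locf(c(30, 365), c(4.0, 9.0), 120), 4.0)
  expect_identical(interpolate_locf(c(30, 365), c(4.0, 9.0), 400), 9.0)
  expect_error(interpolate_locf(c(30, 365), c(4, 9), 10), "before")
})

test_that("linear interpolation is exact OLS and order-invariant", {
  expect_equal(interpolate_linear(c(0, 100), c(3.0, 5.0), 50), 4.0)
  ages <- c(10, 300, 150, 700, 45)
  vals <- 3 + 0.01 * ages
  expect_equal(interpolate_linear(ages, vals, 222), 3 + 0.01 * 222)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(interpolate_linear(ages[perm], vals[perm], 222),
               interpolate_linear(ages, vals, 222))
  expect_error(interpolate_linear(5, 3, 10), "at least 2")
  expect_error(interpolate_linear(c(5, 5), c(3, 4), 10), "variance")
})

test_that("smoothers preserve collinear data and fall back when starved", {
  ages <- c(10, 100, 250, 420, 600, 800)
  vals <- 3 + 0.01 * ages
  expect_equal(interpolate_smooth(ages, vals, 333, "loess"), 3 + 0.01 * 333,
               tolerance = 1e-6)
  expect_equal(interpolate_smooth(ages, vals, 333, "spline"), 3 + 0.01 * 333,
               tolerance = 1e-6)
  expect_warning(
    out <- interpolate_smooth(c(0, 100, 200), c(3, 4, 5), 150),
    "falling back")
  expect_equal(out, 4.5)
})

test_that("on noise-free saturating data the curve interpolator beats the baselines", {
  truth <- c(a1 = 15, b1 = 420, c1 = 3.3)
  d <- exact_series(truth)
  j <- 7  # interior holdout
  at <- d$age_days[j]
  age_r <- d$age_days[-j]; val_r <- d$value[-j]
  err <- function(x) abs(x - d$value[j])
  e_mm <- err(mm_value(fit_mm(age_r, val_r)$params, at))
  expect_lt(e_mm, 1e-8)
  expect_lt(e_mm, err(interpolate_locf(age_r, val_r, at)))
  expect_lt(err(interpolate_smooth(age_r, val_r, at, "loess")),
            err(interpolate_locf(age_r, val_r, at)))
})

test_that("RMSE summaries follow the linear-interpolation quantile convention", {
  s <- summarize_rmse(c(0.3, 0.3, 0.3))
  expect_identical(s$mean, 0.3)
  expect_identical(s$median, 0.3)
  expect_identical(s$sd, 0)
  expect_identical(s$iqr, 0)
  s2 <- summarize_rmse(c(1, 2, 3, 4))
  expect_equal(s2$median, 2.5)
  expect_equal(s2$iqr, 1.5)
  expect_equal(s2$p90, 3.7)
  # permutation invariance
  x <- c(0.1, 0.5, 0.22, 0.9, 0.31, 0.18)
  expect_equal(unclass(summarize_rmse(x)), unclass(summarize_rmse(rev(x))))
  expect_error(summarize_rmse(numeric(0)), "empty")
})

test_that("Spearman correlation of c1 with birth size behaves at the extremes", {
  expect_equal(c1_birth_correlation(1:10, (1:10)^2), 1)
  expect_equal(c1_birth_correlation(1:10, -(1:10)), -1)
  expect_error(c1_birth_correlation(1:2, 1:2), "at least 3")
  expect_error(c1_birth_correlation(rep(1, 5), 1:5), "variance")
  expect_error(c1_birth_correlation(1:4, 1:5), "paired")
})

test_that("holdout selection is seeded, method-independent and paired", {
  cfg <- cohort_config(n_subjects = 40, seed = 3)
  co <- generate_cohort(cfg)$cohort
  h1 <- holdout_experiment(co, methods = c("mm", "locf"), seed = 99)
  h2 <- holdout_experiment(co, methods = c("locf", "linear", "mm"), seed = 99)
  # identical holdout choices whatever the method list
  expect_identical(h1$holdouts, h2$holdouts)
  # rerun with the same seed reproduces the summaries exactly
  h3 <- holdout_experiment(co, methods = c("mm", "locf"), seed = 99)
  expect_identical(h1$summaries, h3$summaries)
  # a different seed picks different holdouts
  h4 <- holdout_experiment(co, methods = "locf", seed = 100)
  expect_false(identical(h1$holdouts$age_days, h4$holdouts$age_days))
  # every method is summarized over the same subjects (paired comparison)
  tab <- table(h1$per_subject$method)
  expect_true(all(tab == tab[1L]))
  # conservation of subjects
  n_series <- length(split_series(co))
  expect_identical(nrow(h1$holdouts) + h1$n_failures, n_series - h1$n_ineligible)
  expect_error(holdout_experiment(co, methods = "sitar"), "unknown method")
})

test_that("holdout errors vanish on noise-free curve data", {
  cfg <- cohort_config(n_subjects = 25, noise_sd = 0, visit_missingness = 0,
                       linear_grower_fraction = 0, seed = 8)
  co <- generate_cohort(cfg)$cohort
  h <- holdout_experiment(co, methods = c("mm", "locf"), seed = 1234)
  expect_lt(h$summaries$mm$mean, 1e-6)
  expect_lt(h$summaries$mm$mean, h$summaries$locf$mean)
})

test_that("the empty drop-set changes nothing and dropped visits degrade imputation", {
  cfg <- cohort_config(n_subjects = 25, visit_missingness = 0,
                       linear_grower_fraction = 0, seed = 12)
  co <- generate_cohort(cfg)$cohort
  res <- imputation_experiment(co, subset = 7, max_drop = 1)
  expect_identical(res$delta_rmse[res$n_dropped == 0], 0)
  expect_identical(nrow(res), 8L)  # empty set + 7 single drops
  expect_true(all(res$n_subjects + res$n_failures + res$n_degenerate ==
                    attr(res, "n_subjects_in")))
  # on noise-free data any single-visit drop that keeps the birth record
  # leaves the model identifiable: delta stays essentially zero
  res0 <- imputation_experiment(
    generate_cohort(cohort_config(n_subjects = 10, noise_sd = 0,
                                  visit_missingness = 0,
                                  linear_grower_fraction = 0,
                                  seed = 4))$cohort,
    subset = 7, max_drop = 1)
  others <- res0$n_dropped == 1 & res0$dropped != "1"
  expect_true(all(abs(res0$delta_rmse[others]) < 1e-6))
  expect_error(imputation_experiment(co, subset = 9), "7 or 12")
})

test_that("last-value prediction is exact for noise-free subjects and windows nest", {
  cfg <- cohort_config(n_subjects = 20, noise_sd = 0, visit_missingness = 0,
                       linear_grower_fraction = 0, seed = 5)
  co <- generate_cohort(cfg)$cohort
  p1 <- prediction_experiment(co, "Y1")
  expect_true(all(p1$rmse < 1e-6))
  expect_identical(unique(p1$eval_window), "Y2-3")
  # subject conservation
  n_in <- length(split_series(co))
  expect_identical(length(unique(p1$subject_id)) + attr(p1, "n_failures") +
                     attr(p1, "n_ineligible"), n_in)
  # noisy cohort: error grows as the fit window shrinks
  cfgn <- cohort_config(n_subjects = 60, visit_missingness = 0,
                        linear_grower_fraction = 0, seed = 6)
  con <- generate_cohort(cfgn)$cohort
  tab <- prediction_table(con)
  m <- function(fw, ew) tab$mean[tab$fit_window == fw & tab$eval_window == ew]
  expect_lte(m("Y1-3", "Y1-3"), m("Y1+Y2", "Y3"))
  expect_lte(m("Y1+Y2", "Y3"), m("Y1", "Y2-3"))
  expect_identical(nrow(tab), 5L)
})

test_that("eligibility rules exclude subjects with sparse later years", {
  co <- toy_cohort()
  # strip C's year-3 points: C becomes ineligible
  co <- co[!(co$subject_id == "C" & co$age_days > 730), ]
  p <- prediction_experiment(co, "Y1+Y2")
  expect_false("C" %in% p$subject_id)
  expect_identical(attr(p, "n_ineligible"), 1L)
})
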