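# lognormal sdlog whose central 50% spread matches a target IQR around a
# target median: IQR = median * 2*sinh(z75 * sdlog), z75 = qnorm(0.75)
lnorm_sdlog <- function(median, iqr) {
  asinh(iqr / (2 * median)) / stats::qnorm(0.75)
}

# Per-sex marginal parameter distributions calibrated to the reported
# population medians/IQRs for each measure: a1 and b1 are right-skewed
# (log-normal), c1 is normal and approximates birth size.
default_param_distributions <- function(measure) {
  if (measure == "weight") {
    list(
      male = list(a1 = c(meanlog = log(14.1), sdlog = lnorm_sdlog(14.1, 5.77)),
                  b1 = c(meanlog = log(393), sdlog = lnorm_sdlog(393, 327)),
                  c1 = c(mean = 3.35, sd = 0.5)),
      female = list(a1 = c(meanlog = log(14.7), sdlog = lnorm_sdlog(14.7, 6.77)),
                    b1 = c(meanlog = log(499), sdlog = lnorm_sdlog(499, 425)),
                    c1 = c(mean = 3.24, sd = 0.5))
    )
  } else {
    list(
      male = list(a1 = c(meanlog = log(62.0), sdlog = lnorm_sdlog(62.0, 17.7)),
                  b1 = c(meanlog = log(502), sdlog = lnorm_sdlog(502, 266)),
                  c1 = c(mean = 51.0, sd = 2.5)),
      female = list(a1 = c(meanlog = log(64.5), sdlog = lnorm_sdlog(64.5, 19.6)),
                    b1 = c(meanlog = log(547), sdlog = lnorm_sdlog(547, 320)),
                    c1 = c(mean = 50.5, sd = 2.5))
    )
  }
}

#' Configuration of a synthetic growth cohort
#'
#' Collects every knob of the generator. Defaults emulate a large outpatient
#' pediatric sample: per-sex (a1, b1, c1) distributions calibrated to the
#' reported population medians and IQRs, visit times drawn inside the 12
#' well-baby windows, about one measurement in five missing, homoscedastic
#' Gaussian measurement noise (0.2 kg for weight, 1.0 cm for height), and a
#' small fraction (1\%) of linear growers that defeat the saturating model.
#'
#' @param n_subjects cohort size.
#' @param measure \code{"weight"} or \code{"height"}.
#' @param sex_ratio proportion male.
#' @param noise_sd measurement noise sd (kg or cm); \code{NULL} uses the
#'   measure default.
#' @param visit_missingness per-visit independent drop probability for
#'   visits 2-12.
#' @param birth_missingness drop probability for the birth record (visit 1).
#'   Defaults to 0: birth size comes from the delivery record, which is
#'   present for essentially every child followed from birth, unlike a
#'   well-baby visit that can be skipped.
#' @param linear_grower_fraction fraction of subjects growing linearly;
#'   assigned as an exact count (\code{floor(n * fraction)}) stratified
#'   along the subject index, not by coin flips, so fixture counts are
#'   deterministic.
#' @param rank_correlation target Spearman correlation of c1 with a1 and
#'   with b1 (coupled through a Gaussian copula).
#' @param a1_b1_latent_cor latent correlation between a1 and b1 (larger
#'   asymptotes tend to be reached later).
#' @param age_proportional_noise if \code{TRUE}, noise sd grows linearly to
#'   twice its value at 36 months (robustness switch; the default is
#'   homoscedastic).
#' @param param_distributions per-sex marginals, as produced by the defaults;
#'   override to change locations/scales.
#' @param schedule visit windows.
#' @param seed master integer seed; every draw derives from it.
#' @return a list of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n_subjects = 500, measure = c("weight", "height"),
                          sex_ratio = 0.5, noise_sd = NULL,
                          visit_missingness = 0.2, birth_missingness = 0,
                          linear_grower_fraction = 0.01,
                          rank_correlation = 0.30,
                          a1_b1_latent_cor = 0.5,
                          age_proportional_noise = FALSE,
                          param_distributions = NULL,
                          schedule = visit_schedule(), seed = 1) {
  measure <- match.arg(measure)
  if (is.null(noise_sd)) noise_sd <- if (measure == "weight") 0.2 else 1.0
  stopifnot(n_subjects >= 1, sex_ratio >= 0, sex_ratio <= 1,
            noise_sd >= 0, visit_missingness >= 0, visit_missingness < 1,
            birth_missingness >= 0, birth_missingness < 1,
            linear_grower_fraction >= 0, linear_grower_fraction <= 1)
  if (is.null(param_distributions))
    param_distributions <- default_param_distributions(measure)
  structure(list(
    n_subjects = as.integer(n_subjects), measure = measure,
    sex_ratio = sex_ratio, noise_sd = noise_sd,
    visit_missingness = visit_missingness,
    birth_missingness = birth_missingness,
    linear_grower_fraction = linear_grower_fraction,
    rank_correlation = rank_correlation,
    a1_b1_latent_cor = a1_b1_latent_cor,
    age_proportional_noise = age_proportional_noise,
    param_distributions = param_distributions,
    schedule = schedule, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Draw per-child curve parameters
#'
#' Samples \code{n} (a1, b1, c1) triples for one sex: a1 and b1 log-normal,
#' c1 normal, coupled by a Gaussian copula so that c1 (birth size) has the
#' configured rank correlation with both a1 and b1. Rank correlations
#' survive the monotone marginal transforms, so the latent Pearson
#' correlation is set to \code{2*sin(pi*rho/6)}.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param sex \code{"male"} or \code{"female"}.
#' @param n number of draws.
#' @return data frame with columns \code{a1}, \code{b1}, \code{c1}.
#' @export
sample_params <- function(config, sex = c("male", "female"), n = 1) {
  sex <- match.arg(sex)
  d <- config$param_distributions[[sex]]
  r_c <- 2 * sin(pi * config$rank_correlation / 6)
  r_ab <- config$a1_b1_latent_cor
  Sigma <- matrix(c(1, r_ab, r_c,
                    r_ab, 1, r_c,
                    r_c, r_c, 1), 3, 3)
  L <- chol(Sigma)
  z <- matrix(stats::rnorm(3 * n), n, 3) %*% L
  u <- stats::pnorm(z)
  data.frame(
    a1 = stats::qlnorm(u[, 1L], d$a1[["meanlog"]], d$a1[["sdlog"]]),
    b1 = stats::qlnorm(u[, 2L], d$b1[["meanlog"]], d$b1[["sdlog"]]),
    c1 = stats::qnorm(u[, 3L], d$c1[["mean"]], d$c1[["sd"]])
  )
}

#' Generate one child's measurement series
#'
#' Visit 1 is the birth record at day 1; visits 2-12 get an age drawn
#' uniformly (integer days) inside their well-baby window. Visits are then
#' dropped independently: the birth record with probability
#' \code{config$birth_missingness}, the rest with
#' \code{config$visit_missingness}.
#' Values are curve values plus Gaussian noise, floored at 0.1 units. A
#' linear grower instead follows the straight line through (0, c1) that
#' reaches, at day 1095, the value its own sampled curve would have reached
#' — a draw from the cohort's 36-month size distribution.
#'
#' @param params one row of \code{\link{sample_params}} (or a named triple).
#' @param config a \code{\link{cohort_config}}.
#' @param linear is this subject a linear grower?
#' @return data frame with columns \code{visit}, \code{age_days},
#'   \code{value}; zero rows if every visit was dropped.
#' @export
generate_series <- function(params, config, linear = FALSE) {
  p <- as_mm_params(params[c("a1", "b1", "c1")])
  sched <- config$schedule
  n_v <- nrow(sched)
  ages <- integer(n_v)
  ages[1L] <- 1L
  for (i in seq_len(n_v)[-1L])
    ages[i] <- sample(seq.int(sched$min_day[i], sched$max_day[i]), 1L)
  miss_p <- c(config$birth_missingness,
              rep(config$visit_missingness, n_v - 1L))
  keep <- stats::runif(n_v) >= miss_p
  ages <- ages[keep]
  if (length(ages) == 0L)
    return(data.frame(visit = integer(0), age_days = integer(0),
                      value = numeric(0)))
  mu <- if (linear) {
    slope <- (mm_value(p, 1095) - p[["c1"]]) / 1095
    p[["c1"]] + slope * ages
  } else {
    mm_value(p, ages)
  }
  sd_i <- if (config$age_proportional_noise) {
    config$noise_sd * (1 + ages / 1125)
  } else rep(config$noise_sd, length(ages))
  value <- pmax(mu + stats::rnorm(length(ages), 0, sd_i), 0.1)
  data.frame(visit = sched$visit[keep], age_days = ages, value = value)
}

#' Generate a full synthetic cohort with ground truth
#'
#' Fully determined by \code{config$seed}. Sexes and linear-grower flags are
#' stratified deterministically along the subject index (subject \code{i} is
#' male iff \code{floor(i * ratio)} increments at \code{i}, and likewise for
#' linear growers), which gives exact counts \code{floor(n * fraction)} and
#' guarantees that appending subjects leaves every earlier subject's flags
#' and data untouched; each subject consumes its own derived RNG stream.
#' Optionally writes the cohort and truth tables as CSV in the dialect of
#' \code{\link{load_cohort}}.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param path optional cohort CSV output path.
#' @param truth_path optional truth CSV output path.
#' @return list with \code{cohort} (long data frame) and \code{truth} (one
#'   row per subject: \code{subject_id}, \code{sex}, \code{a1}, \code{b1},
#'   \code{c1}, \code{is_linear_grower}).
#' @export
generate_cohort <- function(config, path = NULL, truth_path = NULL) {
  n <- config$n_subjects
  ids <- sprintf("S%05d", seq_len(n))
  # index-stratified assignment: exact counts, stable under appending
  strat <- function(frac) {
    i <- seq_len(n)
    floor(i * frac) > floor((i - 1) * frac)
  }
  sexes <- ifelse(strat(config$sex_ratio), "male", "female")
  is_lin <- strat(config$linear_grower_fraction)

  rows <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    res <- with_seed(subject_seed(config$seed, i), {
      pars <- sample_params(config, sexes[i], n = 1)
      ser <- generate_series(pars, config, linear = is_lin[i])
      attempts <- 0L
      while (nrow(ser) == 0L && attempts < 10L) {
        ser <- generate_series(pars, config, linear = is_lin[i])
        attempts <- attempts + 1L
      }
      list(pars = pars, ser = ser)
    })
    truth[[i]] <- data.frame(subject_id = ids[i], sex = sexes[i],
                             a1 = res$pars$a1, b1 = res$pars$b1,
                             c1 = res$pars$c1, is_linear_grower = is_lin[i])
    if (nrow(res$ser) > 0L)
      rows[[i]] <- data.frame(subject_id = ids[i], sex = sexes[i],
                              measure = config$measure,
                              age_days = res$ser$age_days,
                              value = res$ser$value)
  }
  cohort <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  truth <- do.call(rbind, truth)
  rownames(cohort) <- rownames(truth) <- NULL
  if (!is.null(path)) write_cohort(cohort, path)
  if (!is.null(truth_path))
    utils::write.csv(truth, truth_path, row.names = FALSE, quote = FALSE)
  list(cohort = cohort, truth = truth)
}
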