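#' Convert pounds to kilograms
#'
#' Exact conversion by the international definition of the pound,
#' 1 lb = 0.45359237 kg.
#'
#' @param weight_lb non-negative weight(s) in pounds.
#' @return weight(s) in kg.
#' @export
lb_to_kg <- function(weight_lb) {
  if (any(weight_lb < 0)) stop("weight must be non-negative")
  weight_lb * 0.45359237
}

#' Read a longitudinal growth cohort from a long-format CSV
#'
#' Expected columns: \code{subject_id}, \code{sex} (\code{male}/\code{female}),
#' \code{age_days}, \code{value}, and optionally \code{measure}
#' (\code{weight}/\code{height}) and \code{unit} (\code{kg}, \code{lb} or
#' \code{cm}; \code{lb} values are converted to kg on load). Rows with a
#' missing required field are skipped and counted. Internal units are always
#' kg, cm and days.
#'
#' @param path CSV file path.
#' @param measure optional filter, \code{"weight"} or \code{"height"}; series
#'   of the other kind are dropped.
#' @param max_bad_fraction error if more than this fraction of rows is
#'   unusable.
#' @return a cohort data frame (columns \code{subject_id}, \code{sex},
#'   \code{measure}, \code{age_days}, \code{value}), sorted by subject and
#'   age, with attribute \code{"n_skipped"} giving the count of skipped rows.
#' @export
load_cohort <- function(path, measure = NULL, max_bad_fraction = 0.5) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "sex", "age_days", "value")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  if (!"measure" %in% names(raw))
    raw$measure <- if (is.null(measure)) "weight" else measure
  raw$age_days <- suppressWarnings(as.numeric(raw$age_days))
  raw$value <- suppressWarnings(as.numeric(raw$value))
  bad <- !stats::complete.cases(raw[req]) | raw$value <= 0 | raw$age_days < 0
  if (mean(bad) > max_bad_fraction)
    stop("more than ", round(100 * max_bad_fraction),
         "% of rows are unusable")
  d <- raw[!bad, , drop = FALSE]
  if ("unit" %in% names(d)) {
    islb <- !is.na(d$unit) & d$unit == "lb"
    d$value[islb] <- lb_to_kg(d$value[islb])
    d$unit <- NULL
  }
  if (!is.null(measure)) d <- d[d$measure == measure, , drop = FALSE]
  d <- d[order(d$subject_id, d$age_days),
         c("subject_id", "sex", "measure", "age_days", "value")]
  rownames(d) <- NULL
  attr(d, "n_skipped") <- sum(bad)
  d
}

#' Write a cohort in the long CSV dialect read by \code{load_cohort}
#'
#' @param cohort a cohort data frame.
#' @param path output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  cols <- c("subject_id", "sex", "measure", "age_days", "value")
  stopifnot(all(cols %in% names(cohort)))
  out <- cohort[cols]
  out$unit <- ifelse(out$measure == "height", "cm", "kg")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a cohort into per-subject measurement series
#'
#' @param cohort a cohort data frame.
#' @return a named list of series data frames (sorted by age), one per
#'   subject present in the cohort.
#' @export
split_series <- function(cohort) {
  lapply(split(cohort, cohort$subject_id), function(d) {
    d <- d[order(d$age_days), , drop = FALSE]
    rownames(d) <- NULL
    d
  })
}
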