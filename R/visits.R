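#' The 12 recommended well-baby visit windows
#'
#' Day windows (closed intervals, 0-based days since birth) around the twelve
#' scheduled well-child visits from birth to 36 months. Visit 1 is the birth
#' record; day-0 and day-1 records both qualify.
#'
#' @return data frame with columns \code{visit} (1-12), \code{min_day},
#'   \code{max_day}; windows are non-overlapping and increasing.
#' @export
visit_schedule <- function() {
  data.frame(
    visit   = 1:12,
    min_day = c(0, 20, 46, 95, 158, 250, 310, 410, 500, 640, 842, 1024),
    max_day = c(1, 44, 90, 148, 225, 298, 399, 490, 600, 800, 982, 1125)
  )
}

#' Assign a series' measurements to well-baby visits
#'
#' Each measurement whose age falls inside a visit window is a candidate for
#' that visit; the candidate closest to the window midpoint wins, with ties
#' going to the earlier age. Windows do not overlap, so no measurement can be
#' assigned twice. Measurements in no window stay unassigned.
#'
#' @param series a series data frame with columns \code{age_days},
#'   \code{value} (one subject, one measure).
#' @param schedule a \code{\link{visit_schedule}}-shaped data frame.
#' @return data frame with one row per visit: \code{visit}, \code{age_days},
#'   \code{value} (\code{NA} where no measurement fell in the window).
#' @export
assign_visits <- function(series, schedule = visit_schedule()) {
  stopifnot(all(c("age_days", "value") %in% names(series)))
  out <- data.frame(visit = schedule$visit, age_days = NA_real_,
                    value = NA_real_)
  for (i in seq_len(nrow(schedule))) {
    inside <- which(series$age_days >= schedule$min_day[i] &
                    series$age_days <= schedule$max_day[i])
    if (length(inside) == 0L) next
    mid <- (schedule$min_day[i] + schedule$max_day[i]) / 2
    d <- abs(series$age_days[inside] - mid)
    # ties broken toward the earlier age
    best <- inside[order(d, series$age_days[inside])][1L]
    out$age_days[i] <- series$age_days[best]
    out$value[i] <- series$value[best]
  }
  out
}

#' Does a subject have all scheduled visits through visit 7 or 12?
#'
#' @param assignment result of \code{\link{assign_visits}}.
#' @param through_visit 7 (first-year complete) or 12 (all three years).
#' @return \code{TRUE} iff visits 1..\code{through_visit} all have a chosen
#'   measurement.
#' @export
has_complete_visits <- function(assignment, through_visit) {
  if (!through_visit %in% c(7L, 12L))
    stop("'through_visit' must be 7 or 12")
  idx <- assignment$visit %in% seq_len(through_visit)
  all(!is.na(assignment$value[idx]))
}
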