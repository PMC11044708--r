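.quarters <- c("late_night", "morning", "afternoon", "early_night")

#' Day relative to parturition
#'
#' Calendar-day difference between the date of `t` and the parturition
#' date (wall-clock dates, not 24-h offsets); the day of parturition is
#' day 0.
#'
#' @param t POSIXct time(s).
#' @param parturition_time POSIXct parturition timestamp.
#' @return integer vector of day offsets.
#' @export
day_relative <- function(t, parturition_time) {
  stopifnot(inherits(t, "POSIXct"), inherits(parturition_time, "POSIXct"))
  as.integer(as.Date(t, tz = .tz) - as.Date(parturition_time, tz = .tz))
}

# Overlap in seconds of intervals [s1,e1) with window [ws,we), vectorized
interval_overlap_s <- function(s1, e1, ws, we) {
  pmax(0, as.numeric(pmin(as.numeric(e1), we) - pmax(as.numeric(s1), ws)))
}

#' Summarize lying behaviour by parturition-aligned quarter-days
#'
#' Splits each calendar day relative to parturition into four 6-h
#' wall-clock quarters — late_night (00-06), morning (06-12), afternoon
#' (12-18), early_night (18-24) — and reports per quarter the number of
#' bouts starting in it, the lying seconds (summed intersection of bouts
#' with the quarter window), the observed coverage seconds, and the lying
#' proportion `lying_s / coverage_s`. A bout spanning a quarter boundary is
#' counted once, in the quarter containing its start. Only quarters with
#' positive coverage are reported.
#'
#' @param bouts a [bout_table()] of lying/rest bouts for one animal.
#' @param coverage data.frame of coverage intervals (`start`, `stop`), e.g.
#'   from [trace_coverage()]; defaults to the span of the bouts.
#' @param meta list or one-row data.frame with `animal_id` and
#'   `parturition_time`.
#' @param quarter_hours start hours of the four quarters (default
#'   `c(0, 6, 12, 18)`).
#' @return data.frame with `animal_id`, `day_rel`, `quarter`, `n_bouts`,
#'   `lying_s`, `coverage_s`, `proportion`.
#' @export
summarize_quarters <- function(bouts, coverage = NULL, meta,
                               quarter_hours = c(0, 6, 12, 18)) {
  stopifnot(inherits(bouts, "bout_table"), length(quarter_hours) == 4)
  pt <- if (is.data.frame(meta)) meta$parturition_time[1] else meta$parturition_time
  if (is.null(pt) || !inherits(pt, "POSIXct") || is.na(pt)) {
    stop(sprintf("missing parturition_time for animal %s",
                 if (is.data.frame(meta)) meta$animal_id[1] else meta$animal_id),
         call. = FALSE)
  }
  animal <- if (is.data.frame(meta)) as.character(meta$animal_id[1])
            else as.character(meta$animal_id)

  if (is.null(coverage)) {
    if (!nrow(bouts)) return(empty_summary())
    coverage <- data.frame(start = min(bouts$start), stop = max(bouts$stop))
  }
  if (!nrow(coverage)) return(empty_summary())

  cov_s <- as.numeric(coverage$start)
  cov_e <- as.numeric(coverage$stop)
  day0 <- as.POSIXct(as.Date(pt, tz = .tz), tz = .tz)

  first_day <- min(day_relative(coverage$start, pt))
  last_day <- max(day_relative(coverage$stop - 1e-9, pt))

  rows <- list()
  for (d in first_day:last_day) {
    day_start <- as.numeric(day0) + d * 86400
    for (q in seq_len(4)) {
      qs <- day_start + quarter_hours[q] * 3600
      qe <- if (q < 4) day_start + quarter_hours[q + 1] * 3600
            else day_start + 86400
      coverage_s <- sum(interval_overlap_s(cov_s, cov_e, qs, qe))
      if (coverage_s <= 0) next
      lying_s <- if (nrow(bouts))
        sum(interval_overlap_s(bouts$start, bouts$stop, qs, qe)) else 0
      n_bouts <- if (nrow(bouts))
        sum(as.numeric(bouts$start) >= qs & as.numeric(bouts$start) < qe)
        else 0L
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = animal, day_rel = d, quarter = .quarters[q],
        n_bouts = as.integer(n_bouts), lying_s = lying_s,
        coverage_s = coverage_s, proportion = lying_s / coverage_s)
    }
  }
  if (!length(rows)) return(empty_summary())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_summary <- function() {
  data.frame(animal_id = character(0), day_rel = integer(0),
             quarter = character(0), n_bouts = integer(0),
             lying_s = numeric(0), coverage_s = numeric(0),
             proportion = numeric(0))
}
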