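#' Construct an accelerometer trace
#'
#' Builds an `accel_trace` from timestamped y-axis acceleration samples.
#' Timestamps must be strictly increasing after duplicate removal; samples
#' with a non-finite y value are dropped. Any inter-sample interval larger
#' than `gap_tolerance` is recorded as a coverage gap, and samples are
#' assigned to contiguous segments between gaps. Each sample covers the
#' half-open interval `[t, t + 1/nominal_rate)`, so segment coverage runs
#' from the first sample to one sampling period past the last.
#'
#' @param animal_id identifier of the animal/deployment.
#' @param time POSIXct (or parseable character) sample timestamps.
#' @param y y-axis acceleration in g (axis parallel to the leg).
#' @param x,z optional additional axes in g.
#' @param gap_tolerance seconds; larger inter-sample intervals become gaps.
#' @param nominal_rate nominal sampling rate in Hz (default 1).
#' @return an `accel_trace`: list with `animal_id`, `samples` (data.frame
#'   `time`, `y`, optional `x`, `z`, `segment`), `gaps` (data.frame `start`,
#'   `stop`, `duration_s`), `nominal_rate`, `gap_tolerance`.
#' @export
accel_trace <- function(animal_id, time, y, x = NULL, z = NULL,
                        gap_tolerance = 5, nominal_rate = 1) {
  if (is.character(time)) time <- parse_time(time)
  stopifnot(inherits(time, "POSIXct"), length(time) == length(y),
            gap_tolerance > 0, nominal_rate > 0)
  attr(time, "tzone") <- .tz

  dup <- duplicated(time)
  if (any(dup)) {
    warning(sprintf("%d duplicate timestamp(s) collapsed to first occurrence",
                    sum(dup)), call. = FALSE)
    y <- y[!dup]
    if (!is.null(x)) x <- x[!dup]
    if (!is.null(z)) z <- z[!dup]
    time <- time[!dup]
  }
  if (is.unsorted(time, strictly = TRUE)) {
    o <- order(time)
    time <- time[o]; y <- y[o]
    if (!is.null(x)) x <- x[o]
    if (!is.null(z)) z <- z[o]
  }
  bad <- !is.finite(y)
  if (any(bad)) {
    warning(sprintf("%d sample(s) with non-finite y dropped", sum(bad)),
            call. = FALSE)
    time <- time[!bad]; y <- y[!bad]
    if (!is.null(x)) x <- x[!bad]
    if (!is.null(z)) z <- z[!bad]
  }

  n <- length(time)
  if (n == 0) stop("no valid samples", call. = FALSE)
  dt <- as.numeric(diff(time), units = "secs")
  gap_after <- which(dt > gap_tolerance)
  gaps <- data.frame(start = time[gap_after][seq_along(gap_after)],
                     stop = time[gap_after + 1L][seq_along(gap_after)],
                     duration_s = dt[gap_after])
  if (!length(gap_after)) {
    gaps <- data.frame(start = time[0], stop = time[0],
                       duration_s = numeric(0))
  }
  segment <- cumsum(c(1L, as.integer(seq_len(n - 1L) %in% gap_after)))

  samples <- data.frame(time = time, y = y)
  if (!is.null(x)) samples$x <- x
  if (!is.null(z)) samples$z <- z
  samples$segment <- segment

  structure(list(animal_id = as.character(animal_id), samples = samples,
                 gaps = gaps, nominal_rate = nominal_rate,
                 gap_tolerance = gap_tolerance),
            class = "accel_trace")
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> animal %s: %d samples @ %g Hz, %d segment(s), %d gap(s)\n",
              x$animal_id, nrow(x$samples), x$nominal_rate,
              max(x$samples$segment), nrow(x$gaps)))
  invisible(x)
}

#' Coverage intervals of a trace
#'
#' Half-open intervals `[start, stop)` with valid sensor samples, one per
#' contiguous segment; gap time is excluded.
#'
#' @param trace an `accel_trace`.
#' @return data.frame with `start`, `stop` (POSIXct) and `duration_s`.
#' @export
trace_coverage <- function(trace) {
  stopifnot(inherits(trace, "accel_trace"))
  s <- trace$samples
  step <- 1 / trace$nominal_rate
  seg <- factor(s$segment, levels = sort(unique(s$segment)))
  tt <- split(as.numeric(s$time), seg)
  start <- as.POSIXct(vapply(tt, min, 0), origin = "1970-01-01", tz = .tz)
  stop <- as.POSIXct(vapply(tt, max, 0) + step, origin = "1970-01-01", tz = .tz)
  data.frame(start = start, stop = stop,
             duration_s = as.numeric(stop - start, units = "secs"),
             row.names = NULL)
}

#' Read a logger CSV into an accelerometer trace
#'
#' Reads a delimited logger export with one row per sample. The column map
#' defaults to the `(time, x, y, z)` layout; unknown extra columns are
#' ignored. Duplicate timestamps are collapsed to the first occurrence with
#' a warning, non-finite y samples are dropped, and inter-sample intervals
#' exceeding `gap_tolerance` are recorded as coverage gaps.
#'
#' @param path CSV file path.
#' @param column_map named character vector mapping roles to column names;
#'   must name `time` and `y`, may name `x`, `z`.
#' @param gap_tolerance seconds (default 5 at 1 Hz).
#' @param nominal_rate sampling rate in Hz.
#' @param animal_id animal identifier; defaults to the file name stem.
#' @param delim field delimiter.
#' @return an [accel_trace()].
#' @export
read_accel_csv <- function(path,
                           column_map = c(time = "time", x = "x", y = "y", z = "z"),
                           gap_tolerance = 5, nominal_rate = 1,
                           animal_id = NULL, delim = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- read.csv(path, sep = delim, stringsAsFactors = FALSE,
                 check.names = FALSE)
  for (role in c("time", "y")) {
    if (!role %in% names(column_map) || !column_map[[role]] %in% names(df)) {
      stop(sprintf("column map must name an existing '%s' column", role),
           call. = FALSE)
    }
  }
  if (is.null(animal_id)) animal_id <- sub("\\.[^.]*$", "", basename(path))
  grab <- function(role) {
    if (role %in% names(column_map) && column_map[[role]] %in% names(df))
      df[[column_map[[role]]]] else NULL
  }
  accel_trace(animal_id,
              time = parse_time(df[[column_map[["time"]]]]),
              y = as.numeric(grab("y")),
              x = if (!is.null(grab("x"))) as.numeric(grab("x")),
              z = if (!is.null(grab("z"))) as.numeric(grab("z")),
              gap_tolerance = gap_tolerance, nominal_rate = nominal_rate)
}

#' Construct an observer-coded ethogram
#'
#' Events are half-open `[start, stop)` bouts of `lying` or `sitting`; time
#' not covered by an event is implicitly upright/standing. Events must be
#' pairwise non-overlapping (adjacency is legal) and lie within the
#' observation window.
#'
#' @param animal_id animal identifier.
#' @param events data.frame with columns `behavior` (`lying`/`sitting`),
#'   `start`, `stop` (POSIXct or parseable character).
#' @param window observation window as POSIXct length-2 vector; defaults to
#'   the span of the events.
#' @return an `ethogram` object.
#' @export
ethogram <- function(animal_id, events, window = NULL) {
  stopifnot(is.data.frame(events),
            all(c("behavior", "start", "stop") %in% names(events)))
  events$behavior <- as.character(events$behavior)
  if (is.character(events$start)) events$start <- parse_time(events$start, "start")
  if (is.character(events$stop)) events$stop <- parse_time(events$stop, "stop")
  attr(events$start, "tzone") <- .tz
  attr(events$stop, "tzone") <- .tz

  bad_lab <- setdiff(unique(events$behavior), c("lying", "sitting"))
  if (length(bad_lab)) {
    stop(sprintf("unknown behavior label(s): %s", paste(bad_lab, collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(events)) {
    if (any(events$stop <= events$start)) {
      i <- which(events$stop <= events$start)[1]
      stop(sprintf("event %d has stop <= start (%s >= %s)", i,
                   fmt_time(events$start[i]), fmt_time(events$stop[i])),
           call. = FALSE)
    }
    events <- events[order(events$start, events$stop), , drop = FALSE]
    rownames(events) <- NULL
    if (nrow(events) > 1) {
      ov <- which(events$start[-1] < events$stop[-nrow(events)])
      if (length(ov)) {
        i <- ov[1]
        stop(sprintf(
          "overlapping events %d (%s %s-%s) and %d (%s %s-%s)",
          i, events$behavior[i], fmt_time(events$start[i]), fmt_time(events$stop[i]),
          i + 1, events$behavior[i + 1], fmt_time(events$start[i + 1]),
          fmt_time(events$stop[i + 1])), call. = FALSE)
      }
    }
  }
  if (is.null(window)) {
    window <- if (nrow(events)) c(min(events$start), max(events$stop))
              else as.POSIXct(c(NA, NA), tz = .tz)
  }
  if (nrow(events) && !anyNA(window) &&
      (any(events$start < window[1]) || any(events$stop > window[2]))) {
    stop("events extend beyond the observation window", call. = FALSE)
  }
  structure(list(animal_id = as.character(animal_id),
                 events = events[, c("behavior", "start", "stop")],
                 window = window),
            class = "ethogram")
}

#' @export
print.ethogram <- function(x, ...) {
  cat(sprintf("<ethogram> animal %s: %d event(s) (%d lying, %d sitting)\n",
              x$animal_id, nrow(x$events), sum(x$events$behavior == "lying"),
              sum(x$events$behavior == "sitting")))
  invisible(x)
}

#' Read an observer ethogram CSV
#'
#' Reads a tabular behavioural-observation export with one row per coded
#' bout (behavior label plus start and stop timestamps).
#'
#' @param path CSV file path.
#' @param column_map named character vector mapping `behavior`, `start`,
#'   `stop` (optionally `animal_id`) to column names.
#' @param animal_id animal identifier; overrides any id column.
#' @param delim field delimiter.
#' @return an [ethogram()].
#' @export
read_ethogram_csv <- function(path,
                              column_map = c(behavior = "behavior",
                                             start = "start", stop = "stop"),
                              animal_id = NULL, delim = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- read.csv(path, sep = delim, stringsAsFactors = FALSE,
                 check.names = FALSE)
  for (role in c("behavior", "start", "stop")) {
    if (!column_map[[role]] %in% names(df)) {
      stop(sprintf("column map must name an existing '%s' column", role),
           call. = FALSE)
    }
  }
  if (is.null(animal_id)) {
    animal_id <- if ("animal_id" %in% names(column_map) &&
                     column_map[["animal_id"]] %in% names(df))
      df[[column_map[["animal_id"]]]][1] else sub("\\.[^.]*$", "", basename(path))
  }
  ethogram(animal_id,
           data.frame(behavior = df[[column_map[["behavior"]]]],
                      start = parse_time(df[[column_map[["start"]]]], "start"),
                      stop = parse_time(df[[column_map[["stop"]]]], "stop")))
}

#' Construct a bout table
#'
#' Half-open `[start, stop)` behaviour bouts with exact durations.
#'
#' @param animal_id animal identifier (recycled).
#' @param behavior `lying` or `rest` (recycled).
#' @param start,stop POSIXct bout boundaries.
#' @param truncated logical; bout abuts a coverage gap or segment edge.
#' @param source one of `sensor`, `ethogram`, `ethogram_merged`, `truth`.
#' @return data.frame of class `bout_table` with columns `animal_id`,
#'   `behavior`, `start`, `stop`, `duration_s`, `truncated` and a `source`
#'   attribute.
#' @export
bout_table <- function(animal_id = character(0), behavior = character(0),
                       start = as.POSIXct(character(0), tz = .tz),
                       stop = as.POSIXct(character(0), tz = .tz),
                       truncated = logical(length(start)),
                       source = "sensor") {
  n <- length(start)
  stopifnot(length(stop) == n,
            source %in% c("sensor", "ethogram", "ethogram_merged", "truth"))
  if (n) {
    stopifnot(all(stop > start))
    attr(start, "tzone") <- .tz
    attr(stop, "tzone") <- .tz
  }
  out <- data.frame(animal_id = rep_len(as.character(animal_id), n),
                    behavior = rep_len(as.character(behavior), n),
                    start = start, stop = stop,
                    duration_s = as.numeric(stop - start, units = "secs"),
                    truncated = rep_len(truncated, n))
  o <- order(out$animal_id, out$start)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("bout_table", "data.frame"), source = source)
}

#' Write a bout table to CSV
#'
#' Column order: `animal_id`, `behavior`, `start`, `stop`, `duration_s`,
#' `truncated`. Timestamps are written as `YYYY-MM-DD HH:MM:SS`; the table
#' round-trips through [read_bouts_csv()].
#'
#' @param bouts a [bout_table()].
#' @param path output file path.
#' @export
write_bouts <- function(bouts, path) {
  stopifnot(inherits(bouts, "bout_table"))
  df <- as.data.frame(bouts)
  df$start <- fmt_time(df$start)
  df$stop <- fmt_time(df$stop)
  df$source <- rep(attr(bouts, "source"), nrow(df))
  write.csv(df[, c("animal_id", "behavior", "start", "stop", "duration_s",
                   "truncated", "source")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a bout table written by [write_bouts()]
#' @param path CSV file path.
#' @return a [bout_table()].
#' @export
read_bouts_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  src <- if (nrow(df) && "source" %in% names(df)) df$source[1] else "sensor"
  bout_table(df$animal_id, df$behavior,
             parse_time(df$start, "start"), parse_time(df$stop, "stop"),
             truncated = if ("truncated" %in% names(df)) df$truncated
                         else logical(nrow(df)),
             source = src)
}

#' Write quarter-day summaries to CSV
#'
#' Column order: `animal_id`, `day_rel`, `quarter`, `n_bouts`, `lying_s`,
#' `coverage_s`, `proportion`; round-trips through [read_summaries_csv()].
#'
#' @param summaries data.frame as produced by [summarize_quarters()].
#' @param path output file path.
#' @export
write_summaries <- function(summaries, path) {
  cols <- c("animal_id", "day_rel", "quarter", "n_bouts", "lying_s",
            "coverage_s", "proportion")
  stopifnot(all(cols %in% names(summaries)))
  write.csv(summaries[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a summary table written by [write_summaries()]
#' @param path CSV file path.
#' @return data.frame of quarter summaries.
#' @export
read_summaries_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$animal_id <- as.character(df$animal_id)
  df
}

#' Write an ethogram to CSV (animal_id, behavior, start, stop)
#' @param eth an [ethogram()].
#' @param path output file path.
#' @export
write_ethogram <- function(eth, path) {
  stopifnot(inherits(eth, "ethogram"))
  df <- data.frame(animal_id = eth$animal_id,
                   behavior = eth$events$behavior,
                   start = fmt_time(eth$events$start),
                   stop = fmt_time(eth$events$stop))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an accelerometer trace to a logger-style CSV (time, y[, x, z])
#' @param trace an [accel_trace()].
#' @param path output file path.
#' @export
write_accel_csv <- function(trace, path) {
  stopifnot(inherits(trace, "accel_trace"))
  s <- trace$samples
  df <- data.frame(time = fmt_time(s$time), y = s$y)
  if (!is.null(s$x)) df$x <- s$x
  if (!is.null(s$z)) df$z <- s$z
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
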