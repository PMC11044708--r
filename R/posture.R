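#' Running median filter
#'
#' Centered (default) or trailing running median. For an even window of
#' `w` samples the centered window covers `w/2` samples behind and
#' `w/2 - 1` ahead, and the median of an even count is the mean of the two
#' central order statistics. At segment edges the centered window is
#' truncated symmetrically (shrunk to the largest window balanced around
#' the sample); the trailing window is truncated at the segment start.
#'
#' @param x numeric vector.
#' @param window window length in samples (>= 1).
#' @param align `"center"` or `"trailing"`.
#' @return numeric vector of smoothed values, same length as `x`.
#' @export
moving_median <- function(x, window, align = c("center", "trailing")) {
  align <- match.arg(align)
  if (!is.numeric(window) || length(window) != 1 || window < 1) {
    stop("window must be a single integer >= 1", call. = FALSE)
  }
  moving_median_cpp(as.numeric(x), as.integer(window), align == "center")
}

#' Classify accelerometer samples as lying vs upright
#'
#' Implements the threshold classifier for a hind-leg logger: the leg is
#' vertical while standing (|y| near 1 g) and horizontal while lying
#' (|y| near 0 g), so a sample is lying when the smoothed |y| falls below
#' the critical lying value. Smoothing uses a running median over `window`
#' samples to reject movement artefacts; it is computed within contiguous
#' segments only and never across coverage gaps. Ties at exactly the
#' critical value classify as upright.
#'
#' `smooth = "signal"` (default) applies the median filter to |y| before
#' thresholding; `smooth = "binary"` thresholds the raw |y| first and
#' median-filters the 0/1 labels (majority vote, ties upright).
#'
#' @param trace an [accel_trace()].
#' @param critical_value critical lying value in g (default 0.75).
#' @param window median window in samples (default 32).
#' @param smooth `"signal"` or `"binary"`.
#' @param align `"center"` (default) or `"trailing"` median window.
#' @return a `posture_series`: list with `animal_id`, `data` (data.frame
#'   `time`, `state` in `{lying, upright}`, `segment`), `nominal_rate`, and
#'   `params`.
#' @export
classify_samples <- function(trace, critical_value = 0.75, window = 32,
                             smooth = c("signal", "binary"),
                             align = c("center", "trailing")) {
  stopifnot(inherits(trace, "accel_trace"))
  smooth <- match.arg(smooth)
  align <- match.arg(align)
  if (!is.finite(critical_value) || critical_value <= 0) {
    stop("critical_value must be > 0", call. = FALSE)
  }
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  s <- trace$samples
  if (!nrow(s)) stop("trace has no samples", call. = FALSE)

  ay <- abs(s$y)
  lying <- logical(nrow(s))
  for (seg in unique(s$segment)) {
    i <- which(s$segment == seg)
    if (smooth == "signal") {
      m <- moving_median(ay[i], window, align)
      lying[i] <- m < critical_value
    } else {
      b <- as.numeric(ay[i] < critical_value)
      m <- moving_median(b, window, align)
      lying[i] <- m > 0.5
    }
  }
  structure(list(animal_id = trace$animal_id,
                 data = data.frame(time = s$time,
                                   state = ifelse(lying, "lying", "upright"),
                                   segment = s$segment),
                 nominal_rate = trace$nominal_rate,
                 params = list(critical_value = critical_value,
                               window = window, smooth = smooth,
                               align = align)),
            class = "posture_series")
}

#' @export
print.posture_series <- function(x, ...) {
  cat(sprintf("<posture_series> animal %s: %d samples, %.1f%% lying\n",
              x$animal_id, nrow(x$data),
              100 * mean(x$data$state == "lying")))
  invisible(x)
}

#' Extract lying bouts from a posture series
#'
#' Maximal runs of lying samples become half-open bouts: start is the first
#' lying sample's timestamp, stop is the first subsequent non-lying sample's
#' timestamp (or one sampling period past the segment's last sample). Bouts
#' never span a coverage gap; a bout abutting a segment edge is flagged
#' truncated. Total bout duration therefore equals the lying-sample count
#' divided by the sampling rate, exactly, segment by segment.
#'
#' @param series a `posture_series` from [classify_samples()].
#' @return a [bout_table()] with `source = "sensor"`.
#' @export
extract_bouts <- function(series) {
  stopifnot(inherits(series, "posture_series"))
  d <- series$data
  step <- 1 / series$nominal_rate
  starts <- stops <- numeric(0)
  truncated <- logical(0)
  for (seg in unique(d$segment)) {
    i <- which(d$segment == seg)
    r <- rle(d$state[i] == "lying")
    ends <- cumsum(r$lengths)
    begins <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      b <- i[begins[j]]; e <- i[ends[j]]
      starts <- c(starts, as.numeric(d$time[b]))
      stops <- c(stops, if (ends[j] == length(i)) as.numeric(d$time[e]) + step
                        else as.numeric(d$time[i[ends[j] + 1L]]))
      truncated <- c(truncated, begins[j] == 1L || ends[j] == length(i))
    }
  }
  bout_table(series$animal_id, "lying",
             start = as.POSIXct(starts, origin = "1970-01-01", tz = .tz),
             stop = as.POSIXct(stops, origin = "1970-01-01", tz = .tz),
             truncated = truncated, source = "sensor")
}
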