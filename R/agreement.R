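#' Raw lying bouts of an ethogram
#'
#' Lying events taken verbatim as bouts (the video dataset before any
#' sitting reconciliation); sitting events are dropped.
#'
#' @param eth an [ethogram()].
#' @return a [bout_table()] with `source = "ethogram"`.
#' @export
ethogram_bouts <- function(eth) {
  stopifnot(inherits(eth, "ethogram"))
  ly <- eth$events[eth$events$behavior == "lying", , drop = FALSE]
  bout_table(eth$animal_id, "lying", ly$start, ly$stop, source = "ethogram")
}

#' Merge transitional sitting into rest bouts
#'
#' A hind-leg sensor cannot distinguish sitting from lying (the leg
#' orientation is the same), so for method comparison transitional sitting
#' is absorbed into the surrounding rest: every maximal chain of
#' lying/sitting events in which consecutive events are contiguous (gap at
#' most `adjacency_tolerance`) and which contains at least one lying event
#' becomes a single rest bout spanning the chain; sitting chains with no
#' lying event remain upright and are discarded. This covers sitting
#' between lying bouts, sitting before standing up, and sitting before
#' lying down.
#'
#' @param eth an [ethogram()].
#' @param adjacency_tolerance maximum gap in seconds between consecutive
#'   chained events (default 1 s, one sample at 1 Hz).
#' @return a [bout_table()] of `rest` bouts, `source = "ethogram_merged"`.
#' @export
merge_transitional_sitting <- function(eth, adjacency_tolerance = 1) {
  stopifnot(inherits(eth, "ethogram"), adjacency_tolerance >= 0)
  ev <- eth$events
  if (!nrow(ev)) {
    return(bout_table(source = "ethogram_merged"))
  }
  gap <- c(Inf, as.numeric(ev$start[-1]) - as.numeric(ev$stop[-nrow(ev)]))
  chain <- cumsum(gap > adjacency_tolerance)
  starts <- stops <- numeric(0)
  for (id in unique(chain)) {
    i <- which(chain == id)
    if (!any(ev$behavior[i] == "lying")) next
    starts <- c(starts, as.numeric(min(ev$start[i])))
    stops <- c(stops, as.numeric(max(ev$stop[i])))
  }
  bout_table(eth$animal_id, "rest",
             start = as.POSIXct(starts, origin = "1970-01-01", tz = .tz),
             stop = as.POSIXct(stops, origin = "1970-01-01", tz = .tz),
             source = "ethogram_merged")
}

#' Build a subjects-by-methods ratings matrix
#'
#' One row per observation window (typically a sow by 24-h period), one
#' column per method. The measure is either the number of bouts starting in
#' the window (`bout_count`) or the summed bout-window overlap in seconds
#' (`lying_seconds`). Windows with zero sensor coverage are dropped with a
#' message (mirroring exclusion of faulty records); windows whose sensor
#' coverage fraction is below `min_coverage_frac` are likewise dropped.
#'
#' @param video [bout_table()] from the video ethogram.
#' @param sensor [bout_table()] from the classifier.
#' @param windows data.frame with `subject_id`, `start`, `stop` (POSIXct),
#'   non-overlapping per subject.
#' @param measure `"bout_count"` or `"lying_seconds"`.
#' @param sensor_coverage optional data.frame of sensor coverage intervals
#'   (`start`, `stop`); `NULL` assumes full coverage.
#' @param min_coverage_frac minimum covered fraction of a window for it to
#'   be retained (default 0.75).
#' @return numeric matrix with columns `video`, `sensor`, one row per
#'   retained window; attribute `dropped` counts excluded windows.
#' @export
build_ratings <- function(video, sensor, windows,
                          measure = c("bout_count", "lying_seconds"),
                          sensor_coverage = NULL, min_coverage_frac = 0.75) {
  measure <- match.arg(measure)
  stopifnot(inherits(video, "bout_table"), inherits(sensor, "bout_table"),
            all(c("subject_id", "start", "stop") %in% names(windows)))

  score <- function(bouts, ws, we) {
    if (!nrow(bouts)) return(0)
    if (measure == "bout_count") {
      sum(as.numeric(bouts$start) >= ws & as.numeric(bouts$start) < we)
    } else {
      sum(interval_overlap_s(bouts$start, bouts$stop, ws, we))
    }
  }

  keep <- vals <- list()
  dropped <- 0L
  for (i in seq_len(nrow(windows))) {
    ws <- as.numeric(windows$start[i]); we <- as.numeric(windows$stop[i])
    if (!is.null(sensor_coverage)) {
      cov <- sum(interval_overlap_s(sensor_coverage$start,
                                    sensor_coverage$stop, ws, we))
      if (cov <= 0 || cov / (we - ws) < min_coverage_frac) {
        dropped <- dropped + 1L
        next
      }
    }
    keep[[length(keep) + 1L]] <- as.character(windows$subject_id[i])
    vals[[length(vals) + 1L]] <- c(video = score(video, ws, we),
                                   sensor = score(sensor, ws, we))
  }
  if (dropped) message(sprintf("%d window(s) dropped for insufficient sensor coverage", dropped))
  m <- do.call(rbind, vals)
  if (is.null(m)) m <- matrix(numeric(0), 0, 2,
                              dimnames = list(NULL, c("video", "sensor")))
  rownames(m) <- unlist(keep)
  structure(m, dropped = dropped)
}

#' Two-way random-effects intraclass correlation
#'
#' Single-measure two-way random-effects ICC from an n subjects by k
#' methods ratings matrix, computed from the definitional two-way ANOVA
#' mean squares. The default form is absolute agreement, ICC(A,1):
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with `MS_R`, `MS_C`, `MS_E` the row (subject), column (method) and
#' residual mean squares; the consistency form ICC(C,1) is available via
#' `form = "consistency"`. Confidence bounds use the standard F-based
#' intervals (Satterthwaite degrees of freedom for the agreement form).
#'
#' A matrix with zero total variance has no defined ICC and raises a
#' classed error (`sowlying_degenerate`) rather than returning a number.
#'
#' @param m numeric matrix, subjects in rows, methods in columns; no
#'   missing cells (rows with missing cells are dropped with a message).
#' @param confidence confidence level (default 0.95).
#' @param form `"agreement"` (ICC(A,1), default) or `"consistency"`
#'   (ICC(C,1)).
#' @return an `icc_result`: list with `estimate`, `ci_low`, `ci_high`,
#'   `ms_rows`, `ms_cols`, `ms_error`, `n`, `k`, `form`, `confidence`.
#' @export
icc_agreement <- function(m, confidence = 0.95,
                          form = c("agreement", "consistency")) {
  form <- match.arg(form)
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    drop_n <- sum(!stats::complete.cases(m))
    message(sprintf("%d subject(s) with missing cells dropped", drop_n))
    m <- m[stats::complete.cases(m), , drop = FALSE]
  }
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("ratings matrix must be at least 2 x 2", call. = FALSE)
  if (confidence <= 0 || confidence >= 1) stop("confidence must be in (0,1)", call. = FALSE)

  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_total <- sum((m - grand)^2)
  if (ss_total == 0) {
    cond <- structure(class = c("sowlying_degenerate", "error", "condition"),
                      list(message = "ratings matrix is constant: ICC undefined (zero total variance)",
                           call = sys.call()))
    stop(cond)
  }
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  alpha <- 1 - confidence

  if (form == "agreement") {
    est <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    # Satterthwaite df for the F-based interval
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    # near-degenerate Satterthwaite df make qf's tail inversion inexact and
    # chatty; the bound is conservative either way
    fl <- suppressWarnings(qf(1 - alpha / 2, n - 1, v))
    fu <- suppressWarnings(qf(1 - alpha / 2, v, n - 1))
    lo <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    if (!is.finite(est)) est <- NA_real_ # degenerate 2x2 pure-interaction case
    if (!is.na(est) && est == 1) {
      lo <- if (!is.finite(lo)) 1 else lo
      hi <- 1
    }
  } else {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    if (mse == 0) {
      lo <- hi <- 1
    } else {
      fv <- msr / mse
      fl <- fv / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      fu <- fv * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      lo <- (fl - 1) / (fl + k - 1)
      hi <- (fu - 1) / (fu + k - 1)
    }
  }

  structure(list(estimate = est, ci_low = lo, ci_high = hi,
                 ms_rows = msr, ms_cols = msc, ms_error = mse,
                 n = n, k = k, form = form, confidence = confidence),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(%s,1) = %.3f (%d%% CI: %.3f to %.3f), n = %d, k = %d\n",
              if (x$form == "agreement") "A" else "C",
              x$estimate, round(100 * x$confidence), x$ci_low, x$ci_high,
              x$n, x$k))
  invisible(x)
}
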