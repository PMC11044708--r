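# Independent brute-force oracles and fixture builders used across tests.

# Quadratic-time running median with the definitional even-count rule
# (mean of the two central order statistics), independent of the package's
# compiled filter.
bf_moving_median <- function(x, window, align = "center") {
  n <- length(x)
  out <- numeric(n)
  back <- window %/% 2
  fwd <- window - back - 1
  for (i in seq_len(n)) {
    if (align == "center") {
      b <- min(back, i - 1)
      f <- min(fwd, n - i)
      if (b < back || f < fwd) {
        h <- min(b, f); lo <- i - h; hi <- i + h
      } else {
        lo <- i - back; hi <- i + fwd
      }
    } else {
      lo <- max(1, i - window + 1); hi <- i
    }
    w <- sort(x[lo:hi])
    m <- length(w)
    out[i] <- if (m %% 2) w[(m + 1) / 2] else (w[m / 2] + w[m / 2 + 1]) / 2
  }
  out
}

# Two-way ANOVA mean squares via stats::aov (independent route), then the
# single-measure two-way random-effects ICC formulas.
oracle_icc <- function(m, form = "agreement") {
  df <- data.frame(y = as.vector(m),
                   subj = factor(as.vector(row(m))),
                   rater = factor(as.vector(col(m))))
  tab <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- if ("Residuals" %in% trimws(rownames(tab)))
    tab[trimws(rownames(tab)) == "Residuals", "Mean Sq"] else 0
  n <- nrow(m); k <- ncol(m)
  est <- if (form == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
  list(estimate = est, msr = msr, msc = msc, mse = mse)
}

# 1 Hz trace from a plain y vector starting at a fixed origin
make_trace <- function(y, start = "2024-03-10 00:00:00", gap_tolerance = 5,
                       animal_id = "test") {
  t0 <- as.POSIXct(start, tz = "UTC")
  accel_trace(animal_id, time = t0 + seq_along(y) - 1, y = y,
              gap_tolerance = gap_tolerance)
}

# ethogram from behavior/offset triples (seconds relative to an origin)
make_eth <- function(behavior, start_s, stop_s,
                     origin = "2024-03-10 00:00:00", window_s = NULL,
                     animal_id = "test") {
  t0 <- as.POSIXct(origin, tz = "UTC")
  win <- if (!is.null(window_s)) t0 + window_s else NULL
  ethogram(animal_id,
           data.frame(behavior = behavior, start = t0 + start_s,
                      stop = t0 + stop_s),
           window = win)
}

# scenario with one constant (proportion, rate) target over all quarters
flat_scenario <- function(days = 0:1, proportion = 0.6, rate = 2,
                          sitting = list(prob = 0, mean_s = 40, sd_s = 20),
                          seed = 1, min_episode_s = 60, ...) {
  targets <- expand.grid(day_rel = days,
                         quarter = c("late_night", "morning", "afternoon",
                                     "early_night"),
                         stringsAsFactors = FALSE)
  targets$proportion <- proportion
  targets$rate <- rate
  scenario_config("crate", days, targets, sitting = sitting, seed = seed,
                  min_episode_s = min_episode_s, ...)
}

# noiseless sensor: exact 1 g standing, exact 0 g lying/sitting
exact_sensor <- function(noise_sd = 0, burst_s = 0, burst_sd = 0) {
  sensor_model(standing_deg = c(mean = 0, sd = 0),
               lying_deg = c(mean = 90, sd = 0),
               sitting_deg = c(mean = 90, sd = 0),
               noise_sd = noise_sd, burst_s = burst_s, burst_sd = burst_sd)
}
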