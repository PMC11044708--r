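#' Sensor model for a hind-leg accelerometer
#'
#' Physics of the y-axis (leg-parallel) channel: the reading is the cosine
#' of the leg angle from vertical, so a standing leg (near 0 deg) reads
#' about 1 g and a lying or sitting leg (tarsus near horizontal, 80-90 deg)
#' reads near 0 g. Per posture episode one leg angle is drawn; per sample
#' Gaussian noise is added; around every posture change a short burst of
#' high-variance movement noise is inserted.
#'
#' @param standing_deg,lying_deg,sitting_deg `c(mean, sd)` of the leg angle
#'   from vertical in degrees for each posture.
#' @param noise_sd per-sample noise sd in g.
#' @param burst_s duration of the movement burst around each posture
#'   change, seconds.
#' @param burst_sd additional noise sd in g during a burst.
#' @param rate sampling rate in Hz (default 1).
#' @return a `sensor_model` list.
#' @export
sensor_model <- function(standing_deg = c(mean = 5, sd = 3),
                         lying_deg = c(mean = 85, sd = 3),
                         sitting_deg = c(mean = 85, sd = 3),
                         noise_sd = 0.05, burst_s = 5, burst_sd = 0.3,
                         rate = 1) {
  ang <- rbind(standing = standing_deg, lying = lying_deg,
               sitting = sitting_deg)
  stopifnot(all(ang[, 1] >= 0 & ang[, 1] <= 90), all(ang[, 2] >= 0),
            noise_sd >= 0, burst_s >= 0, burst_sd >= 0, rate > 0)
  structure(list(angles = ang, noise_sd = noise_sd, burst_s = burst_s,
                 burst_sd = burst_sd, rate = rate), class = "sensor_model")
}

#' Scenario configuration for the behaviour simulator
#'
#' Defines, per day relative to parturition and day quarter, the target
#' lying (rest) proportion and rest-bout rate that the simulated two-state
#' renewal process should realize, plus the transitional-sitting
#' parameters.
#'
#' @param housing `"crate"` or `"free"`.
#' @param days integer vector of days relative to parturition (day 0 =
#'   parturition day) covered by the scenario.
#' @param targets data.frame with `day_rel`, `quarter` (one of
#'   `late_night`, `morning`, `afternoon`, `early_night`), `proportion`
#'   (target rest proportion in `[0,1]`) and `rate` (target rest bouts per
#'   6 h, >= 0). `rate = 0` requires `proportion` 0 or 1 (constant-state
#'   quarter); any other proportion is unreachable and rejected.
#' @param sitting list with `prob` (probability that each of the
#'   lie-down transition, the stand-up transition and an interior
#'   interruption of a rest episode passes through sitting), `mean_s` and
#'   `sd_s` of the sitting duration in seconds.
#' @param seed integer seed for reproducibility (`NULL`: use current RNG
#'   state).
#' @param min_episode_s minimum episode duration in seconds (shifted
#'   exponential floor, a minimum-bout criterion; default 60).
#' @param parturition_time POSIXct of day 0 (only its date is used).
#' @param animal_id identifier given to simulated outputs.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(housing = c("crate", "free"), days = -3:27,
                            targets,
                            sitting = list(prob = 0.3, mean_s = 40, sd_s = 20),
                            seed = NULL, min_episode_s = 60,
                            parturition_time = as.POSIXct("2024-03-15 04:00:00", tz = "UTC"),
                            animal_id = "sow_sim") {
  housing <- match.arg(housing)
  stopifnot(is.data.frame(targets),
            all(c("day_rel", "quarter", "proportion", "rate") %in% names(targets)),
            all(targets$quarter %in% .quarters),
            all(days %in% targets$day_rel))
  if (any(targets$proportion < 0 | targets$proportion > 1)) {
    stop("target proportions must lie in [0, 1]", call. = FALSE)
  }
  if (any(targets$rate < 0)) stop("target rates must be >= 0", call. = FALSE)
  bad <- targets$rate == 0 & targets$proportion > 0 & targets$proportion < 1
  if (any(bad)) {
    stop("rate 0 with 0 < proportion < 1 is an unreachable target", call. = FALSE)
  }
  sto <- targets$rate > 0
  mu_r <- targets$proportion[sto] * 21600 / targets$rate[sto]
  mu_u <- (1 - targets$proportion[sto]) * 21600 / targets$rate[sto]
  if (any(c(mu_r, mu_u) <= min_episode_s)) {
    stop("target (proportion, rate) implies mean episode duration below the minimum episode duration",
         call. = FALSE)
  }
  stopifnot(is.list(sitting), sitting$prob >= 0, sitting$prob <= 1,
            sitting$mean_s > 0, sitting$sd_s >= 0, min_episode_s >= 1)
  structure(list(housing = housing, days = sort(unique(as.integer(days))),
                 targets = targets, sitting = sitting, seed = seed,
                 min_episode_s = min_episode_s,
                 parturition_time = parturition_time,
                 animal_id = animal_id),
            class = "scenario_config")
}

#' Preset scenarios for the two farrowing systems
#'
#' Scenario fixtures encoding the qualitative day-course shapes of lying
#' behaviour around parturition in the two housing systems, as
#' piecewise-linear interpolations over days -3 to 27:
#'
#' * `crate_default`: bout rate rises toward parturition (peak about five
#'   rest bouts per 6 h on day 0), collapses to near zero immediately after
#'   parturition, then recovers moderately; lying time dips before
#'   parturition, peaks after it, is reduced over days 5-20 and rises again
#'   toward weaning.
#' * `free_default`: bout rate starts high, declines toward parturition and
#'   is lowest just after it, stays flat until day 15 and climbs to about
#'   eight bouts per 6 h by day 20; lying time rises toward parturition and
#'   falls toward weaning, especially during the day.
#'
#' In both systems the early-night quarter (18:00-24:00) is almost entirely
#' lying on every day. The presets are scenario fixtures, not empirical
#' reproductions.
#'
#' @param name `"crate_default"` or `"free_default"`.
#' @param days days relative to parturition (default -3:27).
#' @param seed seed stored in the config.
#' @param sitting transitional-sitting parameters, see [scenario_config()].
#' @param animal_id identifier for simulated outputs.
#' @return a [scenario_config()].
#' @export
preset <- function(name = c("crate_default", "free_default"), days = -3:27,
                   seed = NULL,
                   sitting = list(prob = 0.3, mean_s = 40, sd_s = 20),
                   animal_id = name) {
  name <- match.arg(name)
  animal_id <- animal_id[1]
  interp <- function(kx, ky, x) approx(kx, ky, xout = x, rule = 2)$y
  if (name == "crate_default") {
    housing <- "crate"
    rate <- interp(c(-3, -1, 0, 1, 3, 10, 20, 27),
                   c(2, 4, 5, 0.5, 0.5, 1.5, 2, 2.5), days)
    day_prop <- interp(c(-3, -1, 0, 1, 4, 10, 20, 27),
                       c(0.8, 0.65, 0.8, 0.95, 0.95, 0.7, 0.7, 0.85), days)
    night_prop <- day_prop
  } else {
    housing <- "free"
    rate <- interp(c(-3, -1, 0, 1, 15, 20, 27),
                   c(6, 3, 2.5, 1, 1, 8, 7), days)
    day_prop <- interp(c(-3, 0, 15, 20, 27),
                       c(0.6, 0.9, 0.9, 0.8, 0.6), days)
    night_prop <- interp(c(-3, -1, 0, 1, 27),
                         c(0.8, 0.65, 0.8, 0.95, 0.85), days)
  }
  targets <- do.call(rbind, lapply(seq_along(days), function(i) {
    data.frame(day_rel = days[i], quarter = .quarters,
               proportion = c(night_prop[i], day_prop[i], day_prop[i], 0.97),
               rate = rate[i])
  }))
  scenario_config(housing, days, targets, sitting = sitting, seed = seed,
                  animal_id = animal_id)
}

# Solve a quarter's (proportion, rate) target into mean episode durations;
# rate is rest bouts per 6 h, so one rest+upright cycle has mean length
# 21600 / rate and the rest share is the target proportion.
cell_means <- function(p, r) {
  c(rest = p * 21600 / r, upright = (1 - p) * 21600 / r)
}

# Shifted-exponential episode duration, rounded to whole seconds
draw_duration <- function(mu, floor_s) {
  max(1, round(floor_s + rexp(1, rate = 1 / (mu - floor_s))))
}

#' Simulate a ground-truth ethogram
#'
#' Simulates the sow's rest/upright alternation as a two-state renewal
#' process over the scenario's days: within each day quarter, episode
#' durations are drawn from shifted-exponential distributions whose means
#' are solved from the quarter's target (proportion, rate); the state is
#' carried continuously across quarter boundaries, with durations redrawn
#' when the targets change. Each rest episode is then decomposed into lying
#' sub-bouts flanked or interrupted by transitional sitting according to
#' the sitting parameters, yielding the observer-style ethogram, while the
#' undecomposed rest episodes form the ground-truth rest-bout table.
#'
#' @param config a [scenario_config()].
#' @return list with `ethogram` (an [ethogram()]), `truth` (a
#'   [bout_table()] of rest bouts, `source = "truth"`), and `window`.
#' @export
simulate_ethogram <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  with_local_seed(config$seed, {
    day0 <- as.numeric(as.POSIXct(as.Date(config$parturition_time, tz = .tz),
                                  tz = .tz))
    t0 <- day0 + min(config$days) * 86400
    tend <- day0 + (max(config$days) + 1) * 86400

    # per-cell parameter lookup in chronological order
    cells <- expand.grid(quarter = .quarters, day_rel = config$days,
                         stringsAsFactors = FALSE)
    key <- paste(config$targets$day_rel, config$targets$quarter)
    idx <- match(paste(cells$day_rel, cells$quarter), key)
    if (anyNA(idx)) stop("targets missing for some day/quarter", call. = FALSE)
    p <- config$targets$proportion[idx]
    r <- config$targets$rate[idx]
    cell_start <- t0 + (seq_len(nrow(cells)) - 1L) * 21600

    # merge consecutive cells with identical targets into blocks so that
    # episodes are only redrawn where the behaviour regime changes
    new_block <- c(TRUE, p[-1] != p[-length(p)] | r[-1] != r[-length(r)])
    block_id <- cumsum(new_block)
    blk_start <- cell_start[new_block]
    blk_end <- c(cell_start[new_block][-1], tend)
    blk_p <- p[new_block]
    blk_r <- r[new_block]

    floor_s <- config$min_episode_s
    state <- if (blk_r[1] == 0) (blk_p[1] == 1)
             else runif(1) < blk_p[1] # TRUE = rest
    switches <- numeric(1024) # times at which the state toggles
    n_sw <- 0L
    push <- function(t) {
      if (n_sw == length(switches)) {
        switches[2 * n_sw] <<- 0
      }
      n_sw <<- n_sw + 1L
      switches[n_sw] <<- t
    }
    t <- t0
    for (b in seq_along(blk_start)) {
      bend <- blk_end[b]
      if (blk_r[b] == 0) {
        forced <- blk_p[b] == 1
        if (state != forced) {
          push(t)
          state <- forced
        }
        t <- bend
        next
      }
      mu <- cell_means(blk_p[b], blk_r[b])
      while (t < bend) {
        dur <- draw_duration(if (state) mu[["rest"]] else mu[["upright"]],
                             floor_s)
        if (t + dur >= bend) {
          t <- bend
        } else {
          t <- t + dur
          push(t)
          state <- !state
        }
      }
    }
    switches <- switches[seq_len(n_sw)]

    # reconstruct episodes from the switch times
    bounds <- c(t0, switches, tend)
    ep_start <- bounds[-length(bounds)]
    ep_stop <- bounds[-1]
    start_state <- if (length(switches) %% 2 == 0) state
                   else !state # state after last switch is `state`
    ep_rest <- rep(c(start_state, !start_state),
                   length.out = length(ep_start))

    rest_i <- which(ep_rest)
    truth <- bout_table(config$animal_id, "rest",
                        start = as.POSIXct(ep_start[rest_i], origin = "1970-01-01", tz = .tz),
                        stop = as.POSIXct(ep_stop[rest_i], origin = "1970-01-01", tz = .tz),
                        truncated = ep_start[rest_i] == t0 | ep_stop[rest_i] == tend,
                        source = "truth")

    events <- decompose_rest_episodes(ep_start[rest_i], ep_stop[rest_i],
                                      config$sitting)
    eth <- ethogram(config$animal_id, events,
                    window = as.POSIXct(c(t0, tend), origin = "1970-01-01", tz = .tz))
    list(ethogram = eth, truth = truth,
         window = as.POSIXct(c(t0, tend), origin = "1970-01-01", tz = .tz))
  })
}

# Split each rest episode into lying sub-bouts with optional transitional
# sitting at entry, exit, and one interior interruption; all sub-events are
# contiguous and tile the episode exactly.
decompose_rest_episodes <- function(starts, stops, sitting) {
  if (!length(starts)) {
    return(data.frame(behavior = character(0),
                      start = as.POSIXct(numeric(0), origin = "1970-01-01", tz = .tz),
                      stop = as.POSIXct(numeric(0), origin = "1970-01-01", tz = .tz)))
  }
  min_ly <- 5 # smallest lying fragment, seconds
  acc <- vector("list", length(starts))
  sit_dur <- function() max(1, round(rnorm(1, sitting$mean_s, sitting$sd_s)))
  for (i in seq_along(starts)) {
    D <- stops[i] - starts[i]
    d_entry <- if (runif(1) < sitting$prob) sit_dur() else 0
    d_exit <- if (runif(1) < sitting$prob) sit_dur() else 0
    d_int <- if (runif(1) < sitting$prob) sit_dur() else 0
    # shed sittings that do not fit, interior first
    if (d_entry + d_exit + d_int > D - 2 * min_ly) d_int <- 0
    if (d_entry + d_exit > D - min_ly) d_exit <- 0
    if (d_entry > D - min_ly) d_entry <- 0
    lying_total <- D - d_entry - d_exit - d_int
    if (d_int > 0) {
      ly1 <- round(runif(1, 0.2, 0.8) * lying_total)
      ly1 <- min(max(ly1, min_ly), lying_total - min_ly)
      parts <- data.frame(
        behavior = c("sitting", "lying", "sitting", "lying", "sitting"),
        dur = c(d_entry, ly1, d_int, lying_total - ly1, d_exit))
    } else {
      parts <- data.frame(behavior = c("sitting", "lying", "sitting"),
                          dur = c(d_entry, lying_total, d_exit))
    }
    parts <- parts[parts$dur > 0, , drop = FALSE]
    off <- starts[i] + cumsum(c(0, head(parts$dur, -1)))
    acc[[i]] <- list(parts$behavior, off, off + parts$dur)
  }
  beh <- unlist(lapply(acc, `[[`, 1))
  ev_s <- unlist(lapply(acc, `[[`, 2))
  ev_e <- unlist(lapply(acc, `[[`, 3))
  data.frame(behavior = beh,
             start = as.POSIXct(ev_s, origin = "1970-01-01", tz = .tz),
             stop = as.POSIXct(ev_e, origin = "1970-01-01", tz = .tz))
}

#' Render a synthetic accelerometer trace from an ethogram
#'
#' Generates the y-axis signal of a hind-leg logger for an ethogram: per
#' posture episode a leg angle from vertical is drawn from the sensor
#' model (standing near vertical, lying/sitting near horizontal), each
#' sample reads `cos(angle)` g plus Gaussian noise, and a burst of
#' high-variance samples is inserted around every posture change. Time not
#' covered by an event is upright/standing.
#'
#' @param eth an [ethogram()].
#' @param model a [sensor_model()].
#' @param window POSIXct length-2 render window; defaults to the
#'   ethogram's observation window.
#' @param seed integer seed (`NULL`: use current RNG state).
#' @param gap_tolerance forwarded to the resulting [accel_trace()].
#' @return an [accel_trace()].
#' @export
render_accel <- function(eth, model = sensor_model(), window = NULL,
                         seed = NULL, gap_tolerance = 5) {
  stopifnot(inherits(eth, "ethogram"), inherits(model, "sensor_model"))
  if (is.null(window)) window <- eth$window
  stopifnot(!anyNA(window))
  with_local_seed(seed, {
    step <- 1 / model$rate
    w0 <- as.numeric(window[1]); w1 <- as.numeric(window[2])

    # tile the window with posture intervals (events + upright filler)
    ev <- eth$events
    ev <- ev[as.numeric(ev$stop) > w0 & as.numeric(ev$start) < w1, , drop = FALSE]
    bnd_s <- pmax(as.numeric(ev$start), w0)
    bnd_e <- pmin(as.numeric(ev$stop), w1)
    pieces <- data.frame(start = bnd_s, stop = bnd_e,
                         posture = ev$behavior)
    gaps_s <- c(w0, bnd_e)
    gaps_e <- c(bnd_s, w1)
    fill <- gaps_e > gaps_s
    pieces <- rbind(pieces,
                    data.frame(start = gaps_s[fill], stop = gaps_e[fill],
                               posture = "standing"))
    pieces <- pieces[order(pieces$start), , drop = FALSE]

    times <- seq(w0, w1 - step, by = step)
    piece_of <- findInterval(times, pieces$start)
    ang <- model$angles
    ep_angle <- pmin(90, pmax(0, rnorm(nrow(pieces),
                                       ang[pieces$posture, 1],
                                       ang[pieces$posture, 2])))
    y <- cospi(ep_angle[piece_of] / 180) +
      rnorm(length(times), 0, model$noise_sd)

    if (model$burst_s > 0 && model$burst_sd > 0 && nrow(pieces) > 1) {
      changes <- pieces$start[-1]
      changes <- changes[pieces$posture[-1] != pieces$posture[-nrow(pieces)]]
      if (length(changes)) {
        half <- model$burst_s / 2
        idx <- findInterval(times, changes)
        near_prev <- idx >= 1 & (times - changes[pmax(idx, 1)]) < half
        near_next <- idx < length(changes) &
          (changes[pmin(idx + 1, length(changes))] - times) <= half
        in_burst <- near_prev | near_next
        y[in_burst] <- y[in_burst] + rnorm(sum(in_burst), 0, model$burst_sd)
      }
    }
    accel_trace(eth$animal_id,
                time = as.POSIXct(times, origin = "1970-01-01", tz = .tz),
                y = y, gap_tolerance = gap_tolerance,
                nominal_rate = model$rate)
  })
}
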