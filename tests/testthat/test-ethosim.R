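test_that("constant-state targets produce constant-state quarters", {
  # proportion 1, rate 0 over a full day: one rest bout spanning 24 h
  cfg <- flat_scenario(days = 0, proportion = 1, rate = 0, seed = 2)
  sim <- simulate_ethogram(cfg)
  expect_equal(nrow(sim$truth), 1)
  expect_equal(sim$truth$duration_s, 86400)
  expect_equal(sim$ethogram$events$behavior, "lying")

  # proportion 0 everywhere: empty ethogram
  cfg0 <- flat_scenario(days = 0, proportion = 0, rate = 0, seed = 2)
  sim0 <- simulate_ethogram(cfg0)
  expect_equal(nrow(sim0$truth), 0)
  expect_equal(nrow(sim0$ethogram$events), 0)
})

test_that("unreachable and invalid targets are rejected", {
  expect_error(flat_scenario(proportion = 0.5, rate = 0), "unreachable")
  expect_error(flat_scenario(proportion = 1.2, rate = 1), "proportion")
  expect_error(flat_scenario(proportion = 0.5, rate = -1), ">= 0")
  # target implying a mean episode below the floor
  expect_error(flat_scenario(proportion = 0.999, rate = 5), "minimum episode")
})

test_that("realized proportion and bout rate hit the renewal targets", {
  # long-run Monte Carlo over many simulated days at proportion 0.5 and
  # five bouts per 6 h, no sitting
  cfg <- flat_scenario(days = 0:999, proportion = 0.5, rate = 5, seed = 3)
  sim <- simulate_ethogram(cfg)
  n_days <- 1000
  prop <- sum(sim$truth$duration_s) / (n_days * 86400)
  rate <- nrow(sim$truth) / (n_days * 4)
  expect_lt(abs(prop - 0.5), 0.02)
  expect_lt(abs(rate - 5) / 5, 0.05)
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- flat_scenario(days = 0:1, proportion = 0.6, rate = 3,
                       sitting = list(prob = 0.4, mean_s = 40, sd_s = 20),
                       seed = 4)
  s1 <- simulate_ethogram(cfg)
  s2 <- simulate_ethogram(cfg)
  expect_identical(s1$ethogram$events, s2$ethogram$events)
  expect_identical(as.data.frame(s1$truth), as.data.frame(s2$truth))
  t1 <- render_accel(s1$ethogram, sensor_model(), seed = 5)
  t2 <- render_accel(s2$ethogram, sensor_model(), seed = 5)
  expect_identical(t1$samples, t2$samples)
})

test_that("ethogram events tile the ground-truth rest bouts exactly", {
  cfg <- flat_scenario(days = 0:2, proportion = 0.6, rate = 3,
                       sitting = list(prob = 0.5, mean_s = 30, sd_s = 15),
                       seed = 8)
  sim <- simulate_ethogram(cfg)
  ev_total <- sum(as.numeric(sim$ethogram$events$stop) -
                  as.numeric(sim$ethogram$events$start))
  expect_identical(ev_total, sum(sim$truth$duration_s))
  # merging transitional sitting reconstructs the truth table exactly
  merged <- merge_transitional_sitting(sim$ethogram)
  expect_equal(merged$start, sim$truth$start)
  expect_equal(merged$stop, sim$truth$stop)
})

test_that("noise-free rendering is exact cosine physics", {
  eth <- make_eth(c("lying", "sitting"), c(100, 400), c(400, 430),
                  window_s = c(0, 600))
  tr <- render_accel(eth, exact_sensor(), seed = 1)
  y <- tr$samples$y
  expect_true(all(y %in% c(0, 1)))
  expect_equal(y[1:100], rep(1, 100))    # standing before lying
  expect_equal(y[101:430], rep(0, 330))  # lying + sitting both flat
  expect_equal(y[431:600], rep(1, 170))  # standing after
})

test_that("noise-free pipeline recovers ground truth within half a window", {
  cfg <- flat_scenario(days = 0:1, proportion = 0.6, rate = 3,
                       sitting = list(prob = 0.4, mean_s = 40, sd_s = 20),
                       seed = 12)
  sim <- simulate_ethogram(cfg)
  tr <- render_accel(sim$ethogram, exact_sensor(), seed = 13)
  b <- extract_bouts(classify_samples(tr))
  expect_equal(nrow(b), nrow(sim$truth))
  expect_true(all(abs(as.numeric(b$start) - as.numeric(sim$truth$start)) <= 16))
  expect_true(all(abs(as.numeric(b$stop) - as.numeric(sim$truth$stop)) <= 16))
})

test_that("movement bursts are rejected by the median filter", {
  # one lying episode with strong transition bursts: classification of
  # bouts >= 60 s is unchanged relative to the burst-free render
  eth <- make_eth("lying", 300, 900, window_s = c(0, 1200))
  clean <- render_accel(eth, exact_sensor(), seed = 21)
  noisy <- render_accel(eth, exact_sensor(burst_s = 10, burst_sd = 0.5), seed = 21)
  b_clean <- extract_bouts(classify_samples(clean))
  b_noisy <- extract_bouts(classify_samples(noisy))
  expect_equal(nrow(b_noisy), 1)
  expect_equal(as.data.frame(b_noisy), as.data.frame(b_clean))
  # oracle: brute-force median of the noisy |y| crosses 0.75 at the same
  # samples as the compiled filter
  m <- bf_moving_median(abs(noisy$samples$y), 32)
  expect_identical(m < 0.75,
                   classify_samples(noisy)$data$state == "lying")
})

test_that("presets encode the published day-course directions", {
  crate <- preset("crate_default")
  free <- preset("free_default")
  rate_at <- function(cfg, d, q = "morning") {
    t <- cfg$targets
    t$rate[t$day_rel == d & t$quarter == q]
  }
  prop_at <- function(cfg, d, q) {
    t <- cfg$targets
    t$proportion[t$day_rel == d & t$quarter == q]
  }
  # crate: bout rate peaks at parturition, collapses right after
  expect_gt(rate_at(crate, 0), rate_at(crate, 2))
  # free: nest-leaving rise between day 10 and day 20
  expect_gt(rate_at(free, 20), rate_at(free, 10))
  # both systems lie almost all of the time from 18:00 to 24:00, every day
  for (cfg in list(crate, free)) {
    en <- cfg$targets$proportion[cfg$targets$quarter == "early_night"]
    expect_true(all(en >= 0.95))
  }
  expect_error(preset("outdoor"), "arg")
})

test_that("noisy pipeline recovers daily lying proportion within 0.02", {
  # long bouts (>= 300 s) and moderate sensor noise
  cfg <- flat_scenario(days = 0:2, proportion = 0.7, rate = 2,
                       sitting = list(prob = 0.3, mean_s = 60, sd_s = 20),
                       seed = 31, min_episode_s = 300)
  sim <- simulate_ethogram(cfg)
  tr <- render_accel(sim$ethogram, sensor_model(noise_sd = 0.1), seed = 32)
  b <- extract_bouts(classify_samples(tr))
  for (d in 0:2) {
    d0 <- as.numeric(sim$window[1]) + d * 86400
    est <- sum(pmax(0, pmin(as.numeric(b$stop), d0 + 86400) -
                       pmax(as.numeric(b$start), d0)))
    truth <- sum(pmax(0, pmin(as.numeric(sim$truth$stop), d0 + 86400) -
                         pmax(as.numeric(sim$truth$start), d0)))
    expect_lt(abs(est - truth) / 86400, 0.02)
  }
})
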