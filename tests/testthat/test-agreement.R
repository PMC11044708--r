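test_that("the three transitional-sitting cases each merge to one rest bout", {
  # sitting between two lying bouts
  m1 <- merge_transitional_sitting(
    make_eth(c("lying", "sitting", "lying"), c(0, 60, 90), c(60, 90, 150)))
  expect_equal(nrow(m1), 1)
  expect_equal(m1$duration_s, 150)
  expect_equal(m1$behavior, "rest")

  # sitting before lying down
  m2 <- merge_transitional_sitting(
    make_eth(c("sitting", "lying"), c(0, 20), c(20, 620)))
  expect_equal(nrow(m2), 1)
  expect_equal(m2$duration_s, 620)

  # sitting before standing up
  m3 <- merge_transitional_sitting(
    make_eth(c("lying", "sitting"), c(0, 600), c(600, 640)))
  expect_equal(nrow(m3), 1)
  expect_equal(m3$duration_s, 640)
})

test_that("sitting alone between standing periods stays upright", {
  m <- merge_transitional_sitting(make_eth("sitting", 0, 120, window_s = c(-300, 400)))
  expect_equal(nrow(m), 0)
})

test_that("chains break when the gap exceeds the adjacency tolerance", {
  eth <- make_eth(c("lying", "lying"), c(0, 100), c(60, 160))
  expect_equal(nrow(merge_transitional_sitting(eth, adjacency_tolerance = 1)), 2)
  expect_equal(nrow(merge_transitional_sitting(eth, adjacency_tolerance = 60)), 1)
})

test_that("merging never increases bout count nor decreases rest duration", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:20, 1)
    durs <- sample(10:300, n, replace = TRUE)
    gaps <- sample(c(0, 0, 0, 5, 120), n, replace = TRUE)
    starts <- cumsum(c(0, (durs + gaps)[-n]))
    beh <- sample(c("lying", "sitting"), n, replace = TRUE)
    eth <- make_eth(beh, starts, starts + durs)
    raw <- ethogram_bouts(eth)
    merged <- merge_transitional_sitting(eth)
    expect_lte(nrow(merged), max(nrow(raw), 1))
    expect_gte(sum(merged$duration_s), sum(raw$duration_s))
  }
})

test_that("build_ratings scores bouts per window and drops uncovered windows", {
  t0 <- as.POSIXct("2024-03-10 00:00:00", tz = "UTC")
  windows <- data.frame(subject_id = paste0("d", 1:5),
                        start = t0 + (0:4) * 86400,
                        stop = t0 + (1:5) * 86400)
  b <- bout_table("a", "lying",
                  start = t0 + c(3600, 90000, 180000, 266400, 352800),
                  stop = t0 + c(7200, 93600, 183600, 270000, 356400),
                  source = "ethogram")
  m <- build_ratings(b, b, windows, measure = "bout_count")
  expect_equal(unname(m[, "video"]), unname(m[, "sensor"]))
  expect_equal(nrow(m), 5)

  # video-only lying for 1 h, sensor silent but covered
  sensor_empty <- bout_table(source = "sensor")
  v <- bout_table("a", "lying", start = t0 + 3600, stop = t0 + 7200,
                  source = "ethogram")
  cov <- data.frame(start = t0, stop = t0 + 86400)
  m2 <- build_ratings(v, sensor_empty, windows[1, ],
                      measure = "lying_seconds", sensor_coverage = cov)
  expect_equal(unname(m2[1, ]), c(3600, 0))

  # zero sensor coverage in later windows drops those rows
  expect_message(
    m3 <- build_ratings(v, sensor_empty, windows, sensor_coverage = cov),
    "dropped")
  expect_equal(nrow(m3), 1)
  expect_equal(attr(m3, "dropped"), 4L)

  # switching the measure never changes the row set
  m4 <- build_ratings(v, sensor_empty, windows, measure = "lying_seconds",
                      sensor_coverage = cov)
  expect_equal(rownames(m4), rownames(m3))
})

test_that("ICC(A,1) matches the definitional ANOVA oracle on the 6x2 fixture", {
  m <- cbind(c(1, 3, 5, 7, 9, 11), c(2, 4, 6, 8, 10, 12))
  r <- icc_agreement(m)
  o <- oracle_icc(m)
  expect_equal(r$estimate, o$estimate, tolerance = 1e-12)
  expect_equal(r$ms_rows, o$msr, tolerance = 1e-12)
  expect_equal(r$ms_cols, o$msc, tolerance = 1e-12)
  # frozen: ICC(A,1) = 28/29 on this fixture (zero residual mean square),
  # matching an independent published implementation to machine precision
  expect_equal(r$estimate, 28 / 29, tolerance = 1e-12)
  expect_lt(r$ci_low, r$estimate)
  expect_gte(r$ci_high, r$estimate)
})

test_that("ICC estimate and CI match an independent published implementation", {
  m <- matrix(c(9.511483941521119, 9.383215560252507,
                11.386078662710608, 11.253123620685471,
                9.283000682911247, 8.247118389205143,
                7.298972661264903, 8.023527678186465,
                7.29177309719975, 8.178371883444614,
                5.123837595209769, 5.735522595225637,
                8.338695770000584, 9.945339676717635,
                12.753199255219897, 14.291910095485301),
              ncol = 2, byrow = TRUE)
  a <- icc_agreement(m)
  expect_equal(a$estimate, 0.9231798824379979, tolerance = 1e-12)
  expect_equal(round(c(a$ci_low, a$ci_high), 2), c(0.67, 0.98))
  co <- icc_agreement(m, form = "consistency")
  expect_equal(co$estimate, 0.9348856961049586, tolerance = 1e-12)
  expect_equal(round(c(co$ci_low, co$ci_high), 2), c(0.71, 0.99))
})

test_that("identical columns with row variance give ICC 1", {
  m <- cbind(c(1, 5, 9, 2), c(1, 5, 9, 2))
  r <- icc_agreement(m)
  expect_equal(r$estimate, 1)
})

test_that("a constant offset with tiny row variance gives ICC near 0", {
  c1 <- c(0, 0.01, -0.02, 0.015, -0.005, 0.02)
  r <- icc_agreement(cbind(c1, c1 + 100))
  # near-degenerate: compare absolutely, both estimates are ~4e-8
  expect_equal(r$estimate, oracle_icc(cbind(c1, c1 + 100))$estimate,
               tolerance = 1e-6)
  expect_lt(abs(r$estimate), 1e-6)
})

test_that("ICC matches the ANOVA oracle on random matrices up to 50x4", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(2:50, 1)
    k <- sample(2:4, 1)
    m <- matrix(rnorm(n * k, 10, 3), n, k) + rnorm(n)
    for (form in c("agreement", "consistency")) {
      r <- icc_agreement(m, form = form)
      o <- oracle_icc(m, form = form)
      expect_equal(r$estimate, o$estimate, tolerance = 1e-10)
      expect_equal(r$ms_error, o$mse, tolerance = 1e-10)
    }
  }
})

test_that("ICC is invariant to location/scale shifts and row permutation", {
  set.seed(43)
  for (rep in 1:50) {
    n <- sample(4:20, 1)
    m <- matrix(rnorm(n * 2, 5, 2), n, 2) + rnorm(n, 0, 3)
    r0 <- icc_agreement(m)
    shift <- icc_agreement(m + runif(1, -50, 50))
    scale <- icc_agreement(m * runif(1, 0.1, 20))
    perm <- icc_agreement(m[sample(n), ])
    expect_equal(shift$estimate, r0$estimate, tolerance = 1e-9)
    expect_equal(scale$estimate, r0$estimate, tolerance = 1e-9)
    expect_equal(perm$estimate, r0$estimate, tolerance = 1e-9)
  }
})

test_that("degenerate and undersized matrices are rejected explicitly", {
  expect_error(icc_agreement(matrix(5, 4, 2)), class = "sowlying_degenerate")
  expect_error(icc_agreement(matrix(1:4, 4, 1)), "at least 2 x 2")
  expect_error(icc_agreement(matrix(1:2, 1, 2)), "at least 2 x 2")
})

test_that("sitting interruptions depress raw-count agreement; merging restores it", {
  # subjects with different true bout rates; half the rest episodes are
  # interrupted by sitting, so raw video counts disagree with the sensor
  set.seed(47)
  days <- 0:7
  targets <- do.call(rbind, lapply(days, function(d) {
    data.frame(day_rel = d,
               quarter = c("late_night", "morning", "afternoon", "early_night"),
               proportion = 0.7, rate = 1 + (d %% 4) * 1.5)
  }))
  cfg <- scenario_config("crate", days, targets,
                         sitting = list(prob = 0.5, mean_s = 40, sd_s = 15),
                         seed = 48)
  sim <- simulate_ethogram(cfg)
  tr <- render_accel(sim$ethogram, sensor_model(), seed = 49)
  sensor <- extract_bouts(classify_samples(tr))
  t0 <- sim$window[1]
  windows <- data.frame(subject_id = paste0("d", days),
                        start = t0 + days * 86400,
                        stop = t0 + (days + 1) * 86400)
  raw <- icc_agreement(build_ratings(ethogram_bouts(sim$ethogram), sensor,
                                     windows, measure = "bout_count"))
  merged <- icc_agreement(build_ratings(merge_transitional_sitting(sim$ethogram),
                                        sensor, windows,
                                        measure = "bout_count"))
  expect_lt(raw$estimate, merged$estimate)
  expect_gt(merged$estimate, 0.8)
})
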