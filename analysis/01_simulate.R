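#!/usr/bin/env Rscript
# Simulate one lactation (day -3 to 27 relative to parturition) per housing
# system: ground-truth ethogram + rest bouts, and the 1 Hz hind-leg
# accelerometer trace a logger would have recorded. Small tables go to
# results/sim/, the bulky raw traces to scratch/sim/.

suppressPackageStartupMessages(library(sowlying))
seed <- 20240315L

dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)
dir.create("scratch/sim", recursive = TRUE, showWarnings = FALSE)

for (name in c("crate_default", "free_default")) {
  sc <- preset(name, days = -3:27)
  sc$seed <- seed
  sim <- simulate_ethogram(sc)
  trace <- render_accel(sim$ethogram, sensor_model(), seed = seed + 1L)
  stem <- sub("_default$", "", name)
  write_ethogram(sim$ethogram, sprintf("results/sim/%s_ethogram.csv", stem))
  write_bouts(sim$truth, sprintf("results/sim/%s_truth_bouts.csv", stem))
  write_accel_csv(trace, sprintf("scratch/sim/%s_accel.csv", stem))
  cat(sprintf(
    "%s: %d rest bouts over 31 d, %.1f%% of time at rest; %d ethogram events (%d sitting)\n",
    stem, nrow(sim$truth), 100 * sum(sim$truth$duration_s) / (31 * 86400),
    nrow(sim$ethogram$events),
    sum(sim$ethogram$events$behavior == "sitting")))
}
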