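#!/usr/bin/env Rscript
# Collapse the sensor bouts into the parturition-aligned quarter-day
# summary tables that the housing-system comparison consumes, and report
# the headline day-course features.

suppressPackageStartupMessages(library(sowlying))
parturition <- as.POSIXct("2024-03-15 04:00:00", tz = "UTC")

for (stem in c("crate", "free")) {
  bouts <- read_bouts_csv(sprintf("results/sim/%s_bouts.csv", stem))
  trace <- read_accel_csv(sprintf("scratch/sim/%s_accel.csv", stem),
                          column_map = c(time = "time", y = "y"))
  s <- summarize_quarters(bouts, trace_coverage(trace),
                          meta = list(animal_id = stem,
                                      parturition_time = parturition))
  write_summaries(s, sprintf("results/sim/%s_quarters.csv", stem))

  daily_bouts <- tapply(s$n_bouts, s$day_rel, mean)
  en <- s$proportion[s$quarter == "early_night"]
  cat(sprintf("%s: bouts/6h peak %.2f on day %s; minimum %.2f on day %s\n",
              stem, max(daily_bouts), names(which.max(daily_bouts)),
              min(daily_bouts), names(which.min(daily_bouts))))
  cat(sprintf("%s: early-night lying proportion %.3f (range %.3f-%.3f)\n",
              stem, mean(en), min(en), max(en)))
}
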