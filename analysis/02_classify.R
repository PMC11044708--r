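#!/usr/bin/env Rscript
# Classify the simulated logger traces sample by sample (moving median over
# 32 samples, critical lying value 0.75 g) and extract lying bouts.

suppressPackageStartupMessages(library(sowlying))

for (stem in c("crate", "free")) {
  trace <- read_accel_csv(sprintf("scratch/sim/%s_accel.csv", stem),
                          column_map = c(time = "time", y = "y"))
  bouts <- extract_bouts(classify_samples(trace))
  write_bouts(bouts, sprintf("results/sim/%s_bouts.csv", stem))
  truth <- read_bouts_csv(sprintf("results/sim/%s_truth_bouts.csv", stem))
  cat(sprintf(
    "%s: %d sensor bouts (truth %d); lying %.1f h (truth rest %.1f h)\n",
    stem, nrow(bouts), nrow(truth),
    sum(bouts$duration_s) / 3600, sum(truth$duration_s) / 3600))
}
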