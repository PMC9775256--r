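#!/usr/bin/env Rscript

# Step 4 — the population effect.
#
# Repeats the damage study on the genetically more homogeneous Italian
# subsample (119 specimens) and compares its accuracy with the full
# two-population sample, asking whether a smaller but more uniform
# reference performs as well as a larger, more diverse one.

suppressPackageStartupMessages(library(morphorec))

ds <- read_csv_wide("results/sample_landmarks.csv")
italian <- run_study(ds, n_targets = 30, seed = 44L,
                     population_filter = "Italian")
print(italian)
write_study_report(italian, "results/italian_subsample_study")

full_stats <- jsonlite::read_json("results/full_sample_study/stats.json")
cat("\nFull sample vs Italian subsample, mean d(true, predicted):\n")
for (cn in names(full_stats$cases)) {
  it <- italian$case_tests[italian$case_tests$case_name == cn, ]
  cat(sprintf("  %s: full %.4f  italian %.4f\n", cn,
              full_stats$cases[[cn]]$mean_d_true_pred, it$mean_d_true_pred))
}
cat("wrote results/italian_subsample_study/\n")
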