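#!/usr/bin/env Rscript
# Step 3 — cross-site evaluation and report.
#
# Loads the fitted arms from step 2, prints the internal/external cross-site
# comparison, and writes the full evaluation report (records, per-vertebra
# errors, per-angle boxplot statistics, PCP curves, figures) under
# results/evaluation/.

suppressPackageStartupMessages(library(fedspine))

st <- readRDS("results/arms/study.rds")
out <- "results/evaluation"
report(st$records, out, figures = requireNamespace("ggplot2", quietly = TRUE))

m <- st$metrics
cat("pooled angle MAE (degrees):\n")
cat(sprintf("  centralized     %.2f\n", m$centralized_angle_mae))
cat(sprintf("  fedavg          %.2f\n", m$fedavg_angle_mae))
cat(sprintf("  local internal  %.2f\n", m$local_internal_angle_mae))
cat(sprintf("  local external  %.2f\n", m$local_external_angle_mae))
cat(sprintf("fedavg / centralized ratio: %.2f\n", m$fedavg_vs_centralized_ratio))
cat(sprintf("landmark error (mm): centralized %.2f, fedavg %.2f, local external %.2f\n",
            m$centralized_landmark_err_mm, m$fedavg_landmark_err_mm,
            m$local_external_landmark_err_mm))
cat("\ncross-site records:\n")
print(records_to_df(st$records), digits = 3)
cat("\nreport written to ", out, "\n")
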