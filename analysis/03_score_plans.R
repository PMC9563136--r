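#!/usr/bin/env Rscript
# Step 3 -- PQM scoring.
#
# Scores every plan of the evaluated cohort with the nine-metric PQM table
# (PTV D2 / HI / CI, bladder D15 / D50, femoral head D25 / D40 per side;
# 0-10 points each, plan total in [0, 90]) and summarises the per-metric
# scores and totals per strategy, the score-table view of the hybrid vs
# script comparison.
#
# Input:   results/metric_table.csv   (step 2)
# Outputs: results/pqm_scores.csv, results/pqm_summary.csv

suppressPackageStartupMessages(library(planqc))
if (!file.exists("results/metric_table.csv"))
  stop("run analysis/02_evaluate_plans.R first")

metrics <- read.csv("results/metric_table.csv")
pqm <- score_cohort(metrics)
write.csv(pqm, "results/pqm_scores.csv", row.names = FALSE)

summary <- cohort_summary(pqm)
write.csv(summary, "results/pqm_summary.csv", row.names = FALSE)

totals <- summary[summary$metric == "PQM_total", ]
totals <- totals[order(-totals$mean), ]
cat("Total PQM score per strategy (mean +/- sd):\n")
for (i in seq_len(nrow(totals)))
  cat(sprintf("  %-16s %6.2f +/- %5.2f\n", totals$strategy_label[i],
              totals$mean[i], totals$sd[i]))
for (s in c("easy", "moderate", "hard")) {
  h <- totals$mean[totals$strategy_label == paste0("hybrid_", s)]
  p <- totals$mean[totals$strategy_label == paste0("script_", s)]
  cat(sprintf("%-8s setting: hybrid %5.2f vs script %5.2f (%s)\n", s, h, p,
              ifelse(h > p, "hybrid higher", "script higher")))
}
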