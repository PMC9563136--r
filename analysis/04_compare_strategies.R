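#!/usr/bin/env Rscript
# Step 4 -- Statistical comparison and robustness.
#
# Paired comparison (Shapiro-Wilk-guided paired t / Wilcoxon signed-rank,
# two-sided, alpha = 0.05) of hybrid vs script planning per goal setting,
# over every dose metric and the PQM total, plus the robustness spread
# (max - min of the setting means) of each metric for each method.
#
# Inputs:  results/metric_table.csv, results/pqm_scores.csv (steps 2-3)
# Outputs: results/paired_tests.csv, results/robustness.csv

suppressPackageStartupMessages(library(planqc))
for (f in c("results/metric_table.csv", "results/pqm_scores.csv"))
  if (!file.exists(f)) stop("run analysis steps 2 and 3 first (missing ", f, ")")

metrics <- read.csv("results/metric_table.csv")
pqm <- read.csv("results/pqm_scores.csv")

tests <- list()
for (s in c("easy", "moderate", "hard")) {
  tests[[paste0("m", s)]] <-
    compare_strategies(metrics, paste0("script_", s), paste0("hybrid_", s))
  tests[[paste0("p", s)]] <-
    compare_strategies(pqm, paste0("script_", s), paste0("hybrid_", s),
                       columns = "PQM_total")
}
# hybrid vs the clinically accepted manual plan, moderate setting
tests$manual <- compare_strategies(metrics, "manual", "hybrid_moderate")
paired <- do.call(rbind, tests)
write.csv(paired, "results/paired_tests.csv", row.names = FALSE)

rob <- robustness_spread(cohort_summary(metrics))
write.csv(rob, "results/robustness.csv", row.names = FALSE)

pt <- paired[paired$metric == "PQM_total", ]
cat("PQM total, hybrid vs script (positive difference favours hybrid):\n")
for (i in seq_len(nrow(pt)))
  cat(sprintf("  %-34s diff %+6.2f  p = %.2g (%s)\n", pt$pair[i],
              pt$mean_difference[i], pt$p_value[i], pt$test_used[i]))
ci <- rob[rob$metric == "CI", ]
cat(sprintf("\nCI across goal settings: hybrid spread %.4f vs script spread %.4f -> %s more robust\n",
            ci$spread[ci$method == "hybrid"], ci$spread[ci$method == "script"],
            ifelse(ci$spread[ci$method == "hybrid"] <
                     ci$spread[ci$method == "script"], "hybrid", "script")))
fem <- rob[rob$metric == "femur_head_L_D40", ]
cat(sprintf("Left femur D40 spread: hybrid %.0f cGy vs script %.0f cGy\n",
            fem$spread[fem$method == "hybrid"],
            fem$spread[fem$method == "script"]))
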