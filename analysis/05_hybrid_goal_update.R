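#!/usr/bin/env Rscript
# Step 5 -- The hybrid goal-update workflow on one patient.
#
# Walks the goal machinery end to end: preset clinical goals at each level,
# the predicted achievable dose from the knowledge-based surrogate, the
# unconditional replacement of OAR goal limits by predicted indices
# (targets kept), the auxiliary conformity-ring goals (max 4200 cGy on body
# minus PTV+5mm, 3000 cGy on body minus PTV+15mm) and the five additional
# OAR goals, all evaluated against the simulated hybrid_moderate plan.
# Patient 1 of the default cohort is used; with seed 1 it is a high-overlap
# case, where the update loosens the unachievable bladder goal.
#
# Output: results/goal_update_example.csv

suppressPackageStartupMessages(library(planqc))
dir.create("results", showWarnings = FALSE)

master_seed <- 1
pseed <- planqc:::mix_seed(master_seed, 1)
ph <- generate_phantom(c(80, 80, 80), 2.5, seed = pseed)
cat(sprintf("Patient P001: bladder-PTV overlap %.2f\n",
            sum(ph$masks$bladder & ph$masks$PTV) / sum(ph$masks$bladder)))

pred <- predict_dose(ph)
rg <- ring_goals(ph)
structures <- rg$structures     # phantom + ring_5mm / ring_15mm

rows <- list()
for (level in c("easy", "moderate", "hard")) {
  goals <- preset_goals(level)
  updated <- update_goals(goals, pred, structures)
  before <- goals_as_data_frame(goals)
  after <- goals_as_data_frame(updated)
  cat(sprintf("\n%s goals after prediction-driven update:\n", level))
  for (i in seq_len(nrow(before)))
    if (before$limit[i] != after$limit[i])
      cat(sprintf("  %-14s %-10s %7.0f -> %7.0f cGy (%s)\n",
                  before$structure[i], before$kind[i], before$limit[i],
                  after$limit[i],
                  ifelse(after$limit[i] > before$limit[i],
                         "loosened", "tightened")))
  final <- add_goals(add_goals(updated, rg$goals), additional_goals())
  hyb_idx <- match("hybrid_moderate", names(strategy_presets()))
  dose <- simulate_dose(structures, strategy_presets()$hybrid_moderate, 5000,
                        seed = planqc:::mix_seed(pseed, hyb_idx))
  pl <- plan(dose, structures, 5000, strategy_label = "hybrid_moderate",
             patient_id = "P001")
  rep <- evaluate_goals(pl, final)
  rep$level <- level
  # signed margin: how far the achieved value sits from the goal, in % of
  # the goal (negative = inside the goal). Updated OAR goals are pinned to
  # the predicted achievable value, so simulated plans land within a few
  # percent of them by construction.
  rep$margin_pct <- 100 * (rep$achieved - rep$limit) / rep$limit
  rows[[level]] <- rep
}
report <- do.call(rbind, rows)
write.csv(report, "results/goal_update_example.csv", row.names = FALSE)

mod <- rows$moderate
cat(sprintf("\nModerate setting: %d of %d goals pass on the hybrid plan\n",
            sum(mod$pass, na.rm = TRUE), sum(mod$evaluable)))
cat(sprintf("Goals within 5%% of their limit: %d of %d (personalised goals track the plan)\n",
            sum(abs(mod$margin_pct) <= 5, na.rm = TRUE), sum(mod$evaluable)))
print(mod[c("structure", "kind", "limit", "achieved", "margin_pct", "pass")],
      digits = 2, row.names = FALSE)
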