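# End-to-end cohort pipeline: simulate -> evaluate -> score.

#' Metric table for a simulated cohort
#'
#' Streams the cohort patient by patient (structures and doses are generated,
#' evaluated and discarded), so memory stays flat in the cohort size. Seeding
#' is identical to [generate_cohort()]: the same master seed gives
#' voxel-identical plans and therefore a byte-identical metric table.
#'
#' @inheritParams generate_cohort
#' @param reference_fraction CI reference isodose as a fraction of the
#'   prescription (see [metric_panel()]).
#' @return data.frame with one [metric_panel()] row per (patient, strategy).
#' @export
cohort_metrics <- function(n_patients, strategy_labels = STRATEGY_LABELS,
                           master_seed = 1, grid_shape = c(80, 80, 80),
                           spacing = 2.5, prescription = 5000,
                           reference_fraction = 0.95) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  bad <- setdiff(strategy_labels, STRATEGY_LABELS)
  if (length(bad))
    stop("unknown strategy label(s) ", paste(bad, collapse = ", "),
         "; valid labels: ", paste(STRATEGY_LABELS, collapse = ", "))
  presets <- strategy_presets()
  rows <- vector("list", n_patients * length(strategy_labels))
  k <- 0L
  for (p in seq_len(n_patients)) {
    pseed <- mix_seed(master_seed, p)
    structures <- generate_phantom(grid_shape, spacing, seed = pseed)
    for (s in seq_along(strategy_labels)) {
      lab <- strategy_labels[s]
      dose <- simulate_dose(structures, presets[[lab]], prescription,
                            seed = mix_seed(pseed, s))
      pl <- plan(dose, structures, prescription, strategy_label = lab,
                 patient_id = sprintf("P%03d", p))
      k <- k + 1L
      rows[[k]] <- metric_panel(pl, reference_fraction)
    }
  }
  do.call(rbind, rows)
}

#' Full strategy comparison on a simulated cohort
#'
#' Runs the whole analysis: simulate the cohort, compute the metric panel
#' per plan, score each plan with the nine-metric PQM table, compare hybrid
#' against script planning per goal setting (paired tests on the PQM total)
#' and measure the robustness spread of each metric across goal settings.
#'
#' @inheritParams cohort_metrics
#' @param alpha significance level for the paired tests.
#' @return list with `metrics` (per-plan panel), `pqm` (per-plan scores and
#'   totals), `summary` (per-strategy mean/sd of every metric),
#'   `pqm_summary` (per-strategy mean/sd of the PQM scores), `tests`
#'   (PQM-total paired tests, hybrid vs script per setting) and `robustness`
#'   (spread of each metric across goal settings per method).
#' @export
run_cohort_comparison <- function(n_patients = 20,
                                  master_seed = 1,
                                  grid_shape = c(80, 80, 80),
                                  spacing = 2.5, prescription = 5000,
                                  alpha = 0.05) {
  metrics <- cohort_metrics(n_patients, STRATEGY_LABELS, master_seed,
                            grid_shape, spacing, prescription)
  pqm <- score_cohort(metrics)
  tests <- do.call(rbind, lapply(c("easy", "moderate", "hard"), function(s) {
    compare_strategies(pqm, paste0("script_", s), paste0("hybrid_", s),
                       columns = "PQM_total", alpha = alpha)
  }))
  list(metrics = metrics,
       pqm = pqm,
       summary = cohort_summary(metrics),
       pqm_summary = cohort_summary(pqm),
       tests = tests,
       robustness = robustness_spread(cohort_summary(metrics)))
}
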