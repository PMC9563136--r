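# Piecewise-linear plan-quality-metric (PQM) scoring.

#' A single PQM scoring specification
#'
#' A metric scores `max_score` points at its favorable limit and `min_score`
#' at its unfavorable one, linearly in between and clamped outside. For
#' lower-is-better metrics the favorable end is `lower_limit`; the
#' conformity index is the one higher-is-better metric, favorable at
#' `upper_limit`.
#'
#' @param roi structure label (`"PTV"`, `"bladder"`, `"femur_head_L"`,
#'   `"femur_head_R"`, ...).
#' @param index metric name (`"D2"`, `"HI"`, `"CI"`, `"D15"`, `"D50"`,
#'   `"D25"`, `"D40"`).
#' @param lower_limit,upper_limit value window in metric units (cGy or
#'   dimensionless); `lower_limit < upper_limit`.
#' @param min_score,max_score points awarded at the unfavorable / favorable
#'   ends; `min_score < max_score`.
#' @param orientation `"lower"` (lower-is-better) or `"higher"`.
#' @return one-row data.frame (rows bind into a scoring table).
#' @export
pqm_spec <- function(roi, index, lower_limit, upper_limit,
                     min_score = 0, max_score = 10,
                     orientation = c("lower", "higher")) {
  orientation <- match.arg(orientation)
  if (!is.finite(lower_limit) || !is.finite(upper_limit) ||
      lower_limit >= upper_limit)
    stop("lower_limit must be strictly below upper_limit")
  if (min_score >= max_score)
    stop("min_score must be strictly below max_score")
  data.frame(roi = roi, index = index,
             lower_limit = lower_limit, upper_limit = upper_limit,
             min_score = min_score, max_score = max_score,
             orientation = orientation, stringsAsFactors = FALSE)
}

#' The default nine-metric PQM scoring table
#'
#' PTV D2 (5250-5500 cGy), HI (0-0.15) and CI (0.8-0.9, higher-is-better);
#' bladder D15 (4000-5250) and D50 (2500-4500); D25 (2000-3000) and D40
#' (1250-2500) for each femoral head. Every metric scores 0 to 10 points,
#' for a plan total in \[0, 90\].
#'
#' @return data.frame of nine [pqm_spec()] rows.
#' @export
pqm_table <- function() {
  rbind(
    pqm_spec("PTV", "D2", 5250, 5500),
    pqm_spec("PTV", "HI", 0, 0.15),
    pqm_spec("PTV", "CI", 0.8, 0.9, orientation = "higher"),
    pqm_spec("bladder", "D15", 4000, 5250),
    pqm_spec("bladder", "D50", 2500, 4500),
    pqm_spec("femur_head_L", "D25", 2000, 3000),
    pqm_spec("femur_head_L", "D40", 1250, 2500),
    pqm_spec("femur_head_R", "D25", 2000, 3000),
    pqm_spec("femur_head_R", "D40", 1250, 2500)
  )
}

#' Score one metric value
#'
#' Piecewise-linear interpolation over the spec's value window, clamped to
#' \[min_score, max_score\].
#'
#' @param value metric value in the spec's units; must be finite.
#' @param spec a one-row scoring table ([pqm_spec()]).
#' @return points.
#' @export
score_metric <- function(value, spec) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("cannot score a non-finite metric value")
  frac <- (value - spec$lower_limit) / (spec$upper_limit - spec$lower_limit)
  frac <- min(max(frac, 0), 1)
  if (spec$orientation == "lower") frac <- 1 - frac
  spec$min_score + frac * (spec$max_score - spec$min_score)
}

#' Score a plan's metric panel
#'
#' Applies [score_metric()] to each row of the scoring table, reading metric
#' values from a [metric_panel()] row. The total is the sum of the
#' per-metric scores (in \[0, 90\] for the default table). A missing (NA)
#' metric is listed as unscored and makes the total NA, with a warning, so
#' incomplete plans never enter cohort totals silently.
#'
#' @param metrics one-row data.frame from [metric_panel()] (or a named list
#'   with the same columns).
#' @param specs scoring table, default [pqm_table()].
#' @return a `pqm_report`: list with `scores` (data.frame roi, index, value,
#'   score), `total`, `patient_id`, `strategy_label`.
#' @export
score_plan <- function(metrics, specs = pqm_table()) {
  metrics <- as.list(metrics)
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    spec <- specs[i, ]
    col <- metric_column(spec$roi, spec$index)
    value <- metrics[[col]]
    if (is.null(value)) value <- NA_real_
    score <- if (is.na(value)) NA_real_ else score_metric(value, spec)
    data.frame(roi = spec$roi, index = spec$index, value = value,
               score = score, stringsAsFactors = FALSE)
  })
  scores <- do.call(rbind, rows)
  if (anyNA(scores$score)) {
    warning("unscored metric(s): ",
            paste(metric_column(scores$roi, scores$index)[is.na(scores$score)],
                  collapse = ", "),
            "; plan total is NA", call. = FALSE)
    total <- NA_real_
  } else {
    total <- sum(scores$score)
  }
  structure(list(scores = scores, total = total,
                 patient_id = metrics$patient_id %||% NA_character_,
                 strategy_label = metrics$strategy_label %||% NA_character_),
            class = "pqm_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pqm_report <- function(x, ...) {
  cat(sprintf("<pqm_report> %s / %s, total %.2f\n",
              x$patient_id, x$strategy_label, x$total))
  print(x$scores, digits = 4)
  invisible(x)
}

#' PQM scores for a cohort metric table
#'
#' @param metrics data.frame of [metric_panel()] rows (one per plan).
#' @param specs scoring table, default [pqm_table()].
#' @return data.frame: patient_id, strategy_label, one column per metric
#'   score (named `score_<roi>_<index>`), and `PQM_total`.
#' @export
score_cohort <- function(metrics, specs = pqm_table()) {
  rows <- lapply(seq_len(nrow(metrics)), function(i) {
    rep <- score_plan(metrics[i, ], specs)
    sc <- as.list(rep$scores$score)
    names(sc) <- paste0("score_", metric_column(rep$scores$roi,
                                                rep$scores$index))
    cbind(data.frame(patient_id = rep$patient_id,
                     strategy_label = rep$strategy_label,
                     stringsAsFactors = FALSE),
          as.data.frame(sc), PQM_total = rep$total)
  })
  do.call(rbind, rows)
}
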