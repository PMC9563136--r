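# Paired statistical protocol and robustness analysis.

#' Paired comparison of one metric between two strategies
#'
#' Reproduces the study protocol: a Shapiro-Wilk test on the paired
#' differences (at `normality_alpha`) chooses between a paired t-test
#' (normal differences) and a Wilcoxon signed-rank test; two-sided at level
#' `alpha`. Zero differences are dropped on the Wilcoxon path; the exact
#' null distribution is used for n <= 25 without ties, the normal
#' approximation with continuity correction otherwise. All-zero differences
#' are degenerate: p = 1, not significant. Constant non-zero differences
#' (Shapiro-Wilk and the t-test are both undefined) take the Wilcoxon path.
#'
#' @param values_a,values_b per-patient metric values, paired by position,
#'   equal lengths >= 5.
#' @param alpha significance level (default 0.05).
#' @param normality_alpha Shapiro-Wilk level for the test choice.
#' @param test `"auto"` (Shapiro-Wilk choice), `"t"` or `"wilcoxon"`.
#' @param metric,pair optional labels carried into the result.
#' @return a `paired_test_result`: list with `metric`, `pair`, `test_used`
#'   (`"paired-t"`, `"wilcoxon-signed-rank"` or `"degenerate"`),
#'   `statistic`, `p_value`, `significant`, `mean_difference` (b - a), `n`.
#' @export
paired_compare <- function(values_a, values_b, alpha = 0.05,
                           normality_alpha = 0.05,
                           test = c("auto", "t", "wilcoxon"),
                           metric = NA_character_, pair = NA_character_) {
  test <- match.arg(test)
  if (length(values_a) != length(values_b))
    stop("paired samples must have equal length")
  if (length(values_a) < 5)
    stop("paired comparison requires at least 5 pairs")
  if (anyNA(values_a) || anyNA(values_b))
    stop("paired samples must not contain NA")
  d <- values_b - values_a
  res <- function(test_used, statistic, p_value) {
    structure(list(metric = metric, pair = pair, test_used = test_used,
                   statistic = unname(statistic), p_value = p_value,
                   significant = p_value < alpha,
                   mean_difference = mean(d), n = length(d)),
              class = "paired_test_result")
  }
  if (all(d == 0)) return(res("degenerate", NA_real_, 1))

  if (test == "auto") {
    test <- if (sd(d) == 0) "wilcoxon"
            else if (shapiro.test(d)$p.value >= normality_alpha) "t"
            else "wilcoxon"
  }
  if (test == "t") {
    ht <- t.test(values_b, values_a, paired = TRUE)
    return(res("paired-t", ht$statistic, ht$p.value))
  }
  dz <- d[d != 0]  # zero differences dropped
  exact <- length(dz) <= 25 && !anyDuplicated(abs(dz))
  ht <- suppressWarnings(
    wilcox.test(dz, exact = exact, correct = TRUE))
  res("wilcoxon-signed-rank", ht$statistic, ht$p.value)
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("<paired_test> %s %s: %s, stat %.4g, p = %.4g%s (n = %d)\n",
              ifelse(is.na(x$metric), "", x$metric),
              ifelse(is.na(x$pair), "", x$pair),
              x$test_used, x$statistic, x$p_value,
              ifelse(x$significant, " *", ""), x$n))
  invisible(x)
}

#' Per-strategy mean and standard deviation of each metric
#'
#' @param metrics data.frame with `patient_id`, `strategy_label` and one
#'   numeric column per metric ([metric_panel()] or [score_cohort()] rows);
#'   at least 2 patients. Patients with NA values for a metric are excluded
#'   from that metric's summary with a warning.
#' @param columns metric columns to summarise (default: all numeric columns
#'   except `prescription`).
#' @return data.frame: metric, strategy_label, mean, sd, n.
#' @export
cohort_summary <- function(metrics, columns = NULL) {
  if (length(unique(metrics$patient_id)) < 2)
    stop("cohort summary requires at least 2 patients")
  if (is.null(columns)) {
    num <- vapply(metrics, is.numeric, logical(1))
    columns <- setdiff(names(metrics)[num], "prescription")
  }
  rows <- list()
  for (col in columns) {
    if (anyNA(metrics[[col]]))
      warning("metric '", col, "': plans with NA excluded from the summary",
              call. = FALSE)
    for (s in unique(metrics$strategy_label)) {
      v <- metrics[[col]][metrics$strategy_label == s]
      v <- v[!is.na(v)]
      rows[[length(rows) + 1L]] <-
        data.frame(metric = col, strategy_label = s,
                   mean = mean(v), sd = sd(v), n = length(v),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Robustness of each planning method across goal settings
#'
#' For every metric and method (script, hybrid), collects the cohort mean at
#' the easy, moderate and hard settings and the spread `max - min` across
#' them; the method with the smaller spread is the more robust one for that
#' metric.
#'
#' @param summary output of [cohort_summary()] covering the six
#'   `script_*` / `hybrid_*` strategies. Metrics missing a setting are
#'   excluded with a warning.
#' @return data.frame: metric, method, mean_easy, mean_moderate, mean_hard,
#'   spread, more_robust (logical: smallest spread among the methods for the
#'   metric).
#' @export
robustness_spread <- function(summary) {
  settings <- c("easy", "moderate", "hard")
  rows <- list()
  for (m in unique(summary$metric)) {
    for (method in c("hybrid", "script")) {
      means <- vapply(settings, function(s) {
        v <- summary$mean[summary$metric == m &
                          summary$strategy_label == paste(method, s, sep = "_")]
        if (length(v) == 1L) v else NA_real_
      }, numeric(1))
      if (anyNA(means)) {
        warning("metric '", m, "': method '", method,
                "' is missing a goal setting and is excluded", call. = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <-
        data.frame(metric = m, method = method,
                   mean_easy = means[["easy"]],
                   mean_moderate = means[["moderate"]],
                   mean_hard = means[["hard"]],
                   spread = max(means) - min(means),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$more_robust <- ave(out$spread, out$metric,
                         FUN = function(s) s == min(s)) > 0
  out
}

#' Paired tests for a set of metrics between two strategies
#'
#' Convenience wrapper running [paired_compare()] per metric column for one
#' strategy pair, pairing plans by patient.
#'
#' @param metrics cohort metric table ([metric_panel()] or [score_cohort()]
#'   rows).
#' @param strategy_a,strategy_b the two strategy labels to compare.
#' @param columns metric columns (default: all numeric except prescription).
#' @param ... passed to [paired_compare()].
#' @return data.frame: metric, pair, test_used, statistic, p_value,
#'   significant, mean_difference (b - a), n.
#' @export
compare_strategies <- function(metrics, strategy_a, strategy_b,
                               columns = NULL, ...) {
  if (is.null(columns)) {
    num <- vapply(metrics, is.numeric, logical(1))
    columns <- setdiff(names(metrics)[num], "prescription")
  }
  a <- metrics[metrics$strategy_label == strategy_a, ]
  b <- metrics[metrics$strategy_label == strategy_b, ]
  a <- a[order(a$patient_id), ]
  b <- b[order(b$patient_id), ]
  if (!identical(a$patient_id, b$patient_id))
    stop("strategies '", strategy_a, "' and '", strategy_b,
         "' do not cover the same patients")
  pair <- paste(strategy_b, "vs", strategy_a)
  rows <- lapply(columns, function(col) {
    r <- paired_compare(a[[col]], b[[col]], metric = col, pair = pair, ...)
    data.frame(metric = col, pair = pair, test_used = r$test_used,
               statistic = r$statistic, p_value = r$p_value,
               significant = r$significant,
               mean_difference = r$mean_difference, n = r$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
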