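# Full meta-evaluation report: every metric against every requested
# human-score component, with all three correlations, their intervals,
# and the paired Wilcoxon test.

component_column <- function(component) {
  switch(component,
    D = "D",
    plausibility = "p_bar",
    specificity = "s_bar",
    omission = "o_bar",
    stop("unknown component '", component,
         "'; use D, plausibility, specificity or omission")
  )
}

#' Correlate automated metrics with human evaluation scores
#'
#' Joins a scored-record table with a metric-score table on record
#' identity and computes, for every metric and requested component, the
#' Spearman, Pearson and Kendall tau-b correlations (with intervals and
#' p-values) and the Wilcoxon signed-rank p-value for the paired
#' difference.  Components other than `D` are the 0--5 component means;
#' for the Wilcoxon pairing they are divided by the scale maximum and the
#' metric is min-max rescaled to `[0, 1]` (rank correlations are invariant
#' to both).
#'
#' @param scores Scores tibble (the `$scores` element of [score_cohort()],
#'   with `record_id`, `D`, `p_bar`, `s_bar`, `o_bar`).
#' @param metric_scores Metric tibble from [run_metric_suite()]
#'   (`pair_id` must match `record_id`).
#' @param components Subset of `c("D", "plausibility", "specificity",
#'   "omission")`.
#' @param ci_method Interval method for the rank correlations
#'   (`"bootstrap"`, `"fisher"` or `"none"`).
#' @param n_boot Bootstrap resamples per interval.
#' @param seed Base seed; each report row derives its own sub-seed so the
#'   report is reproducible as a whole.
#' @param rescale_wilcoxon Min-max rescale metric values before the paired
#'   test (recommended: log-probability metrics are unbounded).
#' @param max_join_loss Error if more than this fraction of scored records
#'   finds no metric value for some metric.
#' @param p_adjust Multiple-testing adjustment applied per component
#'   across metrics (`"none"` or any [stats::p.adjust()] method).
#' @return Tibble with one row per (metric, component).
#' @export
correlation_table <- function(scores, metric_scores,
                              components = c("D", "plausibility",
                                             "specificity", "omission"),
                              ci_method = "bootstrap", n_boot = 2000,
                              seed = 1, rescale_wilcoxon = TRUE,
                              max_join_loss = 0.1, p_adjust = "none") {
  stopifnot(all(c("record_id", "D") %in% names(scores)),
            all(c("pair_id", "metric_name", "value") %in% names(metric_scores)))
  rows <- list()
  row_i <- 0L
  for (metric in unique(metric_scores$metric_name)) {
    msub <- metric_scores[metric_scores$metric_name == metric, , drop = FALSE]
    merged <- merge(as.data.frame(scores), as.data.frame(msub),
                    by.x = "record_id", by.y = "pair_id")
    merged <- merged[order(merged$record_id), , drop = FALSE]
    lost <- 1 - nrow(merged) / nrow(scores)
    if (lost > max_join_loss) {
      stop("metric '", metric, "': ", round(100 * lost, 1),
           "% of scored records lost in the join (limit ",
           round(100 * max_join_loss, 1), "%)")
    }
    for (component in components) {
      row_i <- row_i + 1L
      col <- component_column(component)
      h <- merged[[col]]
      m <- merged$value
      keep <- !is.na(h) & !is.na(m)
      h <- h[keep]
      m <- m[keep]
      sub_seed <- (seed + 7919 * row_i) %% 2147483647
      sp <- spearman_rho(h, m, ci_method = ci_method, n_boot = n_boot,
                         seed = sub_seed)
      pe <- pearson_r(h, m)
      kd <- kendall_tau_b(h, m, ci_method = ci_method, n_boot = n_boot,
                          seed = sub_seed + 1)
      h_unit <- if (component == "D") h else h / 5
      wx <- wilcoxon_signed_rank(h_unit, m, rescale = rescale_wilcoxon)
      rows[[row_i]] <- tibble::tibble(
        metric_name = metric, component = component, n = length(h),
        spearman = sp$estimate, spearman_lo = sp$ci_lower,
        spearman_hi = sp$ci_upper, spearman_p = sp$p_value,
        pearson = pe$estimate, pearson_lo = pe$ci_lower,
        pearson_hi = pe$ci_upper, pearson_p = pe$p_value,
        kendall = kd$estimate, kendall_lo = kd$ci_lower,
        kendall_hi = kd$ci_upper, kendall_p = kd$p_value,
        wilcoxon_statistic = wx$statistic, wilcoxon_p = wx$p_value,
        ci_method = ci_method,
        backend_id = msub$backend_id[1]
      )
    }
  }
  out <- do.call(rbind, rows)
  if (p_adjust != "none") {
    for (component in components) {
      sel <- out$component == component
      for (colp in c("spearman_p", "pearson_p", "kendall_p", "wilcoxon_p")) {
        out[[colp]][sel] <- stats::p.adjust(out[[colp]][sel], method = p_adjust)
      }
    }
  }
  out
}

#' Write a correlation report to CSV and optionally JSON
#'
#' @param report Tibble from [correlation_table()].
#' @param csv_path Output CSV path.
#' @param json_path Optional output JSON path.
#' @return `csv_path`, invisibly.
#' @export
write_correlation_report <- function(report, csv_path, json_path = NULL) {
  utils::write.csv(as.data.frame(report), csv_path, row.names = FALSE, na = "")
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(csv_path)
}
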