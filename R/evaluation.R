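#' Compute count-regression metrics
#'
#' R-squared here is the coefficient of determination
#' `1 - SS_res / SS_tot` (residual sum of squares against the label-mean
#' baseline), not a squared correlation: a biased predictor is penalised.
#' Totals accounting reports the predicted total as a percentage of the
#' annotated total, the quantity survey programmes care about.
#'
#' @param labels nonnegative integer counts.
#' @param predictions real-valued predicted counts, same length.
#' @param round_predictions round to the nearest integer and clamp at 0
#'   before computing metrics (reporting sensitivity option).
#' @return an object of class `metric_report` with fields `r_squared`,
#'   `rmse`, `mae`, `n`, `sum_labels`, `sum_predictions`, `totals_percent`.
#'   `r_squared` is `NA` when the labels have zero variance, and
#'   `totals_percent` is `NA` when the labels sum to zero.
#' @export
compute_metrics <- function(labels, predictions, round_predictions = FALSE) {
  assert_that(length(labels) >= 1, "`labels` must be nonempty")
  assert_that(length(labels) == length(predictions),
              "`labels` and `predictions` must have equal length")
  assert_that(all(labels >= 0), "`labels` must be nonnegative counts")
  if (round_predictions) predictions <- pmax(0, round(predictions))
  res <- predictions - labels
  ss_res <- sum(res^2)
  ss_tot <- sum((labels - mean(labels))^2)
  structure(list(
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    rmse = sqrt(mean(res^2)),
    mae = mean(abs(res)),
    n = length(labels),
    sum_labels = sum(labels),
    sum_predictions = sum(predictions),
    totals_percent = if (sum(labels) > 0) 100 * sum(predictions) / sum(labels)
    else NA_real_),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> n=%d  R2=%s  RMSE=%.2f  MAE=%.2f  totals %.0f/%.0f (%s%%)\n",
              x$n,
              if (is.na(x$r_squared)) "NA" else sprintf("%.2f", x$r_squared),
              x$rmse, x$mae, x$sum_predictions, x$sum_labels,
              if (is.na(x$totals_percent)) "NA" else sprintf("%.1f", x$totals_percent)))
  invisible(x)
}

#' Percentage undercount of the predicted totals
#'
#' @param report a [compute_metrics()] report with a positive label total.
#' @return `100 * (sum_labels - sum_predictions) / sum_labels`; positive when
#'   the model under-counts in total.
#' @export
totals_underestimate <- function(report) {
  assert_that(inherits(report, "metric_report"), "`report` must be a metric_report")
  if (report$sum_labels <= 0)
    stop("totals underestimate is undefined for a zero label total", call. = FALSE)
  100 * (report$sum_labels - report$sum_predictions) / report$sum_labels
}

#' Export label-vs-prediction scatter data
#'
#' Writes a CSV with columns `label`, `prediction` and `reference` (the
#' `y = x` optimum at each label) for plotting predicted against annotated
#' counts. The pairs round-trip losslessly through [utils::read.csv()].
#'
#' @param labels,predictions as in [compute_metrics()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_scatter <- function(labels, predictions, path) {
  assert_that(length(labels) >= 1 && length(labels) == length(predictions),
              "`labels` and `predictions` must be nonempty and of equal length")
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop(sprintf("cannot write scatter data: directory '%s' does not exist", dir),
         call. = FALSE)
  utils::write.csv(data.frame(label = labels, prediction = predictions,
                              reference = labels),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a metric report as YAML and CSV
#'
#' @param report a [compute_metrics()] report.
#' @param stem file stem; `<stem>.yaml` and `<stem>.csv` are written.
#' @return `stem`, invisibly.
#' @export
write_metric_report <- function(report, stem) {
  vals <- unclass(report)
  yaml::write_yaml(vals, paste0(stem, ".yaml"))
  utils::write.csv(as.data.frame(vals), paste0(stem, ".csv"), row.names = FALSE)
  invisible(stem)
}

#' Per-bin RMSE of predictions
#'
#' @param labels,predictions as in [compute_metrics()].
#' @param bins integer bin index per item (e.g. from [assign_bins()]).
#' @return data frame with `bin`, `n`, `rmse`.
#' @export
binned_rmse <- function(labels, predictions, bins) {
  res2 <- (predictions - labels)^2
  agg <- tapply(res2, bins, mean)
  data.frame(bin = as.integer(names(agg)),
             n = as.integer(table(bins)),
             rmse = sqrt(as.numeric(agg)))
}
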