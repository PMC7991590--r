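## Confusion-matrix evaluation, accessibility correlations and
## cross-dataset summaries. Each residue class is evaluated one-vs-rest
## against the three-class truth labels.

#' Confusion counts for one class, one-vs-rest
#'
#' Counts are taken over the intersection of predicted and labelled
#' positions; labelled positions without a prediction (e.g. dropped by
#' the minimum-mutant filter) are excluded and reported via `message()`.
#' For the buried framing, positions on the truth's exclusion list are
#' omitted entirely, mirroring their exclusion from the buried call.
#'
#' @param pred A `prediction_table` (see [assign_classes]).
#' @param truth A [residue_truth].
#' @param positive_class One of `"active_site"`, `"buried"`,
#'   `"exposed_nonactive"`.
#' @return An object of class `confusion_counts`: list with `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion <- function(pred, truth, positive_class = TRUTH_CLASSES) {
  positive_class <- match.arg(positive_class)
  common <- intersect(pred$position, truth$position)
  missing <- setdiff(truth$position, pred$position)
  if (length(missing) > 0L) {
    message(sprintf("confusion: %d labelled position(s) without a prediction excluded: %s",
                    length(missing), paste(utils::head(missing, 20), collapse = ", ")))
  }
  if (positive_class == "buried") {
    common <- setdiff(common, truth_exclusions(truth))
  }
  if (length(common) == 0L) {
    stop_validation("confusion: no position has both a prediction and a truth label")
  }
  p <- pred$predicted_class[match(common, pred$position)] == positive_class
  t <- truth$true_class[match(common, truth$position)] == positive_class
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t)),
            class = "confusion_counts")
}

#' Confusion counts from raw counts
#' @param tp,fp,tn,fn Non-negative integers.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop_validation("confusion_counts: counts must be non-negative integers")
  }
  structure(as.list(counts), class = "confusion_counts")
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
#' `accuracy = (TP+TN)/total`,
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Any zero factor in the MCC denominator yields `mcc = 0` (the standard
#' convention, keeping the report total); a zero denominator in
#' sensitivity or specificity yields `NA`.
#'
#' @param c A `confusion_counts` object.
#' @return Named list with `sensitivity`, `specificity`, `accuracy`,
#'   `mcc`, `n`.
#' @export
class_metrics <- function(c) {
  tp <- c$tp; fp <- c$fp; tn <- c$tn; fn <- c$fn
  n <- tp + fp + tn + fn
  if (n == 0) stop_validation("class_metrics: empty confusion matrix")
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  list(sensitivity = rate(tp, tp + fn),
       specificity = rate(tn, tn + fp),
       accuracy = (tp + tn) / n,
       mcc = if (denom == 0) 0 else (tp * tn - fp * fn) / denom,
       n = n)
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper used for comparing predicted with
#' structure-calculated accessibility.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop_validation("pearson: need equal-length vectors of length >= 3")
  }
  if (pop_sd(x) == 0 || pop_sd(y) == 0) {
    stop_degenerate("pearson: correlation undefined for constant input")
  }
  stats::cor(x, y, method = "pearson")
}

#' Unweighted cross-dataset column means
#'
#' Aggregates per-dataset metric values into a summary row: the
#' arithmetic mean of each numeric column, each dataset weighted equally
#' regardless of its residue count. Rounding happens only at presentation
#' time.
#'
#' @param rows A `data.frame` with one row per dataset; non-numeric
#'   columns (e.g. the dataset name) are ignored.
#' @return Named numeric vector of column means.
#' @export
summarize_datasets <- function(rows) {
  if (is.null(rows) || nrow(rows) == 0L) {
    stop_validation("summarize_datasets: need >= 1 row")
  }
  num <- vapply(rows, is.numeric, logical(1))
  vapply(rows[num], mean, numeric(1))
}

#' Evaluate predictions against truth labels for all three classes
#'
#' @param pred A `prediction_table`.
#' @param truth A [residue_truth].
#' @param dataset_id Label for the report rows.
#' @return A `data.frame` of class `metrics_report`: one row per class
#'   with columns `dataset`, `class`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `accuracy`, `mcc`, `n`.
#' @export
evaluate_predictions <- function(pred, truth, dataset_id = NA_character_) {
  rows <- lapply(TRUTH_CLASSES, function(cl) {
    cc <- confusion(pred, truth, cl)
    m <- class_metrics(cc)
    data.frame(dataset = dataset_id, class = cl,
               tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
               sensitivity = m$sensitivity, specificity = m$specificity,
               accuracy = m$accuracy, mcc = m$mcc, n = m$n,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("metrics_report", "data.frame"))
}

#' Write a metrics report in the conventional benchmark layout
#'
#' One row per (dataset, class): percentages to 1 decimal, MCC to 2
#' decimals, plus an unweighted `MEAN` summary row per class when more
#' than one dataset is present.
#'
#' @param report A `metrics_report` (rows from one or more datasets).
#' @param path Output TSV path.
#' @export
write_metrics_report <- function(report, path) {
  fmt <- report[, c("dataset", "class")]
  fmt$sensitivity_pct <- sprintf("%.1f", 100 * report$sensitivity)
  fmt$specificity_pct <- sprintf("%.1f", 100 * report$specificity)
  fmt$accuracy_pct <- sprintf("%.1f", 100 * report$accuracy)
  fmt$mcc <- sprintf("%.2f", report$mcc)
  if (length(unique(report$dataset)) > 1L) {
    for (cl in unique(report$class)) {
      sub <- report[report$class == cl, ]
      m <- summarize_datasets(sub[, c("sensitivity", "specificity", "accuracy", "mcc")])
      fmt <- rbind(fmt, data.frame(
        dataset = "MEAN", class = cl,
        sensitivity_pct = sprintf("%.1f", 100 * m[["sensitivity"]]),
        specificity_pct = sprintf("%.1f", 100 * m[["specificity"]]),
        accuracy_pct = sprintf("%.1f", 100 * m[["accuracy"]]),
        mcc = sprintf("%.2f", m[["mcc"]]), stringsAsFactors = FALSE))
    }
  }
  utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Published benchmark summaries bundled with the package
#'
#' Transcriptions of the published per-dataset benchmark tables from the
#' study of twelve deep mutational scanning datasets that this method
#' implements: accessibility-predictor correlations against
#' structure-calculated accessibility, and the per-dataset
#' sensitivity/specificity/accuracy/MCC of the three residue-class
#' predictions. Used to verify that [summarize_datasets] reproduces the
#' published cross-dataset means.
#'
#' @param which One of `"accessibility_correlations"`, `"active_site"`,
#'   `"buried"`, `"exposed_nonactive"`.
#' @return A `data.frame`, one row per published dataset.
#' @export
published_benchmarks <- function(which = c("accessibility_correlations",
                                           "active_site", "buried",
                                           "exposed_nonactive")) {
  which <- match.arg(which)
  file <- system.file("extdata",
                      paste0("published_", which, ".tsv"),
                      package = "dmsites", mustWork = TRUE)
  utils::read.table(file, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
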