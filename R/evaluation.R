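#' One-vs-rest confusion counts for multi-class predictions
#'
#' For each class k, a sample counts as TP if label and prediction are both
#' k, FP if predicted k but labeled otherwise, FN if labeled k but predicted
#' otherwise, and TN else. Per class, tp + fp + fn + tn equals the sample
#' count, and the TPs summed over classes equal the number of correct
#' predictions.
#'
#' @param labels,preds Integer vectors of 0-based class indices, equal
#'   length.
#' @param C Number of classes.
#' @return A data frame of class `"confusion_counts"` with one row per
#'   class and columns `class`, `tp`, `fp`, `fn`, `tn`, plus attribute `n`
#'   (total samples).
#' @export
confusion_from_predictions <- function(labels, preds, C) {
  if (length(labels) != length(preds))
    stop_invalid("labels and preds must have equal length")
  if (any(labels < 0L | labels >= C) || any(preds < 0L | preds >= C))
    stop_invalid("labels/preds must lie in [0, C)")
  n <- length(labels)
  out <- data.frame(class = 0:(C - 1L), tp = 0L, fp = 0L, fn = 0L, tn = 0L)
  for (k in 0:(C - 1L)) {
    tp <- sum(labels == k & preds == k)
    fp <- sum(labels != k & preds == k)
    fn <- sum(labels == k & preds != k)
    out[k + 1L, c("tp", "fp", "fn", "tn")] <-
      c(tp, fp, fn, n - tp - fp - fn)
  }
  attr(out, "n") <- n
  class(out) <- c("confusion_counts", "data.frame")
  out
}

#' Accuracy, precision, recall, and F1 from confusion counts
#'
#' Accuracy is the fraction of correct predictions. Precision
#' (`tp / (tp + fp)`), recall (`tp / (tp + fn)`), and
#' `F1 = 2 P R / (P + R)` are computed per class and macro-averaged
#' (unweighted class mean), which treats every species equally in the
#' roughly class-balanced settings this package targets. A class whose
#' denominator is empty gets the value 0 and is flagged in the per-class
#' table rather than producing NaN.
#'
#' @param counts A `"confusion_counts"` data frame.
#' @return A list of class `"metrics_report"` with scalar `accuracy`,
#'   `precision`, `recall`, `f1` (macro), and `per_class`, a data frame with
#'   per-class values and a `zero_denominator` flag.
#' @export
metrics_report <- function(counts) {
  n <- attr(counts, "n")
  safe_div <- function(num, den) ifelse(den > 0, num / pmax(den, 1), 0)
  prec <- safe_div(counts$tp, counts$tp + counts$fp)
  rec <- safe_div(counts$tp, counts$tp + counts$fn)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  per_class <- data.frame(
    class = counts$class, precision = prec, recall = rec, f1 = f1,
    zero_denominator = (counts$tp + counts$fp == 0L) | (counts$tp + counts$fn == 0L))
  structure(list(accuracy = sum(counts$tp) / n,
                 precision = mean(prec), recall = mean(rec), f1 = mean(f1),
                 per_class = per_class),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f (macro, %d classes)\n",
              x$accuracy, x$precision, x$recall, x$f1, nrow(x$per_class)))
  invisible(x)
}

#' Write a metrics report as JSON or CSV
#'
#' The CSV has the per-class rows followed by a macro summary row with
#' class `"macro"`; the JSON mirrors the report structure.
#'
#' @param report A `"metrics_report"`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_metrics_json <- function(report, file) {
  jsonlite::write_json(
    list(accuracy = report$accuracy, precision = report$precision,
         recall = report$recall, f1 = report$f1,
         per_class = report$per_class),
    file, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(file)
}

#' @rdname write_metrics_json
#' @export
write_metrics_csv <- function(report, file) {
  pc <- report$per_class
  pc$class <- as.character(pc$class)
  summary_row <- data.frame(class = "macro", precision = report$precision,
                            recall = report$recall, f1 = report$f1,
                            zero_denominator = FALSE)
  write.csv(rbind(pc, summary_row), file, row.names = FALSE)
  invisible(file)
}
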