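## Confusion matrices and multiclass metrics (one-vs-all precision, recall,
## F1) with macro and support-weighted aggregation.

#' Confusion matrix over a fixed label vocabulary
#'
#' Rows are the true class, columns the predicted class, so per-class recall
#' (the true positive rate) can be read off the diagonal of the
#' row-normalized matrix.
#'
#' @param y_true,y_pred label vectors of equal length.
#' @param class_labels ordered vocabulary; both label vectors must draw from
#'   it. Defaults to the sorted union of observed labels.
#' @return an object of class `confusion_matrix`: integer matrix with
#'   dimnames, attribute `class_labels`.
#' @export
confusion_matrix <- function(y_true, y_pred, class_labels = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (is.null(class_labels)) class_labels <- sort(unique(c(y_true, y_pred)))
  unknown <- setdiff(unique(c(y_true, y_pred)), class_labels)
  if (length(unknown)) {
    stop("labels outside the vocabulary: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  k <- length(class_labels)
  counts <- matrix(0L, k, k, dimnames = list(true = class_labels,
                                             predicted = class_labels))
  if (length(y_true)) {
    tab <- table(factor(y_true, class_labels), factor(y_pred, class_labels))
    counts[] <- as.integer(tab)
  }
  structure(counts, class = c("confusion_matrix", "matrix"),
            class_labels = class_labels)
}

#' Per-class one-vs-all counts and metrics
#'
#' For each class: `TP` is the diagonal entry, `FP` the column sum minus
#' `TP`, `FN` the row sum minus `TP`, `TN` the remainder; precision,
#' recall and F1 follow. A zero denominator yields 0 with `undefined = TRUE`
#' so macro means stay defined.
#'
#' @param cm a [confusion_matrix()].
#' @return data frame with one row per class: `class`, `TP`, `FP`, `FN`,
#'   `TN`, `support`, `precision`, `recall`, `f1`, `undefined`.
#' @export
per_class_metrics <- function(cm) {
  counts <- unclass(cm)
  total <- sum(counts)
  tp <- diag(counts)
  fp <- colSums(counts) - tp
  fn <- rowSums(counts) - tp
  tn <- total - tp - fp - fn
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  data.frame(
    class = attr(cm, "class_labels"),
    TP = as.integer(tp), FP = as.integer(fp), FN = as.integer(fn),
    TN = as.integer(tn), support = as.integer(tp + fn),
    precision = precision, recall = recall, f1 = f1,
    undefined = (tp + fp == 0) | (tp + fn == 0),
    row.names = NULL
  )
}

#' Aggregate per-class metrics into a report
#'
#' Macro averages are unweighted means over classes; weighted averages weight
#' each class by its support. Accuracy is the trace over the total; the
#' algebraic identity weighted recall = accuracy is asserted.
#'
#' @param metrics output of [per_class_metrics()].
#' @return list of class `metrics_report`: `macro` and `weighted`
#'   (each precision/recall/f1), `accuracy`, `per_class`.
#' @export
aggregate_metrics <- function(metrics) {
  if (nrow(metrics) == 0) stop("no classes to aggregate", call. = FALSE)
  total <- sum(metrics$support)
  macro <- list(precision = mean(metrics$precision),
                recall = mean(metrics$recall),
                f1 = mean(metrics$f1))
  w <- if (total > 0) metrics$support / total else
    rep(1 / nrow(metrics), nrow(metrics))
  weighted <- list(precision = sum(w * metrics$precision),
                   recall = sum(w * metrics$recall),
                   f1 = sum(w * metrics$f1))
  accuracy <- if (total > 0) sum(metrics$TP) / total else 0
  if (total > 0 && abs(weighted$recall - accuracy) > 1e-12) {
    stop("internal error: weighted recall does not equal accuracy",
         call. = FALSE)
  }
  structure(list(macro = macro, weighted = weighted, accuracy = accuracy,
                 per_class = metrics),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f\n", x$accuracy))
  cat(sprintf("macro    P %.4f  R %.4f  F1 %.4f\n",
              x$macro$precision, x$macro$recall, x$macro$f1))
  cat(sprintf("weighted P %.4f  R %.4f  F1 %.4f\n",
              x$weighted$precision, x$weighted$recall, x$weighted$f1))
  invisible(x)
}

#' Evaluate a trained model on the validation side of a plan
#'
#' @param model a `har_cnn`.
#' @param dataset the `har_dataset` the plan refers to.
#' @param plan the `split_plan` used for training.
#' @return a `metrics_report` with the confusion matrix attached as
#'   attribute `"confusion"`.
#' @export
evaluate_model <- function(model, dataset, plan) {
  lab <- plan_labels(dataset, plan)
  idx <- plan$val_indices
  pred <- predict(model, dataset$values[idx, , , drop = FALSE])
  cm <- confusion_matrix(lab$class_labels[lab$y[idx]], pred$label,
                         model$class_labels)
  rep <- aggregate_metrics(per_class_metrics(cm))
  attr(rep, "confusion") <- cm
  rep
}

#' Export a metrics report as JSON
#' @param report a `metrics_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  obj <- list(accuracy = report$accuracy, macro = report$macro,
              weighted = report$weighted, per_class = report$per_class)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), path, useBytes = TRUE)
  invisible(path)
}
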