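# Confusion-matrix metrics. Rows are actual classes, columns predicted.
# Precision = TP/(TP+FP), recall = TP/(TP+FN), F1 = harmonic mean; every 0/0
# is 0 by convention. Macro-average = unweighted mean over classes (the
# headline aggregate); micro-average (= accuracy in single-label multiclass)
# is also reported.

#' Confusion matrix of actual versus predicted labels
#'
#' @param actual,predicted Vectors of class labels.
#' @param classes Class order (default [comp_classes()]).
#' @return Integer matrix with `classes` as both dimnames; rows = actual.
#' @export
confusion_matrix <- function(actual, predicted, classes = comp_classes()) {
  bad <- setdiff(unique(c(actual, predicted)), classes)
  if (length(bad)) stopf("labels outside class set: %s",
                         paste(bad, collapse = ", "))
  a <- factor(actual, levels = classes)
  p <- factor(predicted, levels = classes)
  cm <- table(actual = a, predicted = p)
  matrix(as.integer(cm), nrow = length(classes),
         dimnames = list(actual = classes, predicted = classes))
}

#' Precision, recall and F1 for one class (one-vs-rest)
#'
#' With `TP = cm[cls, cls]`, `FP` the rest of the predicted column and `FN`
#' the rest of the actual row: precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)`; 0/0 cases are 0.
#'
#' @param cm Square confusion matrix with dimnames (rows = actual).
#' @param cls Class name.
#' @return Named vector `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(cm, cls) {
  if (!cls %in% rownames(cm)) stopf("unknown class '%s'", cls)
  tp <- cm[cls, cls]
  fp <- sum(cm[, cls]) - tp
  fn <- sum(cm[cls, ]) - tp
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  c(precision = precision, recall = recall, f1 = f1)
}

#' Per-class and aggregate metrics of a confusion matrix
#'
#' @param cm Confusion matrix (rows = actual).
#' @return Data frame with one row per class plus attributes; see also
#'   [macro_f1()] and [micro_f1()].
#' @export
class_metrics <- function(cm) {
  out <- t(vapply(rownames(cm), function(cls) precision_recall_f1(cm, cls),
                  numeric(3)))
  data.frame(class = rownames(cm), out, row.names = NULL)
}

#' @rdname class_metrics
#' @export
macro_f1 <- function(cm) {
  mean(vapply(rownames(cm), function(cls) precision_recall_f1(cm, cls)[["f1"]],
              numeric(1)))
}

#' @rdname class_metrics
#' @export
micro_f1 <- function(cm) sum(diag(cm)) / sum(cm)
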