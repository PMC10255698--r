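# Evaluation metrics computed from first principles.

#' Multiclass confusion matrix
#'
#' @param y_true,y_pred Integer label vectors of equal length, values in
#'   `0..k-1`.
#' @param k Number of classes.
#' @return A `confusion_counts` object: k x k integer matrix, rows = true
#'   class, columns = predicted class, dimnames "0".."k-1".
#' @export
confusion_matrix <- function(y_true, y_pred, k) {
  k <- check_count(k, "k", lower = 2L)
  if (length(y_true) != length(y_pred)) {
    abort_invalid("y_true and y_pred must have equal length")
  }
  if (length(y_true) == 0L) abort_invalid("empty label vectors")
  if (any(y_true < 0 | y_true >= k) || any(y_pred < 0 | y_pred >= k)) {
    abort_invalid(sprintf("labels must lie in 0..%d", k - 1L))
  }
  m <- matrix(0L, k, k, dimnames = list(true = as.character(0:(k - 1L)),
                                        pred = as.character(0:(k - 1L))))
  for (i in seq_along(y_true)) {
    m[y_true[i] + 1L, y_pred[i] + 1L] <- m[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  }
  structure(m, class = c("confusion_counts", "matrix"))
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2PR / (P + R)`; returns 0 (the package's zero-division
#' convention) when both are 0.
#'
#' @param precision,recall Numeric values in `[0, 1]` (vectorized).
#' @return Numeric F1 values.
#' @export
f1_score <- function(precision, recall) {
  denom <- precision + recall
  ifelse(denom > 0, 2 * precision * recall / denom, 0)
}

#' Macro average
#'
#' Unweighted mean of per-class metric values.
#'
#' @param x Numeric vector of per-class values.
#' @return Scalar mean.
#' @export
macro_average <- function(x) mean(x)

#' Support-weighted average
#'
#' @param x Numeric vector of per-class values.
#' @param support Integer vector of true-instance counts per class.
#' @return Scalar weighted mean.
#' @export
weighted_average <- function(x, support) {
  if (length(x) != length(support)) {
    abort_invalid("x and support must have equal length")
  }
  sum(x * support) / sum(support)
}

#' Full evaluation report from a confusion matrix
#'
#' Computes accuracy (trace / total), per-class precision, recall, F1 and
#' support, plus macro (unweighted) and support-weighted averages. Classes
#' with a zero denominator score 0 with a warning.
#'
#' @param cm A [confusion_matrix()] (or plain square count matrix).
#' @return An `evaluation_report`: list with `accuracy`, `per_class`
#'   (data.frame: class, precision, recall, f1, support), `macro`,
#'   `weighted`, `total`, and `confusion`.
#' @export
metrics_report <- function(cm) {
  m <- unclass(cm)
  if (!is.matrix(m) || nrow(m) != ncol(m) || nrow(m) < 1L) {
    abort_invalid("`cm` must be a square count matrix")
  }
  if (sum(m) == 0) abort_invalid("confusion matrix is empty")
  k <- nrow(m)
  total <- sum(m)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  support <- rowSums(m)
  zden <- (tp + fp) == 0 | (tp + fn) == 0
  if (any(zden)) {
    warning(sprintf("zero denominator for class(es) %s; reporting 0",
                    paste(which(zden) - 1L, collapse = ", ")))
  }
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- f1_score(precision, recall)
  per_class <- data.frame(
    class = 0:(k - 1L),
    precision = as.numeric(precision),
    recall = as.numeric(recall),
    f1 = as.numeric(f1),
    support = as.integer(support)
  )
  structure(
    list(accuracy = sum(tp) / total,
         per_class = per_class,
         macro = c(precision = macro_average(per_class$precision),
                   recall = macro_average(per_class$recall),
                   f1 = macro_average(per_class$f1)),
         weighted = c(precision = weighted_average(per_class$precision, support),
                      recall = weighted_average(per_class$recall, support),
                      f1 = weighted_average(per_class$f1, support)),
         total = as.integer(total),
         confusion = m),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d beats; accuracy %.4f\n", x$total, x$accuracy))
  print(x$per_class, row.names = FALSE)
  cat(sprintf("macro    P %.4f  R %.4f  F1 %.4f\n",
              x$macro["precision"], x$macro["recall"], x$macro["f1"]))
  cat(sprintf("weighted P %.4f  R %.4f  F1 %.4f\n",
              x$weighted["precision"], x$weighted["recall"], x$weighted["f1"]))
  invisible(x)
}

#' Evaluate a trained model on a tagged split
#'
#' @param model A trained `ecg_cnn`.
#' @param data A `beat_dataset`.
#' @param split Which split tag(s) to evaluate (default "test"); use
#'   `NULL` for all rows.
#' @return An `evaluation_report` (see [metrics_report()]).
#' @export
evaluate_model <- function(model, data, split = "test") {
  stopifnot(inherits(data, "beat_dataset"))
  idx <- if (is.null(split)) seq_along(data$labels) else
    which(data$split %in% split)
  if (!length(idx)) abort_invalid("no rows in the requested split")
  pred <- predict(model, data$beats[idx, , drop = FALSE])$label
  cm <- confusion_matrix(data$labels[idx], pred, model$cfg$n_classes)
  metrics_report(cm)
}
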