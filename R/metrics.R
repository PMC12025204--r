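#' Confusion matrix
#'
#' Counts of (true class, predicted class) pairs; rows are true classes,
#' columns predictions.
#'
#' @param y_true,y_pred Integer label vectors (0-based, equal length).
#' @param K Number of classes; default `max(labels) + 1`.
#' @return K x K integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(y_true, y_pred, K = NULL) {
  ll_assert(length(y_true) == length(y_pred),
            "`y_true` and `y_pred` must have equal length",
            "lesionlab_shape_mismatch")
  if (is.null(K)) K <- max(c(y_true, y_pred)) + 1L
  ll_assert(all(y_true >= 0 & y_true < K) && all(y_pred >= 0 & y_pred < K),
            "labels must lie in 0..K-1")
  cm <- matrix(0L, K, K,
               dimnames = list(true = 0:(K - 1), predicted = 0:(K - 1)))
  for (i in seq_along(y_true)) {
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  }
  structure(cm, class = c("confusion_matrix", "matrix", "array"))
}

#' Classification metrics from a confusion matrix
#'
#' Computes overall accuracy plus per-class precision, recall (sensitivity),
#' specificity and F1, with macro (unweighted), micro and support-weighted
#' averages. Zero-denominator cells follow the convention of reporting 0
#' with a warning flag recorded in the report.
#'
#' @param cm A [confusion()] matrix (or any K x K count matrix with rows as
#'   true classes).
#' @return An object of class `metrics_report`: list with `accuracy`,
#'   `per_class` (tibble), `macro`, `micro`, `weighted` (named vectors),
#'   `confusion`, and `zero_division` (logical flag).
#' @export
metrics <- function(cm) {
  cm <- unname(unclass(as.matrix(cm)))
  ll_assert(nrow(cm) == ncol(cm) && all(cm >= 0), "`cm` must be a square count matrix")
  total <- sum(cm)
  ll_assert(total > 0, "empty confusion matrix", "lesionlab_empty_input")
  K <- nrow(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  zero_division <- FALSE
  safe_div <- function(num, den) {
    bad <- den == 0
    if (any(bad)) zero_division <<- TRUE
    out <- ifelse(bad, 0, num / pmax(den, 1))
    out
  }
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  specificity <- safe_div(tn, tn + fp)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  support <- rowSums(cm)
  per_class <- tibble::tibble(
    class = 0:(K - 1), support = as.integer(support),
    precision = precision, recall = recall,
    specificity = specificity, f1 = f1
  )
  summarize <- function(w) {
    w <- w / sum(w)
    c(precision = sum(w * precision), recall = sum(w * recall),
      specificity = sum(w * specificity), f1 = sum(w * f1))
  }
  micro_p <- safe_div(sum(tp), sum(tp + fp))
  micro_r <- safe_div(sum(tp), sum(tp + fn))
  structure(
    list(accuracy = sum(tp) / total,
         per_class = per_class,
         macro = summarize(rep(1, K)),
         weighted = summarize(support),
         micro = c(precision = micro_p, recall = micro_r,
                   specificity = safe_div(sum(tn), sum(tn + fp)),
                   f1 = safe_div(2 * micro_p * micro_r, micro_p + micro_r)),
         confusion = cm, zero_division = zero_division),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> accuracy %.4f (n = %d)\n",
              x$accuracy, sum(x$confusion)))
  cat(sprintf("  macro: precision %.4f, recall %.4f, specificity %.4f, F1 %.4f\n",
              x$macro["precision"], x$macro["recall"],
              x$macro["specificity"], x$macro["f1"]))
  print(x$per_class)
  invisible(x)
}
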