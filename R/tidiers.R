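# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @rdname tidiers
#' @title Tidy summaries of lesionlab objects
#' @description `tidy()` returns per-component tibbles (per-class metrics,
#'   per-epoch training history, per-machine SVM summaries); `glance()`
#'   returns one-row model summaries.
#' @param x A `metrics_report`, `cae_model`, `qsvm_model` or
#'   `pipeline_report`.
#' @param ... Unused.
#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' @rdname tidiers
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy,
    macro_precision = x$macro["precision"], macro_recall = x$macro["recall"],
    macro_specificity = x$macro["specificity"], macro_f1 = x$macro["f1"],
    n = sum(x$confusion), zero_division = x$zero_division
  )
}

#' @rdname tidiers
#' @export
tidy.cae_model <- function(x, ...) x$history

#' @rdname tidiers
#' @export
glance.cae_model <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs_trained = if (nrow(h)) max(h$epoch) else 0L,
    n_params = cae_n_params(x),
    final_train_recon = if (nrow(h)) h$train_recon[nrow(h)] else NA_real_,
    final_train_acc = if (nrow(h)) h$train_acc[nrow(h)] else NA_real_,
    final_val_acc = if (nrow(h)) h$val_acc[nrow(h)] else NA_real_
  )
}

#' @rdname tidiers
#' @export
tidy.qsvm_model <- function(x, ...) {
  tibble::tibble(
    class = vapply(x$machines, function(m) m$class, numeric(1)),
    n_support = vapply(x$machines, function(m) sum(m$alpha > 0), numeric(1)),
    bias = vapply(x$machines, function(m) m$d, numeric(1)),
    alpha_sum = vapply(x$machines, function(m) sum(m$alpha), numeric(1)),
    kkt_balance = vapply(x$machines,
                         function(m) sum(m$alpha * m$yb), numeric(1))
  )
}

#' @rdname tidiers
#' @export
glance.qsvm_model <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$classes), kernel = x$spec$family,
    degree = x$spec$degree, C = x$C, n_train = nrow(x$X)
  )
}

#' @rdname tidiers
#' @export
tidy.pipeline_report <- function(x, ...) tidy(x$metrics)

#' @rdname tidiers
#' @export
glance.pipeline_report <- function(x, ...) {
  out <- glance(x$metrics)
  out$softmax_accuracy <- x$softmax_accuracy
  out$seed <- x$config$seed
  out
}

#' Plot training history
#'
#' Line plot of per-epoch reconstruction/classification losses and
#' accuracies for a trained autoencoder.
#'
#' @param object A `cae_model` with history.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cae_model <- function(object, ...) {
  h <- object$history
  ll_assert(nrow(h) > 0, "model has no training history")
  long <- tibble::tibble(
    epoch = rep(h$epoch, 3L),
    metric = rep(c("train_recon", "train_class", "train_acc"),
                 each = nrow(h)),
    value = c(h$train_recon, h$train_class, h$train_acc)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix as a heatmap
#'
#' @param object A `metrics_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metrics_report <- function(object, ...) {
  cm <- object$confusion
  df <- tibble::tibble(
    true = rep(rownames(cm), times = ncol(cm)),
    predicted = rep(colnames(cm), each = nrow(cm)),
    count = as.vector(cm)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(rownames(cm))) +
    ggplot2::labs(x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}

#' Plot a Grad-CAM heatmap
#'
#' @param object A `gradcam_heatmap`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gradcam_heatmap <- function(object, ...) {
  v <- object$values
  df <- tibble::tibble(
    row = rep(seq_len(nrow(v)), times = ncol(v)),
    col = rep(seq_len(ncol(v)), each = nrow(v)),
    value = as.vector(v)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradientn(colours = c("navy", "green3", "red")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = sprintf("class %d", object$class_id)) +
    ggplot2::theme_minimal()
}
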