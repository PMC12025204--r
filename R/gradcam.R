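#' Grad-CAM heatmap for the autoencoder's classification pathway
#'
#' Backpropagates the pre-softmax logit of `class_id` to the post-ReLU
#' activations of an encoder convolution, averages the gradients spatially
#' into channel weights, and forms `ReLU(sum_k w_k A_k)`, bilinearly
#' up-sampled to the input grid and normalized so the maximum is 1 (an
#' all-zero map is returned unchanged for degenerate gradients).
#'
#' @param model A `cae_model`.
#' @param img A single input image.
#' @param class_id Target class in `0..K-1`.
#' @param layer `"conv2"` (last encoder convolution, default) or `"conv1"`.
#' @return Object of class `gradcam_heatmap`: list with `values` (H x W
#'   matrix in \[0, 1\]), `class_id`, `layer`.
#' @export
gradcam <- function(model, img, class_id, layer = c("conv2", "conv1")) {
  layer <- match.arg(layer)
  ll_assert(class_id >= 0 && class_id < model$cfg$n_classes,
            "`class_id` out of range", "lesionlab_bad_class")
  X <- as_batch(img)
  check_input_size(model, X)
  p <- model$params
  fw <- cae_forward(model, X, training = FALSE)
  # d(logit_c) / d(z) through the dense head
  d_logits <- matrix(0, 1L, model$cfg$n_classes)
  d_logits[1L, class_id + 1L] <- 1
  d_f1 <- relu_backward(tcrossprod(d_logits, p$fW2), fw$f1)
  d_flat <- tcrossprod(d_f1, p$fW1)
  dz <- array(t(d_flat), dim = dim(fw$z))
  d_a2 <- relu_backward(pool2_backward(dz, fw$pc2), fw$a2)
  if (layer == "conv2") {
    act <- fw$a2; grad <- d_a2
  } else {
    g2 <- conv3_backward(d_a2, fw$pc1$Y, p$cW2)
    act <- fw$a1
    grad <- relu_backward(pool2_backward(g2$dX, fw$pc1), fw$a1)
  }
  w <- apply(grad[, , , 1L, drop = FALSE], 3L, mean)
  cam <- matrix(0, dim(act)[1L], dim(act)[2L])
  for (k in seq_along(w)) cam <- cam + w[k] * act[, , k, 1L]
  cam <- pmax(cam, 0)
  cam <- bilinear_resize(cam, model$cfg$input_size, model$cfg$input_size)
  cam <- matrix(cam, model$cfg$input_size, model$cfg$input_size)
  if (max(cam) > 0) cam <- cam / max(cam)
  structure(list(values = cam, class_id = as.integer(class_id),
                 layer = layer),
            class = "gradcam_heatmap")
}

# Simple blue-green-red colormap on [0, 1] (high values render red).
heat_colormap <- function(v) {
  r <- clamp(1.5 - abs(4 * v - 3), 0, 1)
  g <- clamp(1.5 - abs(4 * v - 2), 0, 1)
  b <- clamp(1.5 - abs(4 * v - 1), 0, 1)
  out <- array(0, dim = c(nrow(v), ncol(v), 3L))
  out[, , 1L] <- r; out[, , 2L] <- g; out[, , 3L] <- b
  out
}

#' Overlay a heatmap on an image
#'
#' Alpha-blends a color-mapped heatmap (red = high importance) over the
#' image: `out = (1 - alpha) * img + alpha * colormap(map)`.
#'
#' @param img Image in \[0, 1\] (grayscale images are tinted to RGB).
#' @param map A [gradcam()] heatmap (or a plain H x W matrix in \[0, 1\]).
#' @param alpha Blend weight in \[0, 1\]. Default 0.5.
#' @return H x W x 3 array in \[0, 1\].
#' @export
overlay <- function(img, map, alpha = 0.5) {
  v <- if (inherits(map, "gradcam_heatmap")) map$values else map
  a <- as_image(img)
  ll_assert(all(dim(a)[1:2] == dim(v)), "heatmap/image shape mismatch",
            "lesionlab_shape_mismatch")
  ll_assert(alpha >= 0 && alpha <= 1, "`alpha` must lie in [0, 1]")
  if (dim(a)[3L] == 1L) a <- array(rep(a, 3L), dim = c(dim(a)[1:2], 3L))
  cmap <- heat_colormap(v)
  clamp01((1 - alpha) * a + alpha * cmap)
}

# Fraction of total heatmap mass inside a quadrant (1 = top-left, 2 =
# top-right, 3 = bottom-left, 4 = bottom-right; x = columns, y = rows).
heatmap_quadrant_mass <- function(map, quadrant) {
  v <- if (inherits(map, "gradcam_heatmap")) map$values else map
  H <- nrow(v); W <- ncol(v)
  rows <- if (quadrant %in% c(1L, 2L)) 1:(H %/% 2) else (H %/% 2 + 1L):H
  cols <- if (quadrant %in% c(1L, 3L)) 1:(W %/% 2) else (W %/% 2 + 1L):W
  tot <- sum(v)
  if (tot == 0) return(0)
  sum(v[rows, cols]) / tot
}
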