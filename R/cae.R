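#' Configuration for the convolutional autoencoder
#'
#' Hyperparameters follow the conventional settings for this architecture:
#' Adam with learning rate 0.001, 50 epochs, batch size 32, L2 weight
#' penalty 0.01, dropout 0.5, ReLU activations. The encoder stacks two
#' 3x3-convolution + 2x2/stride-2 max-pooling blocks, so the bottleneck is
#' `input_size / 4` on each side and the mirrored decoder up-samples by 4x
#' back to the input grid.
#'
#' @param input_size Input side length in pixels (divisible by 4).
#' @param channels Input channel count. Default 3 (RGB).
#' @param widths Encoder channel widths, length 2. Default `c(32, 64)`.
#' @param hidden Width of the dense classifier layer. Default 64.
#' @param n_classes Number of output classes.
#' @param learning_rate Adam learning rate. Default 0.001.
#' @param epochs Training epochs. Default 50.
#' @param batch_size Minibatch size. Default 32.
#' @param l2_weight L2 penalty coefficient on weights. Default 0.01.
#' @param dropout Dropout rate on the dense classifier layer, in \[0, 1).
#'   Default 0.5.
#' @param recon_loss_weight Weight of the reconstruction (binary
#'   cross-entropy) term. Default 1.
#' @param class_loss_weight Weight of the classification (categorical
#'   cross-entropy) term. Default 1.
#' @param seed Integer seed for initialization, shuffling and dropout.
#'
#' @return An object of class `ae_config`.
#' @export
ae_config <- function(input_size = 64, channels = 3, widths = c(32, 64),
                      hidden = 64, n_classes = 7, learning_rate = 0.001,
                      epochs = 50, batch_size = 32, l2_weight = 0.01,
                      dropout = 0.5, recon_loss_weight = 1,
                      class_loss_weight = 1, seed = 1) {
  ll_assert(input_size %% 4 == 0,
            "`input_size` must be divisible by 4 (two pooling stages)",
            "lesionlab_bad_size")
  ll_assert(length(widths) == 2 && all(widths >= 1),
            "`widths` must be two positive channel counts")
  ll_assert(learning_rate > 0 && epochs >= 0 && batch_size >= 1,
            "rates and counts must be positive")
  ll_assert(dropout >= 0 && dropout < 1, "`dropout` must lie in [0, 1)")
  ll_assert(l2_weight >= 0 && recon_loss_weight >= 0 && class_loss_weight >= 0,
            "loss weights must be non-negative")
  structure(
    list(input_size = as.integer(input_size), channels = as.integer(channels),
         widths = as.integer(widths), hidden = as.integer(hidden),
         n_classes = as.integer(n_classes), learning_rate = learning_rate,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         l2_weight = l2_weight, dropout = dropout,
         recon_loss_weight = recon_loss_weight,
         class_loss_weight = class_loss_weight, seed = as.integer(seed)),
    class = "ae_config"
  )
}

#' Build an untrained convolutional autoencoder
#'
#' Encoder: two blocks of 3x3 convolution + ReLU + 2x2/stride-2 max pooling.
#' Decoder: mirrored 2x nearest-neighbour up-sampling + 3x3 convolutions with
#' a sigmoid output, expanding the bottleneck by a factor of 4 per side.
#' Classifier head: flatten, dense ReLU with dropout, softmax over classes.
#' Initialization is He-scaled Gaussian, deterministic given `cfg$seed`.
#'
#' @param cfg An [ae_config()].
#' @return An object of class `cae_model`.
#' @export
build_cae <- function(cfg) {
  ll_assert(inherits(cfg, "ae_config"), "`cfg` must be an ae_config")
  s <- cfg$input_size; C <- cfg$channels
  c1 <- cfg$widths[1L]; c2 <- cfg$widths[2L]
  bs <- s %/% 4L
  flat <- bs * bs * c2
  params <- with_seed(cfg$seed, list(
    cW1 = init_param(c(3, 3, C, c1), 9 * C),   cb1 = numeric(c1),
    cW2 = init_param(c(3, 3, c1, c2), 9 * c1), cb2 = numeric(c2),
    dW1 = init_param(c(3, 3, c2, c1), 9 * c2), db1 = numeric(c1),
    dW2 = init_param(c(3, 3, c1, C), 9 * c1),  db2 = numeric(C),
    fW1 = init_param(c(flat, cfg$hidden), flat), fb1 = numeric(cfg$hidden),
    fW2 = init_param(c(cfg$hidden, cfg$n_classes), cfg$hidden),
    fb2 = numeric(cfg$n_classes)
  ))
  structure(
    list(cfg = cfg, params = params, bottleneck = c(bs, bs, c2),
         history = tibble::tibble()),
    class = "cae_model"
  )
}

#' @export
print.cae_model <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf(
    "<cae_model> input %dx%dx%d, widths (%d, %d), bottleneck %dx%dx%d, %d classes\n",
    cfg$input_size, cfg$input_size, cfg$channels, cfg$widths[1L],
    cfg$widths[2L], x$bottleneck[1L], x$bottleneck[2L], x$bottleneck[3L],
    cfg$n_classes))
  if (nrow(x$history)) {
    cat(sprintf("  trained %d epochs (lr %g)\n", max(x$history$epoch),
                cfg$learning_rate))
  } else cat("  untrained\n")
  invisible(x)
}

# Count of trainable parameters (closed form over the configured widths).
#' @export
cae_n_params <- function(model) {
  sum(vapply(model$params, function(p) length(p), numeric(1)))
}

# Batch forward pass with caches for the backward pass. X: (H, W, C, N).
cae_forward <- function(model, X, training = FALSE, drop_mask = NULL) {
  p <- model$params
  a1 <- relu(conv3_forward(X, p$cW1, p$cb1))
  pc1 <- pool2_forward(a1)
  a2 <- relu(conv3_forward(pc1$Y, p$cW2, p$cb2))
  pc2 <- pool2_forward(a2)
  z <- pc2$Y
  u1 <- upsample2_forward(z)
  a3 <- relu(conv3_forward(u1, p$dW1, p$db1))
  u2 <- upsample2_forward(a3)
  xhat <- sigmoid(conv3_forward(u2, p$dW2, p$db2))
  N <- dim(X)[4L]
  flat <- t(matrix(z, prod(dim(z)[1:3]), N))
  f1 <- relu(dense_forward(flat, p$fW1, p$fb1))
  fd <- f1
  if (training && model$cfg$dropout > 0) {
    if (is.null(drop_mask)) {
      keep <- 1 - model$cfg$dropout
      drop_mask <- matrix(rbinom(length(f1), 1L, keep) / keep,
                          nrow(f1), ncol(f1))
    }
    fd <- f1 * drop_mask
  }
  logits <- dense_forward(fd, p$fW2, p$fb2)
  probs <- softmax_rows(logits)
  list(a1 = a1, pc1 = pc1, a2 = a2, pc2 = pc2, z = z, u1 = u1, a3 = a3,
       u2 = u2, xhat = xhat, flat = flat, f1 = f1, fd = fd,
       drop_mask = drop_mask, logits = logits, probs = probs)
}

# Joint-loss gradients for one batch. Y: one-hot matrix (N, K).
cae_backward <- function(model, X, Y, fw) {
  p <- model$params
  cfg <- model$cfg
  N <- dim(X)[4L]
  eps <- 1e-7
  xh <- clamp(fw$xhat, eps, 1 - eps)
  # reconstruction branch (BCE through sigmoid): d pre-sigmoid = (xhat - x)/M
  d_pre <- cfg$recon_loss_weight * (xh - X) / length(X)
  gb2 <- conv3_backward(d_pre, fw$u2, p$dW2)
  d_a3 <- relu_backward(upsample2_backward(gb2$dX), fw$a3)
  gb1 <- conv3_backward(d_a3, fw$u1, p$dW1)
  dz_recon <- upsample2_backward(gb1$dX)
  # classification branch (categorical cross-entropy through softmax)
  d_logits <- cfg$class_loss_weight * (fw$probs - Y) / N
  gf2 <- dense_backward(d_logits, fw$fd, p$fW2)
  d_fd <- gf2$dX
  if (!is.null(fw$drop_mask)) d_fd <- d_fd * fw$drop_mask
  d_f1 <- relu_backward(d_fd, fw$f1)
  gf1 <- dense_backward(d_f1, fw$flat, p$fW1)
  dz_cls <- array(t(gf1$dX), dim = dim(fw$z))
  # merge into the encoder
  dz <- dz_recon + dz_cls
  d_a2 <- relu_backward(pool2_backward(dz, fw$pc2), fw$a2)
  ge2 <- conv3_backward(d_a2, fw$pc1$Y, p$cW2)
  d_a1 <- relu_backward(pool2_backward(ge2$dX, fw$pc1), fw$a1)
  ge1 <- conv3_backward(d_a1, X, p$cW1, need_dX = FALSE)
  grads <- list(cW1 = ge1$dW, cb1 = ge1$db, cW2 = ge2$dW, cb2 = ge2$db,
                dW1 = gb1$dW, db1 = gb1$db, dW2 = gb2$dW, db2 = gb2$db,
                fW1 = gf1$dW, fb1 = gf1$db, fW2 = gf2$dW, fb2 = gf2$db)
  if (cfg$l2_weight > 0) {
    for (nm in c("cW1", "cW2", "dW1", "dW2", "fW1", "fW2")) {
      grads[[nm]] <- grads[[nm]] + cfg$l2_weight * p[[nm]]
    }
  }
  grads
}

cae_losses <- function(model, X, Y, fw) {
  cfg <- model$cfg
  recon <- reconstruction_loss(X, fw$xhat)
  class <- -mean(log(pmax(rowSums(fw$probs * Y), 1e-12)))
  l2 <- 0
  if (cfg$l2_weight > 0) {
    for (nm in c("cW1", "cW2", "dW1", "dW2", "fW1", "fW2")) {
      l2 <- l2 + 0.5 * cfg$l2_weight * sum(model$params[[nm]]^2)
    }
  }
  list(recon = recon, class = class,
       total = cfg$recon_loss_weight * recon +
         cfg$class_loss_weight * class + l2)
}

#' Binary cross-entropy reconstruction loss
#'
#' `L = -(1/N) sum_i [x_i log(xhat_i) + (1 - x_i) log(1 - xhat_i)]` with N
#' the element count; predictions are clamped away from 0 and 1 by 1e-7.
#'
#' @param x Original image(s) in \[0, 1\].
#' @param xhat Reconstruction(s), same shape.
#' @return Scalar loss.
#' @export
reconstruction_loss <- function(x, xhat) {
  ll_assert(identical(dim(as_image_or_batch(x)), dim(as_image_or_batch(xhat))),
            "`x` and `xhat` must have identical shapes",
            "lesionlab_shape_mismatch")
  eps <- 1e-7
  xh <- clamp(xhat, eps, 1 - eps)
  -mean(x * log(xh) + (1 - x) * log(1 - xh))
}

as_image_or_batch <- function(x) {
  if (is.array(x) && length(dim(x)) == 4L) x else as_image(x)
}

# Promote a single image to a 1-image batch.
as_batch <- function(img) {
  a <- as_image_or_batch(img)
  if (length(dim(a)) == 3L) dim(a) <- c(dim(a), 1L)
  a
}

check_input_size <- function(model, X) {
  ll_assert(all(dim(X)[1:3] == c(model$cfg$input_size, model$cfg$input_size,
                                 model$cfg$channels)),
            sprintf("input must be %dx%dx%d", model$cfg$input_size,
                    model$cfg$input_size, model$cfg$channels),
            "lesionlab_shape_mismatch")
}

#' Encode images to latent codes
#'
#' Runs the encoder (inference mode) and returns the bottleneck activations.
#'
#' @param model A [build_cae()] / [train_cae()] model.
#' @param img A single image or an H x W x C x N batch.
#' @return Latent array `h x w x c2` (or `h x w x c2 x N` for batches).
#' @export
cae_encode <- function(model, img) {
  X <- as_batch(img)
  check_input_size(model, X)
  p <- model$params
  a1 <- relu(conv3_forward(X, p$cW1, p$cb1))
  a2 <- relu(conv3_forward(pool2_forward(a1)$Y, p$cW2, p$cb2))
  z <- pool2_forward(a2)$Y
  if (dim(z)[4L] == 1L) array(z, dim = dim(z)[1:3]) else z
}

#' Decode latent codes to images
#'
#' Runs the decoder: two 2x up-sampling + convolution stages with a sigmoid
#' output, so the output grid is 4x the bottleneck grid per side.
#'
#' @param model A CAE model.
#' @param z Latent array matching the model bottleneck (optionally batched).
#' @return Reconstructed image(s) with values in (0, 1).
#' @export
cae_decode <- function(model, z) {
  if (length(dim(z)) == 3L) dim(z) <- c(dim(z), 1L)
  ll_assert(all(dim(z)[1:3] == model$bottleneck),
            sprintf("latent must be %dx%dx%d", model$bottleneck[1L],
                    model$bottleneck[2L], model$bottleneck[3L]),
            "lesionlab_shape_mismatch")
  p <- model$params
  a3 <- relu(conv3_forward(upsample2_forward(z), p$dW1, p$db1))
  xhat <- sigmoid(conv3_forward(upsample2_forward(a3), p$dW2, p$db2))
  if (dim(xhat)[4L] == 1L) array(xhat, dim = dim(xhat)[1:3]) else xhat
}

#' Class probabilities from the softmax head
#'
#' @param model A CAE model.
#' @param img A single image or batch.
#' @return Matrix (N x K) of class probabilities; rows sum to 1.
#' @export
classify_proba <- function(model, img) {
  X <- as_batch(img)
  check_input_size(model, X)
  fw <- cae_forward(model, X, training = FALSE)
  fw$probs
}

# Flattened bottleneck activations as an (N x d) feature matrix.
#' Extract flattened latent features for a dataset
#'
#' @param model A CAE model.
#' @param x A `lesion_dataset`, list of images, or image batch array.
#' @return Numeric matrix, one row per image.
#' @export
latent_features <- function(model, x) {
  X <- if (is.array(x) && length(dim(x)) == 4L) x else dataset_array(x)
  z <- cae_encode(model, X)
  if (length(dim(z)) == 3L) dim(z) <- c(dim(z), 1L)
  t(matrix(z, prod(dim(z)[1:3]), dim(z)[4L]))
}

one_hot <- function(labels, K) {
  Y <- matrix(0, length(labels), K)
  Y[cbind(seq_along(labels), labels + 1L)] <- 1
  Y
}

#' Train the convolutional autoencoder
#'
#' Minimizes `recon_loss_weight * BCE(x, xhat) + class_loss_weight *
#' cross_entropy(labels) + (l2/2) * sum(W^2)` with Adam, recording per-epoch
#' train/validation losses and accuracies. Deterministic given `cfg$seed`.
#' With `epochs = 0` the returned model equals the freshly built one.
#'
#' @param train Training `lesion_dataset`.
#' @param val Validation `lesion_dataset` (may be `NULL`).
#' @param cfg An [ae_config()].
#' @return A trained `cae_model`; `$history` is a tibble with one row per
#'   epoch (`epoch`, `lr`, `train_recon` (BCE), `train_mae` (mean absolute
#'   reconstruction error, the measure used for anomaly scoring),
#'   `train_class`, `train_total`, `train_acc`, `val_recon`, `val_mae`,
#'   `val_acc`).
#' @export
train_cae <- function(train, val, cfg) {
  ll_assert(inherits(cfg, "ae_config"), "`cfg` must be an ae_config")
  ll_assert(length(train$images) > 0, "training set is empty")
  ll_assert(all(train$labels < cfg$n_classes), "labels exceed n_classes")
  model <- build_cae(cfg)
  if (cfg$epochs == 0L) return(model)
  X <- dataset_array(train)
  check_input_size(model, X)
  Y <- one_hot(train$labels, cfg$n_classes)
  Xv <- NULL; Yv <- NULL
  if (!is.null(val) && length(val$images) > 0) {
    Xv <- dataset_array(val)
    Yv <- one_hot(val$labels, cfg$n_classes)
  }
  n <- dim(X)[4L]
  state <- adam_init(model$params)
  hist <- vector("list", cfg$epochs)
  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_recon <- 0; ep_class <- 0; ep_total <- 0; ep_correct <- 0
      ep_mae <- 0
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        Xb <- X[, , , idx, drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        fw <- cae_forward(model, Xb, training = TRUE)
        losses <- cae_losses(model, Xb, Yb, fw)
        if (!is.finite(losses$total)) {
          ll_stop(sprintf("non-finite loss at epoch %d", ep),
                  "lesionlab_divergence")
        }
        grads <- cae_backward(model, Xb, Yb, fw)
        upd <- adam_step(model$params, grads, state, cfg$learning_rate)
        model$params <- upd$params
        state <- upd$state
        w <- length(idx) / n
        ep_mae <- ep_mae + w * mean(abs(fw$xhat - Xb))
        ep_recon <- ep_recon + w * losses$recon
        ep_class <- ep_class + w * losses$class
        ep_total <- ep_total + w * losses$total
        ep_correct <- ep_correct +
          sum(max.col(fw$probs, ties.method = "first") - 1L == train$labels[idx])
      }
      val_recon <- NA_real_; val_acc <- NA_real_; val_mae <- NA_real_
      if (!is.null(Xv)) {
        ev <- cae_evaluate(model, Xv, Yv)
        val_recon <- ev$recon; val_acc <- ev$acc; val_mae <- ev$mae
      }
      hist[[ep]] <- tibble::tibble(
        epoch = ep, lr = cfg$learning_rate,
        train_recon = ep_recon, train_mae = ep_mae,
        train_class = ep_class,
        train_total = ep_total, train_acc = ep_correct / n,
        val_recon = val_recon, val_mae = val_mae, val_acc = val_acc
      )
    }
  })
  model$history <- do.call(rbind, hist)
  model
}

# Inference-mode evaluation in batches of 64 (memory bound, not a tunable).
cae_evaluate <- function(model, X, Y) {
  n <- dim(X)[4L]
  recon <- 0; correct <- 0; mae <- 0
  for (start in seq(1L, n, by = 64L)) {
    idx <- start:min(start + 63L, n)
    Xb <- X[, , , idx, drop = FALSE]
    fw <- cae_forward(model, Xb, training = FALSE)
    recon <- recon + reconstruction_loss(Xb, fw$xhat) * length(idx)
    mae <- mae + mean(abs(fw$xhat - Xb)) * length(idx)
    pred <- max.col(fw$probs, ties.method = "first") - 1L
    correct <- correct + sum(pred == (max.col(Y[idx, , drop = FALSE]) - 1L))
  }
  list(recon = recon / n, acc = correct / n, mae = mae / n)
}

#' Reconstruction-error anomaly scores
#'
#' The anomaly score of an image is the mean absolute per-pixel distance
#' between the image and its autoencoder reconstruction.
#'
#' @param model A CAE model.
#' @param images List of images (or a `lesion_dataset`).
#' @return A tibble with columns `item` and `error`.
#' @export
anomaly_scores <- function(model, images) {
  imgs <- if (inherits(images, "lesion_dataset")) images$images else images
  ll_assert(length(imgs) > 0, "empty image list", "lesionlab_empty_input")
  X <- dataset_array(imgs)
  check_input_size(model, X)
  n <- dim(X)[4L]
  errs <- numeric(n)
  for (start in seq(1L, n, by = 64L)) {
    idx <- start:min(start + 63L, n)
    Xb <- X[, , , idx, drop = FALSE]
    fw <- cae_forward(model, Xb, training = FALSE)
    diff <- abs(Xb - fw$xhat)
    errs[idx] <- apply(diff, 4L, mean)
  }
  tibble::tibble(item = seq_len(n), error = errs)
}

#' Flag anomalies by reconstruction error
#'
#' Threshold is `mean(errors) + k * sd(errors)` computed on the supplied
#' (training) errors; an image is flagged when its error strictly exceeds
#' the threshold.
#'
#' @param errors Numeric vector of reconstruction errors (length >= 2), or
#'   the tibble returned by [anomaly_scores()].
#' @param k Threshold multiplier. Default 2.
#' @param reference Optional separate error vector from which the threshold
#'   is computed (defaults to `errors` themselves).
#' @return A tibble with columns `item`, `error`, `flagged`, plus the
#'   threshold as attribute `"threshold"`.
#' @export
flag_anomalies <- function(errors, k = 2, reference = NULL) {
  if (is.data.frame(errors)) errors <- errors$error
  if (is.data.frame(reference)) reference <- reference$error
  ref <- if (is.null(reference)) errors else reference
  ll_assert(length(ref) >= 2, "need at least 2 reference errors",
            "lesionlab_empty_input")
  thr <- mean(ref) + k * sd(ref)
  out <- tibble::tibble(item = seq_along(errors), error = errors,
                        flagged = errors > thr)
  attr(out, "threshold") <- thr
  out
}
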