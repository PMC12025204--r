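#' Configuration for the class-balancing GAN
#'
#' A small fully connected generator/discriminator pair trained with the
#' classic minimax value function
#' `V(D, G) = E_x[log D(x)] + E_z[log(1 - D(G(z)))]`. One GAN is trained per
#' minority class; its generator synthesizes additional images until the
#' class reaches the majority count.
#'
#' @param latent_dim Noise dimension of `z ~ p_z` (standard normal).
#'   Default 16 (desk scale; 100 is the conventional full-scale choice).
#' @param image_size Image side length in pixels.
#' @param channels Image channel count. Default 3.
#' @param hidden Hidden-layer width for both networks. Default 64.
#' @param lr_g,lr_d Adam learning rates for generator/discriminator.
#'   Defaults 2e-3 and 1e-3 (the slower discriminator keeps the minimax
#'   generator gradient from saturating at this scale).
#' @param batch_size Minibatch size m. Default 16.
#' @param steps Number of alternating update steps. Default 500.
#' @param seed Integer seed.
#' @param logit_epsilon Clamp for the log arguments, in (0, 0.5).
#'   Default 1e-7.
#' @param non_saturating If `TRUE`, the generator minimizes
#'   `-log D(G(z))` instead of `log(1 - D(G(z)))` (a standard stability
#'   variant); the printed minimax loss is the default.
#'
#' @return An object of class `gan_config`.
#' @export
gan_config <- function(latent_dim = 16, image_size = 32, channels = 3,
                       hidden = 64, lr_g = 2e-3, lr_d = 1e-3,
                       batch_size = 16, steps = 500, seed = 1,
                       logit_epsilon = 1e-7, non_saturating = FALSE) {
  ll_assert(latent_dim >= 1, "`latent_dim` must be >= 1")
  ll_assert(lr_g > 0 && lr_d > 0, "learning rates must be > 0")
  ll_assert(logit_epsilon > 0 && logit_epsilon < 0.5,
            "`logit_epsilon` must lie in (0, 0.5)")
  ll_assert(batch_size >= 1 && steps >= 0, "counts must be non-negative")
  structure(
    list(latent_dim = as.integer(latent_dim),
         image_size = as.integer(image_size), channels = as.integer(channels),
         hidden = as.integer(hidden), lr_g = lr_g, lr_d = lr_d,
         batch_size = as.integer(batch_size), steps = as.integer(steps),
         seed = as.integer(seed), logit_epsilon = logit_epsilon,
         non_saturating = non_saturating),
    class = "gan_config"
  )
}

#' Initialize a GAN state
#'
#' @param cfg A [gan_config()].
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @param mean_intensity Optional mean intensity of the training images;
#'   when given, the generator's output bias is warm-started at its logit,
#'   so generation opens at the data's average brightness instead of
#'   mid-gray ([train_gan()] passes this automatically).
#' @return An object of class `gan_state` holding generator and
#'   discriminator parameters, the step counter and running losses.
#' @export
gan_init <- function(cfg, seed = cfg$seed, mean_intensity = NULL) {
  D <- cfg$image_size^2 * cfg$channels
  h <- cfg$hidden
  # sigmoid output layers start near-linear (small weights) so the
  # generator opens at mid-gray and neither head saturates early
  params <- with_seed(seed, list(
    gW1 = init_param(c(cfg$latent_dim, h), cfg$latent_dim), gb1 = numeric(h),
    gW2 = 0.1 * init_param(c(h, D), h), gb2 = numeric(D),
    dW1 = init_param(c(D, h), D), db1 = numeric(h),
    dW2 = 0.1 * init_param(c(h, 1L), h), db2 = numeric(1L)
  ))
  if (!is.null(mean_intensity)) {
    params$gb2[] <- stats::qlogis(clamp(mean_intensity, 0.01, 0.99))
  }
  structure(
    list(cfg = cfg, params = params, step = 0L,
         losses = tibble::tibble()),
    class = "gan_state"
  )
}

#' @export
print.gan_state <- function(x, ...) {
  cat(sprintf("<gan_state> %dx%dx%d images, latent %d, %d steps trained\n",
              x$cfg$image_size, x$cfg$image_size, x$cfg$channels,
              x$cfg$latent_dim, x$step))
  invisible(x)
}

# Generator/discriminator forward passes on row-major batches.
gan_g_forward <- function(state, Z) {
  p <- state$params
  h <- relu(dense_forward(Z, p$gW1, p$gb1))
  x <- sigmoid(dense_forward(h, p$gW2, p$gb2))
  list(h = h, x = x)
}

gan_d_forward <- function(state, X) {
  p <- state$params
  h <- relu(dense_forward(X, p$dW1, p$db1))
  d <- sigmoid(dense_forward(h, p$dW2, p$db2))
  list(h = h, d = d)
}

# Images (list / dataset / batch array) -> row-major matrix (N, H*W*C).
flatten_images <- function(x) {
  X <- if (is.array(x) && length(dim(x)) == 4L) x else dataset_array(x)
  t(matrix(X, prod(dim(X)[1:3]), dim(X)[4L]))
}

clamp_prob <- function(p, eps) clamp(p, eps, 1 - eps)

#' Empirical GAN value function
#'
#' Computes the two-term empirical mean of the minimax payoff,
#' `V = mean(log D(x)) + mean(log(1 - D(G(z))))`, with discriminator outputs
#' clamped to `[eps, 1 - eps]`.
#'
#' @param state A [gan_init()] / [train_gan()] state.
#' @param real_batch Real images: list, `lesion_dataset`, batch array, or an
#'   (N x D) matrix of flattened images.
#' @param noise_batch Matrix (m x latent_dim) of noise vectors.
#' @return Scalar value of the empirical payoff.
#' @export
gan_value <- function(state, real_batch, noise_batch) {
  X <- if (is.matrix(real_batch)) real_batch else flatten_images(real_batch)
  ll_assert(nrow(X) > 0 && nrow(noise_batch) > 0, "empty batch",
            "lesionlab_empty_input")
  eps <- state$cfg$logit_epsilon
  d_real <- clamp_prob(gan_d_forward(state, X)$d, eps)
  fake <- gan_g_forward(state, noise_batch)$x
  d_fake <- clamp_prob(gan_d_forward(state, fake)$d, eps)
  mean(log(d_real)) + mean(log(1 - d_fake))
}

#' Train a GAN on one class of images
#'
#' Alternating updates: the discriminator ascends the stochastic gradient of
#' `log D(x) + log(1 - D(G(z)))` on a fresh minibatch, then the generator
#' (on newly generated fakes) descends `log(1 - D(G(z)))` (or ascends
#' `log D(G(z))` when `non_saturating`). Deterministic given the seed.
#'
#' @param data Images of a single class: `lesion_dataset`, list of images,
#'   or a batch array.
#' @param cfg A [gan_config()].
#' @return A trained `gan_state` with `$losses` (one row per step: `step`,
#'   `loss_d`, `loss_g`, `d_real`, `d_fake`) and `$step` set.
#' @export
train_gan <- function(data, cfg) {
  X <- flatten_images(data)
  n <- nrow(X)
  ll_assert(n >= 1, "no training images", "lesionlab_empty_input")
  state <- gan_init(cfg, mean_intensity = mean(X))
  if (cfg$steps == 0L) return(state)
  eps <- cfg$logit_epsilon
  m <- cfg$batch_size
  state_d <- adam_init(state$params[c("dW1", "db1", "dW2", "db2")])
  state_g <- adam_init(state$params[c("gW1", "gb1", "gW2", "gb2")])
  losses <- vector("list", cfg$steps)
  with_seed(cfg$seed + 1L, {
    for (step in seq_len(cfg$steps)) {
      ## --- discriminator update -------------------------------------------
      idx <- sample.int(n, m, replace = n < m)
      Xr <- X[idx, , drop = FALSE]
      Z <- matrix(rnorm(m * cfg$latent_dim), m, cfg$latent_dim)
      Xf <- gan_g_forward(state, Z)$x
      fr <- gan_d_forward(state, Xr)
      ff <- gan_d_forward(state, Xf)
      dr <- clamp_prob(fr$d, eps); df <- clamp_prob(ff$d, eps)
      loss_d <- -(mean(log(dr)) + mean(log(1 - df)))
      # d loss wrt pre-sigmoid logits: real -(1 - d)/m ; fake d/m
      gd_real <- backprop_d(state, Xr, fr, -(1 - dr) / m)
      gd_fake <- backprop_d(state, Xf, ff, df / m)
      gd <- Map(`+`, gd_real[c("dW1", "db1", "dW2", "db2")],
                gd_fake[c("dW1", "db1", "dW2", "db2")])
      upd <- adam_step(state$params[names(gd)], gd, state_d, cfg$lr_d)
      state$params[names(gd)] <- upd$params
      state_d <- upd$state

      ## --- generator update (fresh fakes) ---------------------------------
      Z2 <- matrix(rnorm(m * cfg$latent_dim), m, cfg$latent_dim)
      gf <- gan_g_forward(state, Z2)
      fg <- gan_d_forward(state, gf$x)
      dg <- clamp_prob(fg$d, eps)
      if (cfg$non_saturating) {
        loss_g <- -mean(log(dg))
        d_logit <- -(1 - dg) / m
      } else {
        # minimax: d/d(logit) of mean(log(1 - D)) is -D/m
        loss_g <- mean(log(1 - dg))
        d_logit <- -dg / m
      }
      gg <- backprop_d(state, gf$x, fg, d_logit, into_input = TRUE)
      dG_x <- gg$dX
      d_h <- relu_backward(tcrossprod(
        sigmoid_backward(dG_x, gf$x), state$params$gW2), gf$h)
      ggrads <- list(
        gW1 = crossprod(Z2, d_h), gb1 = colSums(d_h),
        gW2 = crossprod(gf$h, sigmoid_backward(dG_x, gf$x)),
        gb2 = colSums(sigmoid_backward(dG_x, gf$x))
      )
      updg <- adam_step(state$params[names(ggrads)], ggrads, state_g, cfg$lr_g)
      state$params[names(ggrads)] <- updg$params
      state_g <- updg$state

      if (!is.finite(loss_d) || !is.finite(loss_g)) {
        ll_stop(sprintf("non-finite GAN loss at step %d", step),
                "lesionlab_divergence")
      }
      losses[[step]] <- tibble::tibble(step = step, loss_d = loss_d,
                                       loss_g = loss_g, d_real = mean(dr),
                                       d_fake = mean(df))
      state$step <- step
    }
  })
  state$losses <- do.call(rbind, losses)
  state
}

# Discriminator backprop from d(loss)/d(pre-sigmoid logit).
# Returns parameter grads and (optionally) the gradient w.r.t. the input.
backprop_d <- function(state, X, fw, d_logit, into_input = FALSE) {
  p <- state$params
  d_h <- relu_backward(d_logit %*% t(p$dW2), fw$h)
  out <- list(
    dW1 = crossprod(X, d_h), db1 = colSums(d_h),
    dW2 = crossprod(fw$h, d_logit), db2 = colSums(d_logit)
  )
  if (into_input) out$dX <- tcrossprod(d_h, p$dW1)
  out
}

#' Generate images from a GAN state
#'
#' @param state A `gan_state` (trained or freshly initialized).
#' @param n Number of images (>= 1).
#' @param seed Integer seed for the noise draw.
#' @return List of `n` H x W x C arrays with values in (0, 1).
#' @export
gan_generate <- function(state, n, seed) {
  ll_assert(n >= 1, "`n` must be >= 1", "lesionlab_invalid_argument")
  cfg <- state$cfg
  Z <- with_seed(seed, matrix(rnorm(n * cfg$latent_dim), n, cfg$latent_dim))
  Xf <- gan_g_forward(state, Z)$x
  lapply(seq_len(n), function(i) {
    array(Xf[i, ], dim = c(cfg$image_size, cfg$image_size, cfg$channels))
  })
}

#' Balance a dataset with per-class GAN generators
#'
#' Raises every class count to the majority count by appending synthetic
#' images from the class's trained generator. Original items are untouched;
#' synthetic items carry `synthetic = TRUE` in the metadata.
#'
#' @param ds A `lesion_dataset`.
#' @param per_class_states Named list mapping class id (as character, e.g.
#'   `"2"`) to a `gan_state`; required for every class below the majority
#'   count.
#' @param seed Integer seed for generation.
#' @return The balanced `lesion_dataset`.
#' @export
balance_dataset <- function(ds, per_class_states, seed) {
  ll_assert(inherits(ds, "lesion_dataset"), "`ds` must be a lesion_dataset")
  K <- length(ds$class_names)
  counts <- tabulate(ds$labels + 1L, nbins = K)
  target <- max(counts)
  deficit <- target - counts
  if (all(deficit == 0)) return(ds)
  seeds <- derive_seeds(seed, K)
  for (k in which(deficit > 0)) {
    key <- as.character(k - 1L)
    st <- per_class_states[[key]]
    if (is.null(st)) {
      ll_stop(sprintf("no GAN state for deficient class %s", key),
              "lesionlab_missing_state")
    }
    imgs <- gan_generate(st, deficit[k], seeds[k])
    n0 <- length(ds$images)
    ds$images <- c(ds$images, imgs)
    ds$labels <- c(ds$labels, rep(k - 1L, deficit[k]))
    ds$metadata <- rbind(
      ds$metadata,
      tibble::tibble(item = n0 + seq_len(deficit[k]), path = NA_character_,
                     class_id = k - 1L, class_name = ds$class_names[k],
                     center_x = NA_real_, center_y = NA_real_,
                     synthetic = TRUE)
    )
  }
  ds$metadata$item <- seq_along(ds$images)
  ds
}
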