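test_that("model construction fixes shapes, seeds and parameter counts", {
  cfg <- ae_config(input_size = 64, n_classes = 7, seed = 4)
  m <- build_cae(cfg)
  expect_equal(m$bottleneck, c(16L, 16L, 64L))
  m2 <- build_cae(cfg)
  expect_identical(m$params, m2$params)
  # closed-form parameter count for widths (c1, c2), channels C, classes K
  C <- 3; c1 <- 32; c2 <- 64; hid <- 64; K <- 7; flat <- 16 * 16 * c2
  want <- (9 * C * c1 + c1) + (9 * c1 * c2 + c2) +       # encoder
    (9 * c2 * c1 + c1) + (9 * c1 * C + C) +               # decoder
    (flat * hid + hid) + (hid * K + K)                    # classifier
  expect_equal(cae_n_params(m), want)
  expect_error(ae_config(input_size = 30), class = "lesionlab_bad_size")
})

test_that("encoder and decoder honor the 4x shape algebra", {
  cfg <- ae_config(input_size = 16, widths = c(2, 3), hidden = 4,
                   n_classes = 2, seed = 6)
  m <- build_cae(cfg)
  img <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  z <- cae_encode(m, img)
  expect_equal(dim(z), c(4L, 4L, 3L))
  expect_identical(z, cae_encode(m, img))      # inference determinism
  out <- cae_decode(m, z)
  expect_equal(dim(out), c(16L, 16L, 3L))      # 4x the bottleneck side
  expect_true(all(out > 0 & out < 1))          # sigmoid range
  # zero image with zero biases gives a zero latent (ReLU of 0)
  expect_equal(max(abs(cae_encode(m, array(0, dim = c(16, 16, 3))))), 0)
  expect_error(cae_encode(m, array(0, dim = c(8, 8, 3))),
               class = "lesionlab_shape_mismatch")
  expect_error(cae_decode(m, array(0, dim = c(2, 2, 3))),
               class = "lesionlab_shape_mismatch")
})

test_that("toy encoder matches a naive convolution + pooling oracle", {
  cfg <- ae_config(input_size = 8, channels = 1, widths = c(2, 2),
                   hidden = 2, n_classes = 2, seed = 11)
  m <- build_cae(cfg)
  img <- matrix(runif(64), 8, 8)
  z <- cae_encode(m, array(img, dim = c(8, 8, 1)))
  # naive path: conv -> relu -> pool, twice
  pool_naive <- function(a) {
    d <- dim(a); out <- array(0, dim = c(d[1] / 2, d[2] / 2, d[3]))
    for (c in seq_len(d[3])) for (i in seq_len(d[1] / 2)) for (j in seq_len(d[2] / 2)) {
      out[i, j, c] <- max(a[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c])
    }
    out
  }
  a1 <- pmax(oracle_conv3(array(img, dim = c(8, 8, 1)), m$params$cW1,
                          m$params$cb1), 0)
  p1 <- pool_naive(a1)
  a2 <- pmax(oracle_conv3(p1, m$params$cW2, m$params$cb2), 0)
  expect_lt(max(abs(z - pool_naive(a2))), 1e-10)
})

test_that("reconstruction loss implements binary cross-entropy exactly", {
  half <- matrix(0.5, 2, 2)
  expect_equal(reconstruction_loss(half, half), log(2), tolerance = 1e-6)
  ones <- matrix(1, 2, 2)
  expect_lt(reconstruction_loss(ones, matrix(1 - 1e-7, 2, 2)), 2e-7)
  set.seed(3)
  x <- matrix(runif(4), 2, 2); xh <- matrix(runif(4, 0.01, 0.99), 2, 2)
  manual <- -mean(x * log(xh) + (1 - x) * log(1 - xh))
  expect_lt(abs(reconstruction_loss(x, xh) - manual), 1e-9)
  expect_error(reconstruction_loss(x, matrix(0.5, 3, 3)),
               class = "lesionlab_shape_mismatch")
})

test_that("softmax head produces calibrated probability vectors", {
  cfg <- ae_config(input_size = 8, widths = c(2, 2), hidden = 3,
                   n_classes = 4, seed = 2, dropout = 0)
  m <- build_cae(cfg)
  img <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  p <- classify_proba(m, img)
  expect_equal(rowSums(p), 1, tolerance = 1e-6)
  expect_true(all(p >= 0))
  # identical logits -> uniform probabilities
  m0 <- m; m0$params$fW2[] <- 0; m0$params$fb2[] <- 0
  expect_equal(as.vector(classify_proba(m0, img)), rep(0.25, 4),
               tolerance = 1e-12)
  # softmax shift invariance
  set.seed(8)
  L <- matrix(rnorm(6), 2, 3)
  expect_equal(lesionlab:::softmax_rows(L),
               lesionlab:::softmax_rows(L + 5), tolerance = 1e-12)
})

test_that("training runs deterministically and reduces the loss", {
  spec <- fixture_spec(image_size = 16, n_classes = 2)
  ds <- make_dataset(spec, c(20, 20), seed = 31)
  cfg <- ae_config(input_size = 16, widths = c(4, 8), hidden = 8,
                   n_classes = 2, epochs = 4, batch_size = 8, seed = 7)
  m <- train_cae(ds, NULL, cfg)
  expect_equal(unique(m$history$lr), 0.001)
  expect_equal(nrow(m$history), 4)
  expect_lt(m$history$train_mae[4], m$history$train_mae[1])
  m2 <- train_cae(ds, NULL, cfg)
  expect_identical(m$params, m2$params)
  # zero epochs returns the freshly built model
  m0 <- train_cae(ds, NULL, ae_config(input_size = 16, widths = c(4, 8),
                                      hidden = 8, n_classes = 2,
                                      epochs = 0, seed = 7))
  expect_identical(m0$params, build_cae(m0$cfg)$params)
})

test_that("anomaly scores and threshold flags follow their definitions", {
  cfg <- ae_config(input_size = 8, widths = c(2, 2), hidden = 2,
                   n_classes = 2, seed = 9)
  m <- build_cae(cfg)
  imgs <- lapply(1:3, function(i) array(runif(8 * 8 * 3), dim = c(8, 8, 3)))
  sc <- anomaly_scores(m, imgs)
  expect_equal(nrow(sc), 3)
  # brute-force mean-absolute oracle through encode/decode
  for (i in 1:3) {
    xh <- cae_decode(m, cae_encode(m, imgs[[i]]))
    expect_lt(abs(sc$error[i] - mean(abs(imgs[[i]] - xh))), 1e-10)
  }
  expect_error(anomaly_scores(m, list()), class = "lesionlab_empty_input")
  # threshold arithmetic
  flags <- flag_anomalies(c(rep(0.1, 9), 10), k = 2)
  expect_equal(which(flags$flagged), 10L)
  thr <- attr(flags, "threshold")
  expect_equal(thr, mean(c(rep(0.1, 9), 10)) + 2 * sd(c(rep(0.1, 9), 10)))
  expect_false(any(flag_anomalies(rep(0.3, 5), k = 2)$flagged))
  k0 <- flag_anomalies(c(1, 2, 3, 4), k = 0)
  expect_equal(k0$flagged, c(1, 2, 3, 4) > 2.5)
  expect_error(flag_anomalies(0.5), class = "lesionlab_empty_input")
})
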