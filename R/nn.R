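# Minimal neural-network primitives in base R. Convolutions are 3x3,
# stride 1, zero-padded ("same"), computed as nine shifted BLAS GEMMs over a
# batch laid out as an H x W x C x N array. All layers provide exact
# backward passes; correctness is pinned by finite-difference tests.

.conv_cache <- new.env(parent = emptyenv())

# Gather-index vectors (one per 3x3 offset) mapping output pixels to input
# pixels across a batch; out-of-range pixels point at a trailing zero row.
conv_maps <- function(H, W, N) {
  key <- paste(H, W, N, sep = "_")
  hit <- .conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  HW <- H * W
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  maps <- vector("list", 9L)
  k <- 0L
  for (dj in -1:1) {
    for (di in -1:1) {
      k <- k + 1L
      ii <- i + di; jj <- j + dj
      ok <- ii >= 1L & ii <= H & jj >= 1L & jj <= W
      m <- ifelse(ok, ii + (jj - 1L) * H, 0L)
      idx <- rep(m, N) + rep((seq_len(N) - 1L) * HW, each = HW)
      idx[rep(m == 0L, N)] <- HW * N + 1L
      maps[[k]] <- idx
    }
  }
  out <- list(maps = maps, rev = 10L - seq_len(9L))
  .conv_cache[[key]] <- out
  out
}

# Zero-row-padded pixel-major matrix view of a batch: (HWN + 1) x C.
conv_padded_matrix <- function(X, HWN, C) {
  Xz <- matrix(0, HWN + 1L, C)
  Xz[seq_len(HWN), ] <- aperm(X, c(1L, 2L, 4L, 3L))
  Xz
}

# X: (H, W, C, N); Wt: (3, 3, C, F) ordered [di, dj, c, f]; b: length F.
# Compiled im2col + GEMM path; the pure-R reference below doubles as the
# independent oracle in the tests.
conv3_forward <- function(X, Wt, b) {
  .conv3_forward_cpp(X, Wt, b)
}

conv3_backward <- function(dY, X, Wt, need_dX = TRUE) {
  g <- .conv3_backward_cpp(dY, X, Wt)
  dX <- if (need_dX) {
    .conv3_forward_cpp(dY, flip_weights(Wt), numeric(dim(X)[3L]))
  } else NULL
  list(dX = dX, dW = g$dW, db = g$db)
}

conv3_forward_ref <- function(X, Wt, b) {
  d <- dim(X); H <- d[1L]; W <- d[2L]; C <- d[3L]; N <- d[4L]
  Fc <- dim(Wt)[4L]
  cm <- conv_maps(H, W, N)
  HWN <- H * W * N
  Xz <- conv_padded_matrix(X, HWN, C)
  Y <- matrix(rep(b, each = HWN), HWN, Fc)
  k <- 0L
  for (dj in -1:1) {
    for (di in -1:1) {
      k <- k + 1L
      Wk <- matrix(Wt[di + 2L, dj + 2L, , ], C, Fc)
      Y <- Y + Xz[cm$maps[[k]], , drop = FALSE] %*% Wk
    }
  }
  dim(Y) <- c(H, W, N, Fc)
  aperm(Y, c(1L, 2L, 4L, 3L))
}

# Spatially flipped, channel-transposed weights: conv with these applied to
# dY yields the input gradient of the original convolution.
flip_weights <- function(Wt) {
  d <- dim(Wt)
  out <- array(0, dim = c(3L, 3L, d[4L], d[3L]))
  for (di in 1:3) {
    for (dj in 1:3) {
      out[di, dj, , ] <- t(matrix(Wt[4L - di, 4L - dj, , ], d[3L], d[4L]))
    }
  }
  out
}

conv3_backward_ref <- function(dY, X, Wt, need_dX = TRUE) {
  d <- dim(X); H <- d[1L]; W <- d[2L]; C <- d[3L]; N <- d[4L]
  Fc <- dim(Wt)[4L]
  cm <- conv_maps(H, W, N)
  HWN <- H * W * N
  Xz <- conv_padded_matrix(X, HWN, C)
  dYm <- matrix(aperm(dY, c(1L, 2L, 4L, 3L)), HWN, Fc)
  dW <- array(0, dim = dim(Wt))
  k <- 0L
  for (dj in -1:1) {
    for (di in -1:1) {
      k <- k + 1L
      dW[di + 2L, dj + 2L, , ] <-
        crossprod(Xz[cm$maps[[k]], , drop = FALSE], dYm)
    }
  }
  dX <- if (need_dX) {
    conv3_forward_ref(dY, flip_weights(Wt), numeric(C))
  } else NULL
  list(dX = dX, dW = dW, db = colSums(dYm))
}

# 2x2 max pooling, stride 2. Ties route the gradient to the first position
# in scan order for determinism.
pool2_forward <- function(X) {
  d <- dim(X); H <- d[1L]; W <- d[2L]
  ro <- seq(1L, H, 2L); re <- seq(2L, H, 2L)
  co <- seq(1L, W, 2L); ce <- seq(2L, W, 2L)
  s1 <- X[ro, co, , , drop = FALSE]; s2 <- X[re, co, , , drop = FALSE]
  s3 <- X[ro, ce, , , drop = FALSE]; s4 <- X[re, ce, , , drop = FALSE]
  Y <- pmax(s1, s2, s3, s4)
  m1 <- s1 == Y
  m2 <- (s2 == Y) & !m1
  m3 <- (s3 == Y) & !m1 & !m2
  m4 <- (s4 == Y) & !m1 & !m2 & !m3
  list(Y = Y, masks = list(m1, m2, m3, m4), in_dim = d)
}

pool2_backward <- function(dY, cache) {
  d <- cache$in_dim; H <- d[1L]; W <- d[2L]
  ro <- seq(1L, H, 2L); re <- seq(2L, H, 2L)
  co <- seq(1L, W, 2L); ce <- seq(2L, W, 2L)
  dX <- array(0, dim = d)
  dX[ro, co, , ] <- dY * cache$masks[[1L]]
  dX[re, co, , ] <- dY * cache$masks[[2L]]
  dX[ro, ce, , ] <- dY * cache$masks[[3L]]
  dX[re, ce, , ] <- dY * cache$masks[[4L]]
  dX
}

# 2x nearest-neighbour up-sampling (the reverse of max pooling).
upsample2_forward <- function(X) {
  d <- dim(X)
  X[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), , ,
    drop = FALSE]
}

upsample2_backward <- function(dY) {
  d <- dim(dY); H <- d[1L]; W <- d[2L]
  ro <- seq(1L, H, 2L); re <- seq(2L, H, 2L)
  co <- seq(1L, W, 2L); ce <- seq(2L, W, 2L)
  dY[ro, co, , , drop = FALSE] + dY[re, co, , , drop = FALSE] +
    dY[ro, ce, , , drop = FALSE] + dY[re, ce, , , drop = FALSE]
}

# Dense layer on row-major batches: X (N, d_in), W (d_in, d_out).
dense_forward <- function(X, W, b) X %*% W + rep(b, each = nrow(X))
dense_backward <- function(dY, X, W) {
  list(dX = tcrossprod(dY, W), dW = crossprod(X, dY), db = colSums(dY))
}

relu <- function(x) pmax(x, 0)
relu_backward <- function(dY, Y) dY * (Y > 0)

sigmoid <- function(x) 1 / (1 + exp(-x))
sigmoid_backward <- function(dY, Y) dY * Y * (1 - Y)

softmax_rows <- function(X) {
  e <- exp(X - apply(X, 1L, max))
  e / rowSums(e)
}

# He-scaled Gaussian initialization for a parameter list given fan-ins.
init_param <- function(dims, fan_in) {
  array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
}

adam_init <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
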