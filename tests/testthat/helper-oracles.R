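# Independent brute-force oracles used across the suite. These are written
# as plain scalar/loop code, deliberately separate from the package's
# vectorized implementations.

# Dense 2-D Gaussian convolution with symmetric (edge-repeated) reflection
# padding; kernel truncated at ceiling(3 sigma) like the package kernel.
oracle_gauss_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k1 <- dnorm(seq(-r, r), sd = sigma)
  k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  H <- nrow(m); W <- ncol(m)
  refl <- function(i, n) {
    j <- (i - 1) %% (2 * n)
    j <- ifelse(j < 0, j + 2 * n, j)
    ifelse(j < n, j + 1, 2 * n - j)
  }
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      acc <- 0
      for (di in -r:r) {
        for (dj in -r:r) {
          acc <- acc + K[di + r + 1, dj + r + 1] *
            m[refl(i + di, H), refl(j + dj, W)]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# Naive bilinear resize with the pixel-center convention.
oracle_bilinear_resize <- function(m, h2, w2) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, h2, w2)
  for (i in seq_len(h2)) {
    for (j in seq_len(w2)) {
      p <- min(max((i - 0.5) * H / h2 + 0.5, 1), H)
      q <- min(max((j - 0.5) * W / w2 + 0.5, 1), W)
      i0 <- floor(p); j0 <- floor(q)
      ti <- p - i0; tj <- q - j0
      i1 <- min(i0 + 1, H); j1 <- min(j0 + 1, W)
      out[i, j] <- (1 - ti) * (1 - tj) * m[i0, j0] + (1 - ti) * tj * m[i0, j1] +
        ti * (1 - tj) * m[i1, j0] + ti * tj * m[i1, j1]
    }
  }
  out
}

# Naive 3x3 zero-padded convolution (triple loop) on a single sample.
oracle_conv3 <- function(X, Wt, b) {
  d <- dim(X); H <- d[1]; W <- d[2]; C <- d[3]
  Fc <- dim(Wt)[4]
  out <- array(0, dim = c(H, W, Fc))
  for (f in seq_len(Fc)) {
    for (i in seq_len(H)) {
      for (j in seq_len(W)) {
        acc <- b[f]
        for (di in -1:1) for (dj in -1:1) for (c in seq_len(C)) {
          ii <- i + di; jj <- j + dj
          if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
            acc <- acc + Wt[di + 2, dj + 2, c, f] * X[ii, jj, c]
          }
        }
        out[i, j, f] <- acc
      }
    }
  }
  out
}

# Dense statevector oracle for the second-order-expansion feature map:
# explicit Hadamard/diagonal matrices multiplied out (qubit 1 fastest).
oracle_soe_statevector <- function(x, repetitions = 2, entanglement = NULL) {
  n <- length(x)
  H1 <- matrix(c(1, 1, 1, -1), 2, 2) / sqrt(2)
  Hn <- 1
  for (q in seq_len(n)) Hn <- kronecker(Hn, H1)  # qubit 1 = last factor
  # Pauli-Z eigenvalues with qubit 1 fastest-varying
  bits <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Z <- 1 - 2 * bits
  if (is.null(entanglement) && n >= 2) entanglement <- t(combn(n, 2))
  phase <- Z %*% x
  if (!is.null(entanglement) && nrow(entanglement)) {
    for (p in seq_len(nrow(entanglement))) {
      i <- entanglement[p, 1]; j <- entanglement[p, 2]
      phase <- phase + (pi - x[i]) * (pi - x[j]) * Z[, i] * Z[, j]
    }
  }
  # kronecker with qubit 1 as last factor enumerates qubit n fastest, so
  # build the diagonal in the same basis ordering as the package (qubit 1
  # fastest) and permute Hn accordingly: with H^{\otimes n} symmetric under
  # qubit relabeling, Hn entries depend only on bit parities, so ordering
  # is immaterial; verify via direct product.
  U <- diag(as.vector(exp(1i * phase))) %*% Hn
  psi <- c(1, rep(0, 2^n - 1))
  for (r in seq_len(repetitions)) psi <- U %*% psi
  as.vector(psi)
}

# Per-class metric formulas computed longhand from a confusion matrix.
oracle_metrics <- function(cm) {
  K <- nrow(cm); total <- sum(cm)
  out <- data.frame(class = 0:(K - 1), precision = 0, recall = 0,
                    specificity = 0, f1 = 0)
  for (c in seq_len(K)) {
    tp <- cm[c, c]
    fp <- sum(cm[-c, c])
    fn <- sum(cm[c, -c])
    tn <- total - tp - fp - fn
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    out$precision[c] <- p
    out$recall[c] <- r
    out$specificity[c] <- if (tn + fp == 0) 0 else tn / (tn + fp)
    out$f1[c] <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  }
  out
}

# Scalar-loop CLAHE at the package's own conventions (quantization,
# integer excess redistribution, block-anchored interpolation) — validates
# the vectorized implementation pixel by pixel.
oracle_clahe <- function(m, tiles, clip, levels) {
  H <- nrow(m); W <- ncol(m)
  tr <- tiles[1]; tc <- tiles[2]
  th <- ceiling(H / tr); tw <- ceiling(W / tc)
  refl <- function(i, n) {
    j <- (i - 1) %% (2 * n); j <- ifelse(j < 0, j + 2 * n, j)
    ifelse(j < n, j + 1, 2 * n - j)
  }
  v <- matrix(floor(pmin(pmax(m, 0), 1) * (levels - 1) + 0.5), H, W)
  vp <- v[refl(seq_len(th * tr), H), refl(seq_len(tw * tc), W)]
  clim <- max(1, floor(clip * th * tw / levels))
  clip_hist <- function(h, clim) {
    n_ex <- sum(pmax(h - clim, 0))
    if (n_ex <= 0) return(h)
    h <- pmin(h, clim)
    bin_incr <- n_ex %/% length(h); upper <- clim - bin_incr
    low <- h < upper
    n_ex <- n_ex - sum(low) * bin_incr; h[low] <- h[low] + bin_incr
    mid <- h >= upper & h < clim
    n_ex <- n_ex + sum(h[mid]) - sum(mid) * clim; h[mid] <- clim
    while (n_ex > 0) {
      prev <- n_ex
      for (index in seq_along(h)) {
        under <- h < clim
        step <- max(1, sum(under) %/% n_ex)
        sel <- seq(index, length(h), by = step)
        sel <- sel[under[sel]]
        if (length(sel) > n_ex) sel <- sel[seq_len(n_ex)]
        h[sel] <- h[sel] + 1
        n_ex <- n_ex - length(sel)
        if (n_ex <= 0) break
      }
      if (prev == n_ex) break
    }
    h
  }
  maps <- vector("list", tr * tc)
  for (i in seq_len(tr)) {
    for (j in seq_len(tc)) {
      tile <- vp[((i - 1) * th + 1):(i * th), ((j - 1) * tw + 1):(j * tw)]
      h <- clip_hist(tabulate(tile + 1, nbins = levels), clim)
      maps[[(i - 1) * tc + j]] <- (levels - 1) * cumsum(h) / sum(h)
    }
  }
  getmap <- function(i, j) maps[[(i - 1) * tc + j]]
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    pr <- (i - 1) / th + 0.5
    r1 <- floor(pr); wr <- pr - r1
    if (r1 < 1) { r1 <- 1; wr <- 0 }
    if (r1 >= tr) { r1 <- tr; wr <- 0 }
    r2 <- min(r1 + 1, tr)
    for (j in seq_len(W)) {
      pc <- (j - 1) / tw + 0.5
      c1 <- floor(pc); wc <- pc - c1
      if (c1 < 1) { c1 <- 1; wc <- 0 }
      if (c1 >= tc) { c1 <- tc; wc <- 0 }
      c2 <- min(c1 + 1, tc)
      vv <- v[i, j] + 1
      val <- (1 - wr) * (1 - wc) * getmap(r1, c1)[vv] +
        (1 - wr) * wc * getmap(r1, c2)[vv] +
        wr * (1 - wc) * getmap(r2, c1)[vv] +
        wr * wc * getmap(r2, c2)[vv]
      out[i, j] <- floor(val + 0.5) / (levels - 1)
    }
  }
  out
}

# Run scikit-image's CLAHE through the system python (cross-implementation
# reference); clip is in counts per bin.
skimage_clahe <- function(m, kernel, clip_counts, nbins = 256) {
  fin <- tempfile(fileext = ".txt")
  fout <- tempfile(fileext = ".txt")
  on.exit(unlink(c(fin, fout)))
  write.table(m, fin, row.names = FALSE, col.names = FALSE)
  cl <- clip_counts * nbins / (kernel * kernel) / nbins
  code <- sprintf(paste0(
    "import numpy as np; from skimage.exposure import equalize_adapthist as eq; ",
    "a = np.loadtxt(%s); ",
    "np.savetxt(%s, eq(a, kernel_size=%d, clip_limit=%.12f, nbins=%d))"),
    shQuote(fin), shQuote(fout), kernel, cl, nbins)
  status <- system2("python", c("-c", shQuote(code)))
  if (status != 0) stop("python/skimage reference call failed")
  as.matrix(read.table(fout))
}

# Small deterministic test images.
fixture_image <- function(seed = 1, size = 16) {
  set.seed(seed)
  matrix(runif(size * size), size, size)
}

fixture_image_8bit <- function(seed = 1, size = 16) {
  set.seed(seed)
  matrix(sample(0:255, size * size, replace = TRUE) / 255, size, size)
}
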