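# Internal helpers shared across modules. Image convention: numeric array
# H x W x C (or an H x W matrix for grayscale), intensities in [0, 1].

ll_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "lesionlab_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

ll_assert <- function(cond, msg, class = "lesionlab_invalid_argument") {
  if (!isTRUE(cond)) ll_stop(msg, class)
}

# Run code with a private RNG stream; the caller's .Random.seed is restored.
with_seed <- function(seed, code) {
  ll_assert(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
            "`seed` must be a single finite number")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# Derive n child seeds from one parent seed (all below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
clamp01 <- function(x) clamp(x, 0, 1)

# Deterministic half-up rounding (base round() is round-half-even).
round_half_up <- function(x) floor(x + 0.5)

is_image <- function(x) {
  is.numeric(x) && (is.matrix(x) || (is.array(x) && length(dim(x)) == 3L))
}

# Coerce to H x W x C array; matrices become single-channel.
as_image <- function(x) {
  ll_assert(is_image(x), "input is not an image (numeric matrix or HxWxC array)",
            "lesionlab_not_image")
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

# Restore original shape (matrix in, matrix out).
like_image <- function(values, template) {
  if (is.matrix(template)) {
    matrix(values, nrow(template), ncol(template))
  } else {
    array(values, dim = dim(template))
  }
}

n_channels <- function(x) if (is.matrix(x)) 1L else dim(x)[3L]

# ITU-R 601 luminance.
luminance <- function(img) {
  if (is.matrix(img)) return(img)
  if (dim(img)[3L] == 1L) return(img[, , 1L])
  0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
}

# Reflect (symmetric, edge-repeated) index folding into 1..n.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j < 0, j + 2L * n, j)
  as.integer(ifelse(j < n, j + 1L, 2L * n - j))
}

gauss_kernel_1d <- function(sigma) {
  ll_assert(is.numeric(sigma) && sigma > 0, "`sigma` must be > 0")
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# Dense n x n one-dimensional smoothing operator with reflect padding; the
# 2-D blur of a separable kernel is Rm %*% img %*% t(Cm).
blur_matrix <- function(n, sigma) {
  k <- gauss_kernel_1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  B <- matrix(0, n, n)
  for (o in seq(-r, r)) {
    idx <- cbind(seq_len(n), reflect_index(seq_len(n) + o, n))
    B[idx] <- B[idx] + k[o + r + 1L]
  }
  B
}

# Gaussian blur per channel, reflect boundary, exact separable computation.
gaussian_blur <- function(img, sigma) {
  a <- as_image(img)
  d <- dim(a)
  Rm <- blur_matrix(d[1L], sigma)
  Cm <- if (d[2L] == d[1L]) Rm else blur_matrix(d[2L], sigma)
  out <- a
  for (c in seq_len(d[3L])) out[, , c] <- Rm %*% a[, , c] %*% t(Cm)
  like_image(out, img)
}

# Row/column interpolation matrix for bilinear resampling with the
# pixel-center convention: src = (dst - 0.5) * n_in / n_out + 0.5.
interp_matrix <- function(n_out, n_in) {
  M <- matrix(0, n_out, n_in)
  p <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  p <- clamp(p, 1, n_in)
  i0 <- pmin(floor(p), n_in)
  t <- p - i0
  for (i in seq_len(n_out)) {
    M[i, i0[i]] <- M[i, i0[i]] + (1 - t[i])
    if (t[i] > 0) M[i, i0[i] + 1L] <- M[i, i0[i] + 1L] + t[i]
  }
  M
}

bilinear_resize <- function(img, h_out, w_out = h_out) {
  a <- as_image(img)
  d <- dim(a)
  Rm <- interp_matrix(h_out, d[1L])
  Cm <- interp_matrix(w_out, d[2L])
  out <- array(0, dim = c(h_out, w_out, d[3L]))
  for (c in seq_len(d[3L])) out[, , c] <- Rm %*% a[, , c] %*% t(Cm)
  if (is.matrix(img)) out[, , 1L] else out
}

# Rescale to [0, 1] by min-max; degenerate range maps to a flat 0.5.
rescale01 <- function(x) {
  rng <- range(x)
  if (diff(rng) < 1e-12) return(x * 0 + 0.5)
  (x - rng[1L]) / diff(rng)
}
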