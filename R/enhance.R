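#' Configuration for the image-enhancement chain
#'
#' Parameters for the five enhancement operators (multi-scale retinex, gamma
#' correction, histogram equalization, unsharp masking, CLAHE) and the
#' composed preprocessing pipeline.
#'
#' @param retinex_scales Gaussian surround sigmas in pixels. `NULL` (default)
#'   uses the conventional multi-scale-retinex triple c(15, 80, 250) scaled
#'   by `image_size / 256` at call time.
#' @param retinex_weights Per-scale weights summing to 1; default equal.
#' @param log_epsilon Small positive intensity added inside the logarithms.
#'   Default 1/255.
#' @param gamma Power-law exponent (> 0). Default 0.9 (gentle brightening).
#' @param levels Number of intensity levels L for histogram operators.
#'   Default 256.
#' @param unsharp_k Unsharp-masking gain k (>= 0). Default 1.
#' @param unsharp_sigma Gaussian sigma (pixels) of the unsharp blur. Default 1.
#' @param clahe_clip CLAHE clip limit as a multiple of the mean per-bin tile
#'   count (> 0). Default 2.
#' @param clahe_tiles Tile grid as `c(rows, cols)`. Default `c(8, 8)`.
#' @param stage_order Character vector of stages applied by
#'   [enhance_pipeline()], a subset/permutation of
#'   `c("crop", "retinex", "gamma", "hist_eq", "unsharp", "clahe")`.
#' @param crop_box Optional crop region `c(row_min, col_min, row_max,
#'   col_max)` (1-based, inclusive); `NULL` skips cropping.
#'
#' @return An object of class `enhance_config`.
#' @export
enhance_config <- function(retinex_scales = NULL, retinex_weights = NULL,
                           log_epsilon = 1 / 255, gamma = 0.9, levels = 256,
                           unsharp_k = 1, unsharp_sigma = 1,
                           clahe_clip = 2, clahe_tiles = c(8, 8),
                           stage_order = c("crop", "retinex", "gamma",
                                           "hist_eq", "unsharp", "clahe"),
                           crop_box = NULL) {
  if (!is.null(retinex_scales)) {
    ll_assert(all(retinex_scales > 0), "retinex scales must be > 0")
    if (is.null(retinex_weights)) {
      retinex_weights <- rep(1 / length(retinex_scales),
                             length(retinex_scales))
    }
    ll_assert(length(retinex_weights) == length(retinex_scales),
              "retinex scales and weights must have equal length",
              "lesionlab_bad_retinex")
    ll_assert(abs(sum(retinex_weights) - 1) < 1e-8,
              "retinex weights must sum to 1")
  }
  ll_assert(log_epsilon > 0, "`log_epsilon` must be > 0")
  ll_assert(gamma > 0, "`gamma` must be > 0", "lesionlab_bad_gamma")
  ll_assert(levels >= 2, "`levels` must be at least 2")
  ll_assert(unsharp_k >= 0, "`unsharp_k` must be >= 0")
  ll_assert(unsharp_sigma > 0, "`unsharp_sigma` must be > 0")
  ll_assert(clahe_clip > 0, "`clahe_clip` must be > 0")
  ll_assert(length(clahe_tiles) == 2 && all(clahe_tiles >= 1),
            "`clahe_tiles` must be c(rows, cols) >= 1")
  known <- c("crop", "retinex", "gamma", "hist_eq", "unsharp", "clahe")
  bad <- setdiff(stage_order, known)
  ll_assert(length(bad) == 0,
            paste("unknown stage(s):", paste(bad, collapse = ", ")),
            "lesionlab_unknown_stage")
  structure(
    list(retinex_scales = retinex_scales, retinex_weights = retinex_weights,
         log_epsilon = log_epsilon, gamma = gamma, levels = as.integer(levels),
         unsharp_k = unsharp_k, unsharp_sigma = unsharp_sigma,
         clahe_clip = clahe_clip, clahe_tiles = as.integer(clahe_tiles),
         stage_order = stage_order, crop_box = crop_box),
    class = "enhance_config"
  )
}

# Classic contrast-limited histogram clipping: excess above the limit is
# redistributed uniformly (integer average increment with an upper
# threshold, then a striding pass over the bins still below the limit).
clip_histogram <- function(h, clim) {
  n_ex <- sum(pmax(h - clim, 0))
  if (n_ex <= 0) return(h)
  h <- pmin(h, clim)
  bin_incr <- n_ex %/% length(h)
  upper <- clim - bin_incr
  low <- h < upper
  n_ex <- n_ex - sum(low) * bin_incr
  h[low] <- h[low] + bin_incr
  mid <- h >= upper & h < clim
  n_ex <- n_ex + sum(h[mid]) - sum(mid) * clim
  h[mid] <- clim
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

resolve_retinex <- function(cfg, image_size) {
  scales <- cfg$retinex_scales
  if (is.null(scales)) scales <- c(15, 80, 250) * image_size / 256
  weights <- cfg$retinex_weights
  if (is.null(weights)) weights <- rep(1 / length(scales), length(scales))
  ll_assert(length(weights) == length(scales),
            "retinex scales and weights must have equal length",
            "lesionlab_bad_retinex")
  list(scales = scales, weights = weights)
}

#' Multi-scale retinex
#'
#' Per channel and per scale s computes the log ratio of the image to its
#' Gaussian surround, `R_s = log(I + eps) - log(G_s * I + eps)`, sums the
#' scales with their weights, and (by default) min-max rescales the result
#' to \[0, 1\].
#'
#' @param img Image in \[0, 1\].
#' @param cfg An [enhance_config()].
#' @param rescale If `FALSE`, return the raw weighted log-ratio sum without
#'   the final min-max normalization (useful for numeric checks).
#' @return Enhanced image (same shape).
#' @export
multiscale_retinex <- function(img, cfg = enhance_config(), rescale = TRUE) {
  a <- as_image(img)
  rx <- resolve_retinex(cfg, max(dim(a)[1:2]))
  eps <- cfg$log_epsilon
  out <- array(0, dim = dim(a))
  for (si in seq_along(rx$scales)) {
    for (c in seq_len(dim(a)[3L])) {
      blur <- gaussian_blur(a[, , c], rx$scales[si])
      out[, , c] <- out[, , c] +
        rx$weights[si] * (log(a[, , c] + eps) - log(blur + eps))
    }
  }
  if (rescale) out <- array(rescale01(out), dim = dim(out))
  like_image(out, img)
}

#' Gamma correction
#'
#' Power-law mapping `O = I^gamma` on normalized intensities.
#'
#' @param img Image in \[0, 1\].
#' @param gamma Exponent (> 0).
#' @return Corrected image.
#' @export
gamma_correct <- function(img, gamma) {
  ll_assert(is.numeric(gamma) && length(gamma) == 1 && gamma > 0,
            "`gamma` must be a single value > 0", "lesionlab_bad_gamma")
  a <- as_image(img)
  like_image(clamp01(a)^gamma, img)
}

# Quantize [0,1] intensities to integer levels 0..L-1 (half-up).
quantize_levels <- function(x, levels) {
  as.integer(round_half_up(clamp01(x) * (levels - 1)))
}

# Global histogram-equalization transfer function on integer levels:
# T(v) = round((L-1) * cdf(v)), half-up. Returns the mapped level vector.
he_transfer <- function(v, levels) {
  n <- tabulate(v + 1L, nbins = levels)
  cdf <- cumsum(n) / length(v)
  round_half_up((levels - 1) * cdf)
}

# Apply a new luminance to a color image preserving chrominance ratios.
apply_luminance <- function(img, y_old, y_new) {
  a <- as_image(img)
  if (dim(a)[3L] == 1L) return(like_image(y_new, img))
  ratio <- y_new / pmax(y_old, 1e-8)
  for (c in seq_len(dim(a)[3L])) a[, , c] <- a[, , c] * ratio
  like_image(clamp01(a), img)
}

#' Histogram equalization
#'
#' Maps each quantized intensity through the scaled cumulative distribution
#' function, `v -> round((L-1)/(M N) * sum_{i<=v} n_i)` (half-up rounding),
#' then renormalizes to \[0, 1\]. Color images are equalized on the ITU-R 601
#' luminance with chrominance preserved; a constant image is returned
#' unchanged (degenerate-histogram convention).
#'
#' @param img Image in \[0, 1\].
#' @param levels Number of intensity levels L (>= 2). Default 256.
#' @return Equalized image.
#' @export
hist_equalize <- function(img, levels = 256) {
  ll_assert(levels >= 2, "`levels` must be at least 2")
  a <- as_image(img)
  y <- luminance(a)
  v <- quantize_levels(y, levels)
  if (diff(range(v)) == 0) return(img)
  Tmap <- he_transfer(as.vector(v), levels)
  y_new <- matrix(Tmap[v + 1L] / (levels - 1), nrow(y), ncol(y))
  apply_luminance(img, y, y_new)
}

#' Unsharp masking
#'
#' Edge enhancement `O = clip(I + k (I - G_sigma * I), 0, 1)` applied per
#' channel with a reflect-padded Gaussian blur.
#'
#' @param img Image in \[0, 1\].
#' @param cfg An [enhance_config()] (uses `unsharp_k`, `unsharp_sigma`).
#' @return Sharpened image.
#' @export
unsharp_mask <- function(img, cfg = enhance_config()) {
  a <- as_image(img)
  out <- a
  if (cfg$unsharp_k > 0) {
    blur <- as_image(gaussian_blur(a, cfg$unsharp_sigma))
    out <- clamp01(a + cfg$unsharp_k * (a - blur))
  }
  like_image(out, img)
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Classic tiled equalization: the image (its luminance for color inputs) is
#' divided into a grid of tiles; each tile's histogram is clipped at
#' `clahe_clip` times the mean bin count with the excess redistributed
#' uniformly; each pixel is mapped by bilinear interpolation between the
#' scaled-CDF mappings of the four neighboring tiles (clamped at borders).
#' With a single tile and a clip limit of at least the tile pixel count this
#' reduces exactly to [hist_equalize()]. Constant images are returned
#' unchanged.
#'
#' @param img Image in \[0, 1\].
#' @param cfg An [enhance_config()] (uses `clahe_clip`, `clahe_tiles`,
#'   `levels`).
#' @return Equalized image.
#' @export
clahe <- function(img, cfg = enhance_config()) {
  a <- as_image(img)
  H <- dim(a)[1L]; W <- dim(a)[2L]
  tr <- cfg$clahe_tiles[1L]; tc <- cfg$clahe_tiles[2L]
  ll_assert(tr <= H && tc <= W, "tile grid larger than image",
            "lesionlab_bad_tiles")
  L <- cfg$levels
  y <- luminance(a)
  v <- matrix(quantize_levels(y, L), H, W)
  if (diff(range(v)) == 0) return(img)

  th <- ceiling(H / tr); tw <- ceiling(W / tc)
  Hp <- th * tr; Wp <- tw * tc
  vp <- v[reflect_index(seq_len(Hp), H), reflect_index(seq_len(Wp), W)]

  # per-tile clipped-histogram mappings: continuous (L-1)*cdf, rounded later
  maps <- array(0, dim = c(tr, tc, L))
  limit <- max(1, floor(cfg$clahe_clip * th * tw / L))
  for (i in seq_len(tr)) {
    for (j in seq_len(tc)) {
      tile <- vp[((i - 1L) * th + 1L):(i * th), ((j - 1L) * tw + 1L):(j * tw)]
      h <- clip_histogram(tabulate(tile + 1L, nbins = L), limit)
      maps[i, j, ] <- (L - 1) * cumsum(h) / sum(h)
    }
  }

  # bilinear interpolation between the four neighboring tile mappings,
  # block-anchored as in the classic algorithm (border blocks duplicate
  # the edge mapping)
  pos_r <- (seq_len(H) - 1) / th + 0.5
  r1 <- floor(pos_r)
  wr <- pos_r - r1
  wr[r1 < 1] <- 0; wr[r1 >= tr] <- 0
  r1 <- clamp(r1, 1, tr); r2 <- clamp(r1 + 1, 1, tr)
  pos_c <- (seq_len(W) - 1) / tw + 0.5
  c1 <- floor(pos_c)
  wc <- pos_c - c1
  wc[c1 < 1] <- 0; wc[c1 >= tc] <- 0
  c1 <- clamp(c1, 1, tc); c2 <- clamp(c1 + 1, 1, tc)

  R1 <- matrix(r1, H, W); R2 <- matrix(r2, H, W)
  C1 <- matrix(c1, H, W, byrow = TRUE); C2 <- matrix(c2, H, W, byrow = TRUE)
  WR <- matrix(wr, H, W); WC <- matrix(wc, H, W, byrow = TRUE)
  Vl <- as.vector(v) + 1L
  g <- function(Rm, Cm) maps[cbind(as.vector(Rm), as.vector(Cm), Vl)]
  out_v <- (1 - WR) * (1 - WC) * g(R1, C1) + (1 - WR) * WC * g(R1, C2) +
    WR * (1 - WC) * g(R2, C1) + WR * WC * g(R2, C2)
  y_new <- matrix(round_half_up(out_v) / (L - 1), H, W)
  apply_luminance(img, y, y_new)
}

#' Crop a rectangular region
#'
#' @param img Image.
#' @param box Integer vector `c(row_min, col_min, row_max, col_max)`,
#'   1-based inclusive, within image bounds.
#' @return The sub-image copy.
#' @export
crop_region <- function(img, box) {
  a <- as_image(img)
  ll_assert(length(box) == 4, "`box` must be c(row_min, col_min, row_max, col_max)")
  ll_assert(box[1] >= 1 && box[2] >= 1 && box[3] <= dim(a)[1L] &&
              box[4] <= dim(a)[2L] && box[1] <= box[3] && box[2] <= box[4],
            "crop box out of bounds", "lesionlab_bad_box")
  out <- a[box[1]:box[3], box[2]:box[4], , drop = FALSE]
  if (is.matrix(img)) out <- out[, , 1L]
  out
}

#' Composed enhancement pipeline
#'
#' Applies the configured stages in `cfg$stage_order` (default: crop,
#' retinex, gamma correction, histogram equalization, unsharp masking,
#' CLAHE). Stages absent from `stage_order` are skipped; `crop` is skipped
#' when `crop_box` is `NULL`.
#'
#' @param img Image in \[0, 1\].
#' @param cfg An [enhance_config()].
#' @return Enhanced image in \[0, 1\].
#' @export
enhance_pipeline <- function(img, cfg = enhance_config()) {
  out <- img
  for (stage in cfg$stage_order) {
    out <- switch(
      stage,
      crop = if (is.null(cfg$crop_box)) out else crop_region(out, cfg$crop_box),
      retinex = multiscale_retinex(out, cfg),
      gamma = gamma_correct(out, cfg$gamma),
      hist_eq = hist_equalize(out, cfg$levels),
      unsharp = unsharp_mask(out, cfg),
      clahe = clahe(out, cfg),
      ll_stop(sprintf("unknown stage: %s", stage), "lesionlab_unknown_stage")
    )
  }
  out
}

# Enhance every image in a dataset (geometry-preserving stages only are
# assumed when sizes must stay aligned; crop changes sizes consistently).
enhance_dataset <- function(ds, cfg = enhance_config()) {
  ds$images <- lapply(ds$images, enhance_pipeline, cfg = cfg)
  ds$image_size <- dim(as_image(ds$images[[1L]]))[1L]
  ds
}
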