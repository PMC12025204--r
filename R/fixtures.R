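#' Specification for synthetic lesion-image fixtures
#'
#' Defines the study conditions for the synthetic dermoscopy-like images the
#' package can generate: per-class lesion geometry (radius, border
#' irregularity), lesion/background contrast and pigment texture, plus global
#' background noise. The default seven classes mirror the 0-6 severity coding
#' used for pigmented-lesion taxonomies (actinic keratosis through squamous
#' cell carcinoma); class separability is carried mostly by lesion size,
#' contrast and texture so that geometry survives intensity normalization.
#'
#' @param image_size Side length in pixels (square images). Default 64, the
#'   desk-scale size used throughout the tests; 256 is available for
#'   full-scale runs.
#' @param n_classes Number of lesion classes (>= 2). Default 7.
#' @param class_params Optional data frame with one row per class and columns
#'   `name`, `radius_frac` (lesion radius as a fraction of image size, in
#'   (0, 0.5]), `border_amp` (relative amplitude of the sinusoidal border
#'   perturbation), `contrast` (lesion/background luminance contrast in
#'   \[0, 1\]), `texture_sd` (relative pigment-texture standard deviation).
#'   Defaults interpolate across classes from small/faint to large/dark.
#' @param background_noise_sd Standard deviation of the additive Gaussian
#'   background noise, in intensity units. Default 0.02.
#' @param seed Integer seed stored with the spec (used when a caller does not
#'   pass an explicit one).
#'
#' @return An object of class `fixture_spec`.
#' @export
#' @examples
#' spec <- fixture_spec(image_size = 32, n_classes = 3)
#' img <- make_lesion_image(spec, class_id = 2, seed = 1)
#' dim(img$image)
fixture_spec <- function(image_size = 64, n_classes = 7, class_params = NULL,
                         background_noise_sd = 0.02, seed = 1) {
  ll_assert(image_size >= 8, "`image_size` must be at least 8")
  ll_assert(n_classes >= 2, "`n_classes` must be at least 2")
  ll_assert(background_noise_sd >= 0, "`background_noise_sd` must be >= 0")
  if (is.null(class_params)) {
    class_params <- default_class_params(n_classes)
  }
  ll_assert(nrow(class_params) == n_classes,
            "`class_params` must have one row per class")
  needed <- c("name", "radius_frac", "border_amp", "contrast", "texture_sd")
  ll_assert(all(needed %in% names(class_params)),
            paste("`class_params` must contain columns:",
                  paste(needed, collapse = ", ")))
  ll_assert(all(class_params$contrast >= 0 & class_params$contrast <= 1),
            "contrasts must lie in [0, 1]")
  ll_assert(all(class_params$radius_frac > 0 & class_params$radius_frac <= 0.5),
            "radius fractions must lie in (0, 0.5]")
  structure(
    list(image_size = as.integer(image_size),
         n_classes = as.integer(n_classes),
         class_params = tibble::as_tibble(class_params),
         background_noise_sd = background_noise_sd,
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

# Severity-coded default taxonomy (7 classes); other counts get generic
# names with parameters interpolated over the same ranges.
default_class_params <- function(n_classes) {
  severity_names <- c("actinic_keratosis", "basal_cell_carcinoma",
                      "benign_keratosis", "dermatofibroma",
                      "melanocytic_nevus", "melanoma",
                      "squamous_cell_carcinoma")
  names <- if (n_classes == 7L) {
    paste0(0:6, "_", severity_names)
  } else {
    sprintf("%d_class_%d", seq_len(n_classes) - 1L, seq_len(n_classes) - 1L)
  }
  tibble::tibble(
    name = names,
    radius_frac = seq(0.12, 0.42, length.out = n_classes),
    border_amp = seq(0.02, 0.12, length.out = n_classes),
    contrast = seq(0.20, 0.55, length.out = n_classes),
    texture_sd = seq(0.05, 0.30, length.out = n_classes)
  )
}

# Lesion tint multipliers chosen so the ITU-R 601 luminance drop equals the
# configured contrast exactly (0.299*0.95 + 0.587*1 + 0.114*t_b = 1); the
# spread is kept small so high-contrast lesions do not clip at zero.
lesion_tint <- c(0.95, 1, (1 - 0.299 * 0.95 - 0.587) / 0.114)

#' Generate one synthetic lesion image
#'
#' Draws a single RGB image containing one elliptical lesion with a
#' sinusoidally perturbed border on a smooth low-frequency background with
#' additive Gaussian noise. The lesion darkens the background by the class
#' contrast (in luminance units) and carries multiplicative pigment texture;
#' a class with contrast 0 is invisible. The same `(spec, class_id, seed)`
#' triple always returns a bit-identical image.
#'
#' @param spec A [fixture_spec()].
#' @param class_id Class label in `0:(n_classes - 1)`.
#' @param seed Integer seed.
#' @param center Optional lesion center as fractional `(x, y)` coordinates in
#'   (0, 1); default draws it uniformly from the central region. Useful for
#'   localization experiments that need the lesion confined to a quadrant.
#'
#' @return A list of class `lesion_image` with elements `image` (H x W x 3
#'   array in \[0, 1\]), `class_id`, `center` (fractional x, y), and
#'   `radius_frac`.
#' @export
make_lesion_image <- function(spec, class_id, seed, center = NULL) {
  ll_assert(inherits(spec, "fixture_spec"), "`spec` must be a fixture_spec")
  ll_assert(length(class_id) == 1 && class_id >= 0 && class_id < spec$n_classes,
            sprintf("`class_id` must be in 0..%d", spec$n_classes - 1L),
            "lesionlab_bad_class")
  p <- spec$class_params[class_id + 1L, ]
  s <- spec$image_size
  with_seed(seed, {
    # smooth low-frequency background field around a random base level;
    # bright enough that the darkest lesions stay clear of zero
    base <- runif(1, 0.78, 0.92)
    u <- (seq_len(s) - 0.5) / s
    field <- matrix(0, s, s)
    for (m in 1:3) {
      field <- field +
        runif(1, -1, 1) * outer(cos(pi * m * u + runif(1, 0, 2 * pi)),
                                cos(pi * m * u + runif(1, 0, 2 * pi)))
    }
    bg <- base + 0.04 * field / 3

    if (is.null(center)) center <- runif(2, 0.35, 0.65)
    cx <- center[1L] * s
    cy <- center[2L] * s
    r0 <- p$radius_frac * s
    aspect <- runif(1, 0.75, 1.25)
    theta0 <- runif(1, 0, pi)

    xs <- matrix(rep(seq_len(s) - 0.5, each = s), s, s)   # x = column coord
    ys <- matrix(rep(seq_len(s) - 0.5, times = s), s, s)  # y = row coord
    dx <- (xs - cx) * cos(theta0) + (ys - cy) * sin(theta0)
    dy <- -(xs - cx) * sin(theta0) + (ys - cy) * cos(theta0)
    d <- sqrt((dx / aspect)^2 + (dy * aspect)^2)
    ang <- atan2(dy, dx)

    # sinusoidal border perturbation, a few harmonics
    rb <- rep(1, length(ang))
    for (m in 2:4) {
      rb <- rb + p$border_amp * runif(1, 0.3, 1) *
        sin(m * ang + runif(1, 0, 2 * pi))
    }
    radius <- r0 * matrix(rb, s, s)
    # soft lesion mask with ~1 px transition (keeps statistics smooth)
    mask <- 1 / (1 + exp(-(radius - d) / 0.75))

    texture <- matrix(rnorm(s * s, 0, p$texture_sd), s, s)
    drop <- p$contrast * (1 + texture) * mask

    img <- array(0, dim = c(s, s, 3L))
    for (c in 1:3) {
      img[, , c] <- bg - lesion_tint[c] * drop +
        matrix(rnorm(s * s, 0, spec$background_noise_sd), s, s)
    }
    img <- clamp01(img)
    structure(list(image = img, class_id = as.integer(class_id),
                   center = center, radius_frac = p$radius_frac),
              class = "lesion_image")
  })
}

#' Generate a labeled synthetic dataset
#'
#' Draws `counts_per_class[k]` images for class `k - 1` and assembles them
#' into a [lesion_dataset]. When `dir` is given, the dataset is also written
#' as a class-per-subfolder PNG tree with a plain-text manifest (see
#' [write_dataset()]).
#'
#' @param spec A [fixture_spec()].
#' @param counts_per_class Integer vector of per-class image counts
#'   (length `n_classes`, non-negative, not all zero).
#' @param seed Integer seed; per-image seeds are derived from it.
#' @param dir Optional directory to write the dataset to.
#'
#' @return A `lesion_dataset`.
#' @export
make_dataset <- function(spec, counts_per_class, seed, dir = NULL) {
  ll_assert(inherits(spec, "fixture_spec"), "`spec` must be a fixture_spec")
  ll_assert(length(counts_per_class) == spec$n_classes,
            "`counts_per_class` must have one entry per class")
  ll_assert(all(counts_per_class >= 0), "counts must be non-negative")
  ll_assert(sum(counts_per_class) > 0, "all counts are zero",
            "lesionlab_empty_dataset")
  total <- sum(counts_per_class)
  seeds <- derive_seeds(seed, total)
  images <- vector("list", total)
  labels <- integer(total)
  centers <- matrix(NA_real_, total, 2L)
  i <- 0L
  for (k in seq_len(spec$n_classes)) {
    for (j in seq_len(counts_per_class[k])) {
      i <- i + 1L
      li <- make_lesion_image(spec, k - 1L, seeds[i])
      images[[i]] <- li$image
      labels[i] <- k - 1L
      centers[i, ] <- li$center
    }
  }
  ds <- new_lesion_dataset(
    images = images, labels = labels,
    class_names = spec$class_params$name,
    image_size = spec$image_size,
    metadata = tibble::tibble(
      item = seq_len(total), path = NA_character_,
      class_id = labels,
      class_name = spec$class_params$name[labels + 1L],
      center_x = centers[, 1L], center_y = centers[, 2L],
      synthetic = FALSE
    )
  )
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

#' Generate out-of-distribution anomaly images
#'
#' Draws high-frequency uniform-noise fields, a distribution disjoint from
#' the smooth lesion fixtures, for exercising reconstruction-error anomaly
#' detection.
#'
#' @param n Number of images (>= 1).
#' @param spec A [fixture_spec()] (size and channel conventions are reused).
#' @param seed Integer seed.
#'
#' @return List of H x W x 3 arrays with values in \[0, 1\].
#' @export
make_anomaly_images <- function(n, spec, seed) {
  ll_assert(inherits(spec, "fixture_spec"), "`spec` must be a fixture_spec")
  ll_assert(n >= 1, "`n` must be at least 1")
  s <- spec$image_size
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      array(runif(s * s * 3L), dim = c(s, s, 3L))
    })
  })
}
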