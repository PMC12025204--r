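# Self-contained benchmark experiments at desk scale. These are the runs the
# package's validation suite and the reproduction script both execute; each
# generates its own synthetic data, runs the relevant stage and returns the
# measured quantities.

#' Benchmark: end-to-end fixture classification
#'
#' Runs the full pipeline on the standard synthetic benchmark (7 severity
#' classes, 70 images each, 64 x 64 pixels, enhancement on, GAN off, 10
#' autoencoder epochs, polynomial kernel) and returns the pipeline report.
#'
#' @param seed Integer seed driving every stage.
#' @param permute_labels If `TRUE`, labels are randomly permuted first (the
#'   chance-level negative control).
#' @param epochs Autoencoder epochs. Default 10.
#' @return A `pipeline_report`.
#' @export
benchmark_pipeline <- function(seed = 1, permute_labels = FALSE, epochs = 10) {
  cfg <- pipeline_config(cae = list(epochs = epochs), seed = seed,
                         verbose = FALSE)
  run_pipeline(cfg, permute_labels = permute_labels)
}

#' Benchmark: GAN mean-image convergence over seeds
#'
#' Trains one GAN per seed on 8 x 8 single-class lesion fixtures and
#' measures the mean absolute per-pixel distance between the generator's
#' mean image (64 samples) and the data mean image.
#'
#' @param seed Base seed (training seeds derive from it).
#' @param n_seeds Number of independent training runs. Default 10.
#' @param steps Training steps per run. Default 500.
#' @return Tibble with one row per run: `run`, `l1_per_pixel`,
#'   `d_real_final`, `d_fake_final`.
#' @export
benchmark_gan <- function(seed = 1, n_seeds = 10, steps = 500) {
  spec <- fixture_spec(image_size = 8, n_classes = 2)
  ds <- make_dataset(spec, c(40, 0), seed = seed)
  dmean <- Reduce(`+`, ds$images) / length(ds$images)
  seeds <- derive_seeds(seed + 1L, n_seeds)
  rows <- lapply(seq_len(n_seeds), function(r) {
    cfg <- gan_config(image_size = 8, steps = steps, seed = seeds[r])
    st <- train_gan(ds, cfg)
    gen <- gan_generate(st, 64, seed = seeds[r] + 1L)
    tibble::tibble(
      run = r,
      l1_per_pixel = mean(abs(Reduce(`+`, gen) / length(gen) - dmean)),
      d_real_final = st$losses$d_real[steps],
      d_fake_final = st$losses$d_fake[steps]
    )
  })
  do.call(rbind, rows)
}

#' Benchmark: reconstruction-error anomaly detection
#'
#' Trains the autoencoder on 3-class lesion fixtures (32 x 32, 10 epochs),
#' scores 20 held-out fixtures and 20 high-frequency noise fields, and
#' flags anomalies at the mean + 2 sd threshold of the training errors.
#'
#' @param seed Integer seed.
#' @return List with `detection_rate`, `false_flag_rate`, `threshold`,
#'   `mean_error_train`, `mean_error_heldout`, `mean_error_anomaly`, and the
#'   trained `model`.
#' @export
benchmark_anomaly <- function(seed = 1) {
  seeds <- derive_seeds(seed, 4L)
  spec <- fixture_spec(image_size = 32, n_classes = 3)
  train <- make_dataset(spec, rep(30L, 3L), seed = seeds[1])
  heldout <- make_dataset(spec, rep(7L, 3L), seed = seeds[2])
  cfg <- ae_config(input_size = 32, n_classes = 3, epochs = 10,
                   batch_size = 32, seed = seeds[3])
  model <- train_cae(train, NULL, cfg)
  tr_err <- anomaly_scores(model, train)$error
  e_ho <- anomaly_scores(model, heldout$images[1:20])$error
  e_an <- anomaly_scores(model,
                         make_anomaly_images(20, spec, seed = seeds[4]))$error
  thr <- mean(tr_err) + 2 * sd(tr_err)
  list(detection_rate = mean(e_an > thr),
       false_flag_rate = mean(e_ho > thr),
       threshold = thr,
       mean_error_train = mean(tr_err),
       mean_error_heldout = mean(e_ho),
       mean_error_anomaly = mean(e_an),
       model = model)
}

# Quadrant centers (fractional x, y): top-left, top-right, bottom-left,
# bottom-right in image coordinates (x = columns, y = rows).
quadrant_centers <- list(c(0.25, 0.25), c(0.75, 0.25),
                         c(0.25, 0.75), c(0.75, 0.75))

# Two-class benign/malignant quadrant dataset: lesions small enough to stay
# inside their quadrant; the malignant class carries the positive evidence
# (dark, textured) that saliency can attribute to a location.
gradcam_quadrant_dataset <- function(n, seed0, spec) {
  imgs <- vector("list", n); labs <- integer(n); quads <- integer(n)
  for (i in seq_len(n)) {
    labs[i] <- (i - 1L) %% 2L
    quads[i] <- ((i - 1L) %/% 2L) %% 4L + 1L
    li <- make_lesion_image(spec, labs[i], seed0 + i,
                            center = quadrant_centers[[quads[i]]])
    imgs[[i]] <- li$image
  }
  list(ds = new_lesion_dataset(imgs, labs, spec$class_params$name, 32),
       quads = quads)
}

#' Benchmark: Grad-CAM lesion localization
#'
#' Trains a two-class benign/malignant classifier on 32 x 32 fixtures whose
#' lesions are confined to known image quadrants, then measures — on 20
#' correctly classified malignant validation images — the fraction of
#' heatmap mass falling inside the lesion's quadrant (chance level 0.25).
#' Localization is evaluated on the lesion-positive class because the
#' benign class's evidence is the absence of malignant features, which has
#' no location to attribute.
#'
#' @param seed Integer seed.
#' @param epochs Training epochs. Default 30.
#' @return List with `fractions` (per-image quadrant mass), `n_localized`
#'   (images with at least half their mass in the lesion quadrant),
#'   `n_images`, `accuracy` and the trained `model`.
#' @export
benchmark_gradcam <- function(seed = 1, epochs = 30) {
  seeds <- derive_seeds(seed, 3L)
  params <- tibble::tibble(
    name = c("benign", "malignant"),
    radius_frac = c(0.12, 0.17), border_amp = c(0.03, 0.06),
    contrast = c(0.25, 0.55), texture_sd = c(0.04, 0.25)
  )
  spec <- fixture_spec(image_size = 32, n_classes = 2, class_params = params)
  tr <- gradcam_quadrant_dataset(80, seeds[1], spec)
  va <- gradcam_quadrant_dataset(48, seeds[2], spec)
  cfg <- ae_config(input_size = 32, n_classes = 2, epochs = epochs,
                   batch_size = 16, seed = seeds[3])
  model <- train_cae(tr$ds, NULL, cfg)
  probs <- classify_proba(model, dataset_array(va$ds))
  pred <- max.col(probs, ties.method = "first") - 1L
  ok <- which(pred == va$ds$labels & va$ds$labels == 1L)
  ll_assert(length(ok) >= 20, "fewer than 20 correctly classified images")
  ok <- ok[seq_len(20)]
  fractions <- vapply(ok, function(i) {
    heatmap_quadrant_mass(gradcam(model, va$ds$images[[i]], pred[i]),
                          va$quads[i])
  }, numeric(1))
  list(fractions = fractions,
       n_localized = sum(fractions >= 0.5),
       n_images = length(ok),
       accuracy = mean(pred == va$ds$labels),
       model = model)
}
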