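#' Default pipeline configuration
#'
#' Nested configuration for the end-to-end flow: data source, enhancement,
#' optional GAN balancing, autoencoder training, kernel/classifier settings,
#' split and seeding. Defaults follow the conventional hyperparameter set
#' (learning rate 0.001, 50 epochs, batch 32, dropout 0.5, L2 0.01,
#' polynomial kernel of degree 3 with scale 1 and offset 0, 80/20 stratified
#' split).
#'
#' @param ... Named overrides merged (recursively) into the defaults, e.g.
#'   `pipeline_config(cae = list(epochs = 10), seed = 42)`.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  validate_config(list(...))
}

pipeline_defaults <- function() {
  list(
    dataset = list(
      source = "fixture",            # "fixture" or "folder"
      root = NULL,                   # folder source: dataset directory
      image_size = 64,
      n_classes = 7,
      counts_per_class = rep(70L, 7L)
    ),
    enhance = list(
      enable = TRUE, gamma = 0.9, levels = 256, unsharp_k = 1,
      unsharp_sigma = 1, clahe_clip = 2, clahe_tiles = c(8, 8),
      log_epsilon = 1 / 255, retinex_scales = NULL, retinex_weights = NULL,
      stage_order = c("retinex", "gamma", "hist_eq", "unsharp", "clahe")
    ),
    gan = list(
      enable = FALSE, latent_dim = 16, hidden = 64, lr_g = 2e-3,
      lr_d = 1e-3, batch_size = 16, steps = 500, non_saturating = FALSE
    ),
    cae = list(
      widths = c(32, 64), hidden = 64, learning_rate = 0.001, epochs = 50,
      batch_size = 32, l2_weight = 0.01, dropout = 0.5,
      recon_loss_weight = 1, class_loss_weight = 1
    ),
    svm = list(
      family = "polynomial", degree = 3, scale = 1.0, offset = 0.0,
      n_components = 8, repetitions = 2, angle_scale = 0.1, C = 1.0
    ),
    split = list(fraction = 0.8),
    seed = 1,
    out_dir = NULL,
    verbose = TRUE
  )
}

# Recursive merge with strict key checking.
merge_config <- function(defaults, user, path = "") {
  ll_assert(is.list(user), sprintf("config section '%s' must be a list", path))
  unknown <- setdiff(names(user), names(defaults))
  ll_assert(length(unknown) == 0,
            paste0("unknown config key(s): ",
                   paste0(path, unknown, collapse = ", ")),
            "lesionlab_unknown_key")
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], as.list(user[[nm]]),
                                     paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Validate a raw configuration tree
#'
#' Fills defaults, rejects unknown keys (every offending key is named), and
#' checks types/ranges of the core fields.
#'
#' @param raw A (possibly nested, possibly empty) named list, e.g. parsed
#'   from a YAML file.
#' @return A `pipeline_config`.
#' @export
validate_config <- function(raw = list()) {
  cfg <- merge_config(pipeline_defaults(), raw)
  bad <- character(0)
  chk <- function(ok, key) if (!isTRUE(ok)) bad <<- c(bad, key)
  chk(cfg$dataset$source %in% c("fixture", "folder"), "dataset.source")
  chk(cfg$dataset$image_size >= 8 && cfg$dataset$image_size %% 4 == 0,
      "dataset.image_size")
  chk(cfg$dataset$source != "fixture" ||
        length(cfg$dataset$counts_per_class) == cfg$dataset$n_classes,
      "dataset.counts_per_class")
  chk(cfg$split$fraction > 0 && cfg$split$fraction < 1, "split.fraction")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed")
  chk(cfg$cae$learning_rate > 0, "cae.learning_rate")
  chk(cfg$cae$epochs >= 0, "cae.epochs")
  chk(cfg$cae$dropout >= 0 && cfg$cae$dropout < 1, "cae.dropout")
  chk(cfg$svm$family %in% c("polynomial", "quantum_second_order"),
      "svm.family")
  chk(cfg$svm$C > 0, "svm.C")
  chk(cfg$svm$n_components >= 1, "svm.n_components")
  ll_assert(length(bad) == 0,
            paste("invalid config value(s) for:", paste(bad, collapse = ", ")),
            "lesionlab_bad_config")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with (a subset of) the configuration tree.
#' @return A validated `pipeline_config`.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

pipeline_log <- function(cfg, fmt, ...) {
  if (isTRUE(cfg$verbose)) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  }
}

#' Run the end-to-end classification pipeline
#'
#' Executes, in order: data loading or fixture generation, image
#' enhancement, optional GAN balancing of the training partition, the
#' stratified train/validation split, autoencoder training, latent
#' extraction, feature reduction, SVM fitting, validation prediction and
#' metric computation. All stage seeds derive deterministically from the
#' global seed, so re-running with the same configuration reproduces the
#' report exactly.
#'
#' @param cfg A [pipeline_config()] (or raw list, validated on entry).
#' @param permute_labels If `TRUE`, dataset labels are randomly permuted
#'   before the split — a negative control that should drive validation
#'   accuracy to chance level.
#' @return An object of class `pipeline_report`: list with `metrics`
#'   (a [metrics()] report), `confusion`, `predictions` tibble, `history`,
#'   `softmax_accuracy` (baseline from the autoencoder head), `model`,
#'   `svm`, `config` and `seeds`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), permute_labels = FALSE) {
  if (!inherits(cfg, "pipeline_config")) cfg <- validate_config(cfg)
  seeds <- derive_seeds(cfg$seed, 8L)
  names(seeds) <- c("fixture", "permute", "split", "gan", "cae",
                    "balance", "svm", "spare")

  pipeline_log(cfg, "stage 1/7: data (%s)", cfg$dataset$source)
  ds <- if (cfg$dataset$source == "fixture") {
    spec <- fixture_spec(image_size = cfg$dataset$image_size,
                         n_classes = cfg$dataset$n_classes,
                         seed = seeds["fixture"])
    make_dataset(spec, cfg$dataset$counts_per_class, seeds["fixture"])
  } else {
    raw <- load_folder_dataset(cfg$dataset$root)
    raw$images <- lapply(raw$images, resize_normalize,
                         size = cfg$dataset$image_size)
    raw$image_size <- cfg$dataset$image_size
    raw
  }

  if (permute_labels) {
    perm <- with_seed(seeds["permute"], sample(ds$labels))
    ds$labels <- perm
    ds$metadata$class_id <- perm
    ds$metadata$class_name <- ds$class_names[perm + 1L]
  }

  if (isTRUE(cfg$enhance$enable)) {
    pipeline_log(cfg, "stage 2/7: enhancement (%s)",
                 paste(cfg$enhance$stage_order, collapse = " > "))
    ecfg <- enhance_config(
      retinex_scales = cfg$enhance$retinex_scales,
      retinex_weights = cfg$enhance$retinex_weights,
      log_epsilon = cfg$enhance$log_epsilon, gamma = cfg$enhance$gamma,
      levels = cfg$enhance$levels, unsharp_k = cfg$enhance$unsharp_k,
      unsharp_sigma = cfg$enhance$unsharp_sigma,
      clahe_clip = cfg$enhance$clahe_clip,
      clahe_tiles = cfg$enhance$clahe_tiles,
      stage_order = cfg$enhance$stage_order
    )
    ds <- enhance_dataset(ds, ecfg)
  } else {
    pipeline_log(cfg, "stage 2/7: enhancement disabled")
  }

  pipeline_log(cfg, "stage 3/7: stratified split (fraction %.2f)",
               cfg$split$fraction)
  sp <- split_dataset(ds, cfg$split$fraction, seeds["split"])
  train <- sp$train

  if (isTRUE(cfg$gan$enable)) {
    pipeline_log(cfg, "stage 4/7: GAN balancing of the training partition")
    counts <- tabulate(train$labels + 1L, nbins = length(train$class_names))
    need <- which(counts < max(counts)) - 1L
    states <- list()
    gseeds <- derive_seeds(seeds["gan"], length(train$class_names))
    for (k in need) {
      gcfg <- gan_config(
        latent_dim = cfg$gan$latent_dim, image_size = train$image_size,
        channels = 3, hidden = cfg$gan$hidden, lr_g = cfg$gan$lr_g,
        lr_d = cfg$gan$lr_d, batch_size = cfg$gan$batch_size,
        steps = cfg$gan$steps, seed = gseeds[k + 1L],
        non_saturating = cfg$gan$non_saturating
      )
      states[[as.character(k)]] <-
        train_gan(subset_dataset(train, which(train$labels == k)), gcfg)
    }
    train <- balance_dataset(train, states, seeds["balance"])
  } else {
    pipeline_log(cfg, "stage 4/7: GAN balancing disabled")
  }

  pipeline_log(cfg, "stage 5/7: autoencoder training (%d epochs, lr %g)",
               cfg$cae$epochs, cfg$cae$learning_rate)
  acfg <- ae_config(
    input_size = ds$image_size, channels = 3, widths = cfg$cae$widths,
    hidden = cfg$cae$hidden, n_classes = length(ds$class_names),
    learning_rate = cfg$cae$learning_rate, epochs = cfg$cae$epochs,
    batch_size = cfg$cae$batch_size, l2_weight = cfg$cae$l2_weight,
    dropout = cfg$cae$dropout,
    recon_loss_weight = cfg$cae$recon_loss_weight,
    class_loss_weight = cfg$cae$class_loss_weight, seed = seeds["cae"]
  )
  model <- train_cae(train, sp$validation, acfg)

  pipeline_log(cfg, "stage 6/7: latent extraction and SVM (%s kernel)",
               cfg$svm$family)
  Z_train <- latent_features(model, train)
  Z_val <- latent_features(model, sp$validation)
  n_comp <- min(cfg$svm$n_components, ncol(Z_train))
  red <- reduce_features(Z_train, n_comp)
  spec <- kernel_spec(
    family = cfg$svm$family, degree = cfg$svm$degree, scale = cfg$svm$scale,
    offset = cfg$svm$offset, n_qubits = n_comp,
    repetitions = cfg$svm$repetitions, angle_scale = cfg$svm$angle_scale
  )
  svm <- fit_qsvm(red$features, train$labels, spec, C = cfg$svm$C,
                  projection = red$projection)
  pred <- predict(svm, project_features(red$projection, Z_val),
                  project = FALSE)

  pipeline_log(cfg, "stage 7/7: evaluation")
  cm <- confusion(sp$validation$labels, as.integer(pred),
                  K = length(ds$class_names))
  rep_metrics <- metrics(cm)
  probs <- classify_proba(model, dataset_array(sp$validation))
  softmax_acc <- mean(max.col(probs, ties.method = "first") - 1L ==
                        sp$validation$labels)
  report <- structure(
    list(metrics = rep_metrics, confusion = cm,
         predictions = tibble::tibble(
           item = seq_along(sp$validation$labels),
           truth = sp$validation$labels, predicted = as.integer(pred)
         ),
         history = model$history, softmax_accuracy = softmax_acc,
         model = model, svm = svm, config = cfg, seeds = seeds),
    class = "pipeline_report"
  )
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  pipeline_log(cfg, "done: validation accuracy %.4f (softmax baseline %.4f)",
               rep_metrics$accuracy, softmax_acc)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf(
    "<pipeline_report> validation accuracy %.4f (softmax head %.4f)\n",
    x$metrics$accuracy, x$softmax_accuracy))
  print(x$metrics)
  invisible(x)
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$predictions,
                   file.path(dir, "predictions.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$confusion),
                   file.path(dir, "confusion.csv"))
  if (nrow(report$history)) {
    utils::write.csv(report$history, file.path(dir, "history.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(accuracy = report$metrics$accuracy,
         macro = as.list(report$metrics$macro),
         softmax_accuracy = report$softmax_accuracy,
         seed = report$config$seed),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
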