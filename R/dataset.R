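#' Labeled image dataset
#'
#' An ordered collection of images with dense integer class labels
#' `0..K-1`, the container every pipeline stage consumes. Construct one with
#' [make_dataset()], [load_folder_dataset()] or [new_lesion_dataset()].
#'
#' @param images List of H x W x C arrays in \[0, 1\].
#' @param labels Integer vector of 0-based class indices, same length.
#' @param class_names Character vector of unique class names, length K.
#' @param image_size Side length in pixels.
#' @param metadata Optional tibble with one row per item (paths, lesion
#'   centers, synthetic flags); a minimal one is built when omitted.
#'
#' @return An object of class `lesion_dataset`.
#' @export
new_lesion_dataset <- function(images, labels, class_names, image_size,
                               metadata = NULL) {
  labels <- as.integer(labels)
  ll_assert(length(images) == length(labels),
            "`images` and `labels` must have the same length")
  ll_assert(!anyDuplicated(class_names), "class names must be unique")
  ll_assert(all(labels >= 0 & labels < length(class_names)),
            "labels must be dense 0-based class indices")
  if (is.null(metadata)) {
    metadata <- tibble::tibble(
      item = seq_along(images), path = NA_character_,
      class_id = labels, class_name = class_names[labels + 1L],
      center_x = NA_real_, center_y = NA_real_, synthetic = FALSE
    )
  }
  structure(
    list(images = images, labels = labels,
         class_names = as.character(class_names),
         image_size = as.integer(image_size), metadata = metadata),
    class = "lesion_dataset"
  )
}

#' @export
print.lesion_dataset <- function(x, ...) {
  cat(sprintf("<lesion_dataset> %d images, %d classes, %dx%d px\n",
              length(x$images), length(x$class_names),
              x$image_size, x$image_size))
  counts <- tabulate(x$labels + 1L, nbins = length(x$class_names))
  for (k in seq_along(x$class_names)) {
    cat(sprintf("  [%d] %-28s %d\n", k - 1L, x$class_names[k], counts[k]))
  }
  invisible(x)
}

#' @export
length.lesion_dataset <- function(x) length(x$images)

# Subset a dataset keeping labels/metadata aligned; class set unchanged.
subset_dataset <- function(ds, idx) {
  new_lesion_dataset(
    images = ds$images[idx], labels = ds$labels[idx],
    class_names = ds$class_names, image_size = ds$image_size,
    metadata = ds$metadata[idx, , drop = FALSE]
  )
}

#' Write a dataset as a class-per-subfolder PNG tree
#'
#' Creates `root/<class_name>/img_<k>.png` for every item plus a plain-text
#' manifest (`manifest.txt`, one line per image: relative path, class id,
#' lesion center x, y).
#'
#' @param ds A `lesion_dataset`.
#' @param root Output directory (created if missing).
#' @return Invisibly, the manifest as a tibble.
#' @export
write_dataset <- function(ds, root) {
  ll_assert(inherits(ds, "lesion_dataset"), "`ds` must be a lesion_dataset")
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  per_class_counter <- integer(length(ds$class_names))
  rows <- vector("list", length(ds$images))
  for (i in seq_along(ds$images)) {
    k <- ds$labels[i] + 1L
    per_class_counter[k] <- per_class_counter[k] + 1L
    cls_dir <- file.path(root, ds$class_names[k])
    dir.create(cls_dir, showWarnings = FALSE)
    rel <- file.path(ds$class_names[k],
                     sprintf("img_%04d.png", per_class_counter[k]))
    png::writePNG(clamp01(ds$images[[i]]), file.path(root, rel))
    cx <- ds$metadata$center_x[i]
    cy <- ds$metadata$center_y[i]
    rows[[i]] <- sprintf("%s\t%d\t%s\t%s", rel, ds$labels[i],
                         format(cx, digits = 8), format(cy, digits = 8))
  }
  writeLines(unlist(rows), file.path(root, "manifest.txt"))
  invisible(ds$metadata)
}

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      ll_stop("JPEG decoding requires the EBImage package",
              "lesionlab_undecodable")
    }
    a <- EBImage::imageData(EBImage::readImage(path))
    if (length(dim(a)) == 3L) aperm(a, c(2L, 1L, 3L)) else t(a)
  } else {
    ll_stop(sprintf("unsupported image format: %s", path),
            "lesionlab_undecodable")
  }
  a <- as_image(img)
  if (dim(a)[3L] >= 4L) a <- a[, , 1:3, drop = FALSE]     # drop alpha
  if (dim(a)[3L] == 1L) a <- array(rep(a, 3L), dim = c(dim(a)[1:2], 3L))
  a
}

#' Load a class-per-subfolder image dataset
#'
#' Reads every decodable JPEG/PNG under `root/<class>/`, assigning dense
#' 0-based labels by lexicographic subfolder order (so severity-coded names
#' such as `5_melanoma` map to their severity index).
#'
#' @param root Dataset directory containing one subfolder per class.
#' @param permissive If `TRUE`, undecodable files are reported with a warning
#'   and skipped; otherwise they raise an error.
#'
#' @return A [lesion_dataset].
#' @export
load_folder_dataset <- function(root, permissive = FALSE) {
  ll_assert(dir.exists(root), sprintf("directory not found: %s", root),
            "lesionlab_empty_root")
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  classes <- classes[vapply(classes, function(cl) {
    length(list.files(file.path(root, cl))) > 0
  }, logical(1))]
  ll_assert(length(classes) > 0, "no class subfolders with files found",
            "lesionlab_empty_root")
  images <- list(); labels <- integer(); paths <- character()
  for (k in seq_along(classes)) {
    files <- sort(list.files(file.path(root, classes[k]),
                             pattern = "\\.(png|jpg|jpeg)$",
                             ignore.case = TRUE, full.names = TRUE))
    for (f in files) {
      img <- tryCatch(read_image_file(f), error = function(e) e)
      if (inherits(img, "error")) {
        if (permissive) {
          warning(sprintf("skipping undecodable file: %s", f))
          next
        }
        ll_stop(sprintf("undecodable image: %s", f), "lesionlab_undecodable")
      }
      images[[length(images) + 1L]] <- img
      labels <- c(labels, k - 1L)
      paths <- c(paths, f)
    }
  }
  ll_assert(length(images) > 0, "no decodable images found",
            "lesionlab_empty_root")
  size <- dim(images[[1L]])[1L]
  new_lesion_dataset(
    images = images, labels = labels, class_names = classes,
    image_size = size,
    metadata = tibble::tibble(
      item = seq_along(images), path = paths, class_id = labels,
      class_name = classes[labels + 1L],
      center_x = NA_real_, center_y = NA_real_, synthetic = FALSE
    )
  )
}

#' Resize an image and normalize intensities to \[0, 1\]
#'
#' Bilinear resampling (pixel-center convention) to `size` x `size`;
#' integer-coded inputs (values above 1) are rescaled by 1/255 first.
#'
#' @param img Image matrix or H x W x C array.
#' @param size Output side length in pixels (>= 8).
#' @return Resized image with values in \[0, 1\], same channel count.
#' @export
resize_normalize <- function(img, size) {
  ll_assert(is_image(img), "`img` must be a numeric image",
            "lesionlab_not_image")
  ll_assert(size >= 8, "`size` must be at least 8")
  a <- as_image(img)
  if (max(a) > 1 + 1e-9) a <- a / 255
  a <- clamp01(a)
  out <- bilinear_resize(a, size, size)
  if (is.matrix(img)) out <- matrix(out, size, size)
  out
}

#' Stratified train/validation split
#'
#' Splits a dataset into train and validation partitions with per-class
#' train fractions within one item of the global `train_fraction`; the same
#' seed always reproduces the same membership.
#'
#' @param ds A [lesion_dataset] with at least 2 items per class.
#' @param train_fraction Proportion of each class assigned to training,
#'   in (0, 1). Default 0.8 (the conventional 80/20 split).
#' @param seed Integer seed controlling the shuffle.
#'
#' @return An object of class `split_result`: list with `train`,
#'   `validation` (both `lesion_dataset`), `seed`, `train_fraction`.
#' @export
split_dataset <- function(ds, train_fraction = 0.8, seed = 1) {
  ll_assert(inherits(ds, "lesion_dataset"), "`ds` must be a lesion_dataset")
  ll_assert(train_fraction > 0 && train_fraction < 1,
            "`train_fraction` must lie in (0, 1)",
            "lesionlab_bad_fraction")
  present <- sort(unique(ds$labels))
  counts <- tabulate(ds$labels + 1L, nbins = length(ds$class_names))
  ll_assert(all(counts[present + 1L] >= 2),
            "every class needs at least 2 items for a stratified split")
  train_idx <- integer(0)
  with_seed(seed, {
    for (k in present) {
      idx <- which(ds$labels == k)
      n_train <- min(max(1L, round_half_up(train_fraction * length(idx))),
                     length(idx) - 1L)
      train_idx <- c(train_idx, sample(idx)[seq_len(n_train)])
    }
  })
  train_idx <- sort(train_idx)
  val_idx <- setdiff(seq_along(ds$images), train_idx)
  structure(
    list(train = subset_dataset(ds, train_idx),
         validation = subset_dataset(ds, val_idx),
         seed = as.integer(seed), train_fraction = train_fraction),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> %d train / %d validation (fraction %.2f, seed %d)\n",
              length(x$train$images), length(x$validation$images),
              x$train_fraction, x$seed))
  invisible(x)
}

# Stack a dataset (or list of images) into an H x W x C x N array.
dataset_array <- function(x) {
  imgs <- if (inherits(x, "lesion_dataset")) x$images else x
  d <- dim(as_image(imgs[[1L]]))
  out <- array(0, dim = c(d, length(imgs)))
  for (i in seq_along(imgs)) out[, , , i] <- as_image(imgs[[i]])
  out
}
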