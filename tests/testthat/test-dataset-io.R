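test_that("folder datasets load with lexicographic class order", {
  root <- withr::local_tempdir()
  for (cl in c("melanoma", "benign")) {
    dir.create(file.path(root, cl))
  }
  set.seed(1)
  for (k in 1:3) {
    png::writePNG(array(runif(8 * 8 * 3), dim = c(8, 8, 3)),
                  file.path(root, "benign", sprintf("b%d.png", k)))
  }
  for (k in 1:2) {
    png::writePNG(array(runif(8 * 8 * 3), dim = c(8, 8, 3)),
                  file.path(root, "melanoma", sprintf("m%d.png", k)))
  }
  ds <- load_folder_dataset(root)
  expect_length(ds$images, 5)
  expect_equal(ds$class_names, c("benign", "melanoma"))
  expect_equal(ds$labels, c(0L, 0L, 0L, 1L, 1L))
  expect_error(load_folder_dataset(file.path(root, "missing")),
               class = "lesionlab_empty_root")
})

test_that("severity-coded folder names map melanoma to index 5", {
  spec <- fixture_spec(image_size = 16, n_classes = 7)
  root <- withr::local_tempdir()
  ds <- make_dataset(spec, rep(2L, 7L), seed = 2, dir = root)
  reloaded <- load_folder_dataset(root)
  expect_equal(reloaded$class_names[6], "5_melanoma")
  expect_equal(reloaded$class_names,
               sort(spec$class_params$name))
  expect_equal(tabulate(reloaded$labels + 1, 7), rep(2L, 7L))
  # written-then-reloaded images match up to 8-bit quantization
  expect_lt(max(abs(reloaded$images[[1]] - ds$images[[1]])), 1 / 255)
  # manifest exists with one line per image
  expect_length(readLines(file.path(root, "manifest.txt")), 14)
})

test_that("resize_normalize rescales and matches the bilinear oracle", {
  const <- matrix(0.37, 20, 20)
  expect_equal(resize_normalize(const, 12), matrix(0.37, 12, 12))
  # integer-coded input is brought to [0, 1] without geometric change
  ints <- matrix(seq(0, 255, length.out = 64), 8, 8)
  out <- resize_normalize(ints, 8)
  expect_equal(out, ints / 255, tolerance = 1e-12)
  # checkerboard downsample vs naive oracle
  chk <- outer(1:64, 1:64, function(i, j) (floor((i - 1) / 8) +
                                             floor((j - 1) / 8)) %% 2)
  got <- resize_normalize(chk, 32)
  expect_lt(max(abs(got - oracle_bilinear_resize(chk, 32, 32))), 1e-6)
  expect_error(resize_normalize("x", 16), class = "lesionlab_not_image")
})

test_that("stratified split honors fractions, seeds and partitioning", {
  spec <- fixture_spec(image_size = 16, n_classes = 2)
  ds <- make_dataset(spec, c(5, 5), seed = 5)
  sp <- split_dataset(ds, 0.8, seed = 11)
  expect_length(sp$train$images, 8)
  expect_length(sp$validation$images, 2)
  expect_equal(tabulate(sp$train$labels + 1, 2), c(4L, 4L))
  expect_equal(tabulate(sp$validation$labels + 1, 2), c(1L, 1L))
  sp2 <- split_dataset(ds, 0.8, seed = 11)
  expect_identical(sp$train$metadata$item, sp2$train$metadata$item)
  expect_error(split_dataset(ds, 1.2, seed = 1),
               class = "lesionlab_bad_fraction")
})

test_that("per-class train fractions stay within one item of the target", {
  spec <- fixture_spec(image_size = 16, n_classes = 7)
  counts <- c(150, 180, 120, 160, 140, 130, 120)
  ds <- make_dataset(spec, counts, seed = 8)
  sp <- split_dataset(ds, 0.8, seed = 21)
  for (k in 0:6) {
    n_tr <- sum(sp$train$labels == k)
    expect_lt(abs(n_tr - 0.8 * counts[k + 1]), 1 + 1e-9)
  }
  # partition property over random sizes and seeds
  for (seed in 1:5) {
    set.seed(seed)
    cts <- sample(3:20, 3)
    spec3 <- fixture_spec(image_size = 16, n_classes = 3)
    d <- make_dataset(spec3, cts, seed = seed)
    s <- split_dataset(d, 0.7, seed = seed)
    ids <- c(s$train$metadata$item, s$validation$metadata$item)
    expect_setequal(ids, seq_len(sum(cts)))
    expect_equal(anyDuplicated(ids), 0L)
  }
})
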