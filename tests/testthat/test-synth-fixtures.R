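test_that("lesion images are deterministic, bounded and labeled", {
  spec <- fixture_spec(image_size = 32, n_classes = 3)
  a <- make_lesion_image(spec, 1, seed = 7)
  b <- make_lesion_image(spec, 1, seed = 7)
  expect_identical(a$image, b$image)
  expect_true(all(a$image >= 0 & a$image <= 1))
  expect_equal(dim(a$image), c(32L, 32L, 3L))
  expect_equal(a$class_id, 1L)
  expect_true(all(a$center > 0 & a$center < 1))
  d <- make_lesion_image(spec, 1, seed = 8)
  expect_false(identical(a$image, d$image))
  expect_error(make_lesion_image(spec, 5, seed = 1), class = "lesionlab_bad_class")
})

test_that("zero contrast renders the lesion invisible", {
  params <- tibble::tibble(
    name = c("flat", "dark"), radius_frac = c(0.2, 0.2),
    border_amp = c(0.05, 0.05), contrast = c(0, 0.5),
    texture_sd = c(0.1, 0.1)
  )
  spec <- fixture_spec(image_size = 32, n_classes = 2, class_params = params)
  # inner-lesion minus background-ring luminance difference, per image
  region_diff <- function(li) {
    s <- 32
    y <- 0.299 * li$image[, , 1] + 0.587 * li$image[, , 2] +
      0.114 * li$image[, , 3]
    cx <- li$center[1] * s; cy <- li$center[2] * s
    xs <- matrix(rep(seq_len(s) - 0.5, each = s), s, s)
    ys <- matrix(rep(seq_len(s) - 0.5, times = s), s, s)
    d <- sqrt((xs - cx)^2 + (ys - cy)^2)
    r <- li$radius_frac * s
    mean(y[d < 0.5 * r]) - mean(y[d > 1.6 * r & d < 2.6 * r])
  }
  diffs0 <- vapply(1:20, function(s)
    region_diff(make_lesion_image(spec, 0, s, center = c(0.5, 0.5))),
    numeric(1))
  t0 <- abs(mean(diffs0)) / (sd(diffs0) / sqrt(length(diffs0)))
  expect_lt(t0, 3)   # contrast 0: no detectable lesion signal
  diffs1 <- vapply(1:20, function(s)
    region_diff(make_lesion_image(spec, 1, s, center = c(0.5, 0.5))),
    numeric(1))
  expect_lt(mean(diffs1), -0.3)   # contrast 0.5 darkens the lesion clearly
})

test_that("mean lesion intensities recover the configured contrast gap", {
  params <- tibble::tibble(
    name = c("faint", "dark"), radius_frac = c(0.25, 0.25),
    border_amp = c(0.04, 0.04), contrast = c(0.2, 0.6),
    texture_sd = c(0.05, 0.05)
  )
  spec <- fixture_spec(image_size = 48, n_classes = 2, class_params = params)
  inner_mean <- function(li) {
    s <- 48
    y <- 0.299 * li$image[, , 1] + 0.587 * li$image[, , 2] +
      0.114 * li$image[, , 3]
    cx <- li$center[1] * s; cy <- li$center[2] * s
    xs <- matrix(rep(seq_len(s) - 0.5, each = s), s, s)
    ys <- matrix(rep(seq_len(s) - 0.5, times = s), s, s)
    mean(y[sqrt((xs - cx)^2 + (ys - cy)^2) < 0.5 * li$radius_frac * s])
  }
  m0 <- vapply(1:50, function(s) inner_mean(make_lesion_image(spec, 0, s)),
               numeric(1))
  m1 <- vapply(1:50, function(s) inner_mean(make_lesion_image(spec, 1, 100 + s)),
               numeric(1))
  gap <- mean(m0) - mean(m1)
  se <- sqrt(var(m0) / 50 + var(m1) / 50)
  expect_lt(abs(gap - 0.4), 3 * se)
})

test_that("make_dataset assembles counts, labels and metadata", {
  spec <- fixture_spec(image_size = 16, n_classes = 2)
  ds <- make_dataset(spec, c(10, 10), seed = 3)
  expect_s3_class(ds, "lesion_dataset")
  expect_length(ds$images, 20)
  expect_equal(tabulate(ds$labels + 1, 2), c(10L, 10L))
  imb <- make_dataset(spec, c(100, 10), seed = 3)
  expect_equal(as.vector(table(imb$labels)), c(100L, 10L))
  expect_error(make_dataset(spec, c(0, 0), seed = 1),
               class = "lesionlab_empty_dataset")
  expect_error(make_dataset(spec, c(-1, 5), seed = 1))
  # determinism
  ds2 <- make_dataset(spec, c(10, 10), seed = 3)
  expect_identical(ds$images, ds2$images)
})

test_that("anomaly images are bounded, deterministic and far from fixtures", {
  spec <- fixture_spec(image_size = 16, n_classes = 2)
  an <- make_anomaly_images(5, spec, seed = 4)
  expect_length(an, 5)
  expect_true(all(vapply(an, function(x) all(x >= 0 & x <= 1), logical(1))))
  expect_identical(an, make_anomaly_images(5, spec, seed = 4))
  expect_error(make_anomaly_images(0, spec, seed = 1))
  # pairwise-distance oracle: anomalies are farther from every fixture than
  # fixtures are from each other on average
  ds <- make_dataset(spec, c(5, 5), seed = 9)
  l1 <- function(a, b) mean(abs(a - b))
  fix_base <- mean(utils::combn(10, 2, function(ix)
    l1(ds$images[[ix[1]]], ds$images[[ix[2]]])))
  an_min <- min(vapply(an, function(a)
    min(vapply(ds$images, l1, numeric(1), a = a)), numeric(1)))
  expect_gt(an_min, fix_base)
})
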