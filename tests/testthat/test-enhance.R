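test_that("multi-scale retinex matches the dense-convolution oracle", {
  m <- fixture_image(seed = 2, size = 16)
  cfg <- enhance_config(retinex_scales = 2, log_epsilon = 1 / 255)
  raw <- multiscale_retinex(m, cfg, rescale = FALSE)
  oracle <- log(m + 1 / 255) - log(oracle_gauss_blur(m, 2) + 1 / 255)
  expect_lt(max(abs(raw - oracle)), 1e-6)
  # three scales with explicit weights equal the weighted sum of singles
  cfg3 <- enhance_config(retinex_scales = c(1, 2, 4),
                         retinex_weights = c(0.2, 0.5, 0.3))
  raw3 <- multiscale_retinex(m, cfg3, rescale = FALSE)
  parts <- sapply(c(1, 2, 4), function(s) {
    multiscale_retinex(m, enhance_config(retinex_scales = s), rescale = FALSE)
  }, simplify = FALSE)
  manual <- 0.2 * parts[[1]] + 0.5 * parts[[2]] + 0.3 * parts[[3]]
  expect_lt(max(abs(raw3 - manual)), 1e-12)
  # constant image: zero response before rescaling
  const <- matrix(0.4, 16, 16)
  expect_lt(max(abs(multiscale_retinex(const, cfg, rescale = FALSE))), 1e-12)
  expect_error(
    multiscale_retinex(m, enhance_config(retinex_scales = c(1, 2),
                                         retinex_weights = c(1))),
    class = "lesionlab_bad_retinex")
})

test_that("gamma correction is exact, monotone and composes", {
  m <- fixture_image(seed = 3, size = 16)
  expect_equal(gamma_correct(m, 1), m)
  expect_equal(gamma_correct(matrix(0.25, 4, 4), 2), matrix(0.0625, 4, 4))
  expect_lt(max(abs(gamma_correct(gamma_correct(m, 1.7), 0.4) -
                      gamma_correct(m, 1.7 * 0.4))), 1e-9)
  # strictly monotone
  v <- sort(runif(50))
  out <- as.vector(gamma_correct(matrix(v, 1), 0.7))
  expect_true(all(diff(out) > 0))
  expect_error(gamma_correct(m, -1), class = "lesionlab_bad_gamma")
})

test_that("histogram equalization follows the scaled-CDF formula", {
  expect_equal(hist_equalize(matrix(c(0, 0, 1, 1), 2, 2), 256) * 255,
               matrix(c(128, 128, 255, 255), 2, 2))
  const <- matrix(0.5, 8, 8)
  expect_identical(hist_equalize(const, 256), const)
  # full ramp: CDF of a uniform histogram is linear -> output within 1 level
  ramp <- matrix((0:255) / 255, 16, 16)
  out <- hist_equalize(ramp, 256)
  expect_lte(max(abs(round(out * 255) - round(ramp * 255))), 1)
  # transfer function is non-decreasing on random images
  m <- fixture_image_8bit(seed = 4, size = 16)
  he <- hist_equalize(m, 256)
  ord <- order(as.vector(m))
  expect_true(all(diff(as.vector(he)[ord]) >= -1e-12))
  expect_error(hist_equalize(m, 1))
})

test_that("unsharp masking matches the direct-formula oracle", {
  m <- fixture_image(seed = 5, size = 16)
  cfg <- enhance_config(unsharp_k = 1, unsharp_sigma = 1)
  expect_equal(unsharp_mask(m, enhance_config(unsharp_k = 0)), m)
  const <- matrix(0.6, 16, 16)
  expect_lt(max(abs(unsharp_mask(const, cfg) - const)), 1e-12)
  # step edge: overshoot matches I + k (I - G*I)
  step <- matrix(0.3, 16, 16); step[, 9:16] <- 0.7
  got <- unsharp_mask(step, cfg)
  oracle <- pmin(pmax(step + 1 * (step - oracle_gauss_blur(step, 1)), 0), 1)
  expect_lt(max(abs(got - oracle)), 1e-6)
  expect_gt(max(got), 0.7)   # visible overshoot at the edge
})

test_that("CLAHE reduces to global HE and fixes degenerate inputs", {
  m <- fixture_image_8bit(seed = 6, size = 32)
  one_tile <- clahe(m, enhance_config(clahe_tiles = c(1, 1),
                                      clahe_clip = 256, levels = 256))
  expect_identical(one_tile, hist_equalize(m, 256))
  const <- matrix(0.2, 16, 16)
  expect_identical(clahe(const, enhance_config(clahe_tiles = c(2, 2))), const)
  expect_error(clahe(matrix(0.5, 4, 4),
                     enhance_config(clahe_tiles = c(8, 8))),
               class = "lesionlab_bad_tiles")
})

test_that("CLAHE matches the per-pixel scalar oracle", {
  for (seed in 1:3) {
    m <- fixture_image_8bit(seed = seed, size = 32)
    got <- clahe(m, enhance_config(clahe_tiles = c(2, 2), clahe_clip = 2,
                                   levels = 256))
    want <- oracle_clahe(m, c(2, 2), 2, 256)
    expect_lt(max(abs(got - want)), 1e-12)
  }
  # non-divisible size exercises the reflect padding path
  m2 <- fixture_image_8bit(seed = 9, size = 30)
  got2 <- clahe(m2, enhance_config(clahe_tiles = c(4, 4), clahe_clip = 3,
                                   levels = 256))
  want2 <- oracle_clahe(m2, c(4, 4), 3, 256)
  expect_lt(max(abs(got2 - want2)), 1e-12)
})

test_that("crop extracts exact regions and composes with resize", {
  m <- fixture_image(seed = 7, size = 20)
  expect_identical(crop_region(m, c(1, 1, 20, 20)), m)
  expect_identical(crop_region(m, c(3, 5, 12, 14)), m[3:12, 5:14])
  expect_error(crop_region(m, c(0, 1, 10, 10)), class = "lesionlab_bad_box")
  # crop-then-resize equals manual composition
  a <- resize_normalize(crop_region(m, c(1, 1, 16, 16)), 8)
  b <- resize_normalize(m[1:16, 1:16], 8)
  expect_identical(a, b)
})

test_that("the composed pipeline respects stage order and neutrality", {
  m <- fixture_image(seed = 8, size = 16)
  neutral <- enhance_config(gamma = 1, unsharp_k = 0,
                            stage_order = c("gamma", "unsharp"))
  expect_equal(enhance_pipeline(m, neutral), m)
  cfg <- enhance_config(retinex_scales = 2, gamma = 0.9,
                        clahe_tiles = c(2, 2),
                        stage_order = c("retinex", "gamma", "hist_eq",
                                        "unsharp", "clahe"))
  got <- enhance_pipeline(m, cfg)
  manual <- clahe(unsharp_mask(hist_equalize(gamma_correct(
    multiscale_retinex(m, cfg), 0.9), 256), cfg), cfg)
  expect_identical(got, manual)
  expect_true(all(got >= 0 & got <= 1))
  bad <- enhance_config()
  bad$stage_order <- c("gamma", "sharpen_more")
  expect_error(enhance_pipeline(m, bad), class = "lesionlab_unknown_stage")
  expect_error(enhance_config(stage_order = "sharpen_more"),
               class = "lesionlab_unknown_stage")
})
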