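test_that("raw images validate pixel range against declared depth", {
  expect_s3_class(raw_image(matrix(c(0L, 4095L), 1), 12), "raw_image")
  expect_error(raw_image(matrix(5000L, 1), 12),
               class = "radwindow_error_depth_mismatch")
  expect_error(raw_image(matrix(-1, 1), 12),
               class = "radwindow_error_invalid_image")
})

test_that("images survive a 16-bit write/read round trip", {
  img <- raw_image(random_12bit_image(9, seed = 5), 12)
  path <- withr::local_tempfile(fileext = ".tif")
  write_image(img, path)
  back <- load_image(path, expected_bit_depth = 12)
  expect_equal(back$pixels, img$pixels)
  expect_equal(back$bit_depth, 12L)
})

test_that("load_image reads 8-bit PNG and enforces the declared depth", {
  px <- matrix(sample(0:255, 36, replace = TRUE), 6, 6)
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(px / 255, path)
  back <- load_image(path, expected_bit_depth = 8)
  expect_equal(back$pixels, px)
  # declaring the same file 12-bit is fine (containment) but a stored
  # value above the declared depth is not
  path2 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(5000 / 65535, 2, 2), path2, bits.per.sample = 16)
  expect_error(load_image(path2, expected_bit_depth = 12),
               class = "radwindow_error_depth_mismatch")
  expect_error(load_image(withr::local_tempfile(fileext = ".png")),
               class = "radwindow_error_io")
})

test_that("bit-depth reduction is the floor of the global linear rescale", {
  img <- raw_image(matrix(c(0L, 4095L), 1), 12)
  red <- reduce_bit_depth(img, 8)
  expect_equal(red$pixels, matrix(c(0, 255), 1))
  expect_equal(red$bit_depth, 8L)

  # exhaustive oracle over all 12-bit values
  all12 <- raw_image(matrix(0:4095, 1), 12)
  out <- reduce_bit_depth(all12, 8)$pixels
  expect_equal(as.numeric(out), floor((0:4095) * 255 / 4095))
  expect_true(all(diff(as.numeric(out)) >= 0))
  expect_setequal(unique(as.numeric(out)), 0:255)

  expect_error(reduce_bit_depth(red, 12),
               class = "radwindow_error_invalid_reduction")
})

test_that("quantization collapses distinct values inside narrow bands", {
  all12 <- raw_image(matrix(0:4095, 1), 12)
  red <- reduce_bit_depth(all12, 8)$pixels
  inband <- 1900:2300  # a 400-unit band holds 401 distinct 12-bit values
  expect_lt(length(unique(red[1, inband + 1])), length(inband))
})

test_that("fixed preprocessing matches the windows-module oracle path", {
  img <- raw_image(random_12bit_image(24, seed = 13), 12)
  w <- window_set(2500, 3000)
  got <- preprocess_fixed(img, w, out_size = 24, normalize = FALSE)
  lim <- window_limits(w)
  expected <- (apply_window(img$pixels, w) - lim$lower) * 255 / w$width
  expect_lt(max(abs(got$pixels[, , 1] - expected)), 1e-4)
  expect_equal(got$pixels[, , 1], got$pixels[, , 3])
})

test_that("no window means the full-range window", {
  img <- raw_image(random_12bit_image(16, seed = 21), 12)
  a <- preprocess_fixed(img, NULL, out_size = 16)
  b <- preprocess_fixed(img, full_range_window(), out_size = 16)
  expect_equal(a$pixels, b$pixels)
})

test_that("constant images map to normalized mid-scale", {
  img <- raw_image(matrix(1250L, 8, 8), 12)
  out <- preprocess_fixed(img, window_set(1250, 1000), out_size = 8)
  norm <- imagenet_norm()
  for (j in 1:3) {
    expect_equal(unique(as.numeric(out$pixels[, , j])),
                 (127.5 / 255 - norm$mean[j]) / norm$std[j])
  }
})

test_that("pre-normalization values stay within the output scale", {
  img <- raw_image(random_12bit_image(20, seed = 31), 12)
  out <- preprocess_fixed(img, window_set(400, 700), out_size = 10,
                          normalize = FALSE)
  expect_true(all(out$pixels >= 0 & out$pixels <= 255))
  expect_equal(dim(out$pixels), c(10L, 10L, 3L))
})

test_that("a monotone ramp passes through the identity window unchanged", {
  ramp <- matrix(rep(round(seq(0, 4095, length.out = 16)), each = 16), 16)
  img <- raw_image(ramp, 12)
  out <- preprocess_fixed(img, NULL, out_size = 16, normalize = FALSE)
  expect_equal(out$pixels[, , 1], ramp * 255 / 4096, tolerance = 1e-12)
})

test_that("label tables validate split and finding columns", {
  cfg <- tiny_config(n_train = 6, n_validate = 3, n_test = 3)
  data <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  readr::write_csv(data$labels, file.path(dir, "labels.csv"))
  tab <- read_label_table(file.path(dir, "labels.csv"))
  expect_equal(nrow(tab), 12)
  bad <- dplyr::mutate(data$labels, split = "eval")
  readr::write_csv(bad, file.path(dir, "bad.csv"))
  expect_error(read_label_table(file.path(dir, "bad.csv")),
               class = "radwindow_error_io")
})

test_that("image sets round-trip through disk", {
  cfg <- tiny_config(n_train = 4, n_validate = 2, n_test = 2, image_size = 8)
  data <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_image_set(data, dir)
  back <- read_image_set(dir)
  expect_equal(back$pixels, data$pixels)
  expect_equal(back$labels, data$labels)
})
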