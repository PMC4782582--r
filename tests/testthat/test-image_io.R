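test_that("min-max normalization maps endpoints and constants as documented", {
  tmp <- withr::local_tempfile(fileext = ".png")
  m <- matrix(0, 16, 16); m[1:8, ] <- 1
  png::writePNG(m, tmp)
  img <- load_image(tmp)
  expect_setequal(unique(as.vector(img$pixels)), c(0, 1))

  # constant image maps to all zeros by convention
  png::writePNG(matrix(77 / 255, 12, 12), tmp)
  expect_true(all(load_image(tmp)$pixels == 0))
})

test_that("16-bit TIFF intensities are normalized to (v - min)/(max - min)", {
  tmp <- withr::local_tempfile(fileext = ".tiff")
  vals <- c(100, 300, 500)
  m <- matrix(vals[c(1, 2, 3)[(seq_len(144) %% 3) + 1]] / 65535, 12, 12)
  tiff::writeTIFF(m, tmp, bits.per.sample = 16L)
  img <- load_image(tmp)
  expect_equal(sort(unique(as.vector(img$pixels))), c(0, 0.5, 1),
               tolerance = 1e-9)
})

test_that("8-bit PNG round trip reproduces intensities within 1/255", {
  tmp <- withr::local_tempfile(fileext = ".png")
  set.seed(5)
  m <- matrix(runif(400), 20, 20)
  m <- (m - min(m)) / (max(m) - min(m))  # already normalized
  png::writePNG(m, tmp)
  img1 <- load_image(tmp)
  tmp2 <- withr::local_tempfile(fileext = ".png")
  save_image_png(img1, tmp2)
  img2 <- load_image(tmp2)
  expect_lt(max(abs(img2$pixels - img1$pixels)), 1 / 255 + 1e-12)
})

test_that("RGB rasters collapse by unweighted channel mean", {
  tmp <- withr::local_tempfile(fileext = ".png")
  a <- array(0, c(10, 10, 3))
  a[, , 1] <- 0.9; a[, , 2] <- 0.3; a[, , 3] <- 0.3  # mean 0.5
  a[1, 1, ] <- 0   # one dark pixel to anchor the normalization
  a[10, 10, ] <- 1 # and one bright
  png::writePNG(a, tmp)
  img <- load_image(tmp)
  expect_equal(img$pixels[5, 5], 0.5, tolerance = 2 / 255)
})

test_that("mirroring reverses columns and is an involution", {
  m <- matrix(runif(9 * 12), 9, 12)
  img <- gray_image(m, normalize = TRUE)
  mir <- mirror_image(img)
  expect_identical(mir$pixels, img$pixels[, 12:1])
  expect_identical(mirror_image(mir)$pixels, img$pixels)

  # a column-symmetric image is a fixed point
  sym <- gray_image(cbind(m[, 1:6], m[, 6:1]), normalize = TRUE)
  expect_identical(mirror_image(sym)$pixels, sym$pixels)
})

test_that("unreadable and undersized inputs raise decode/dimension errors", {
  tmp <- withr::local_tempfile(fileext = ".png")
  writeLines("not a png", tmp)
  expect_error(load_image(tmp), class = "decode_error")
  expect_error(load_image("no/such/file.png"), class = "decode_error")
  expect_error(gray_image(matrix(0.5, 4, 4)), class = "dimension_error")
})

test_that("configs load from YAML and JSON with validation and defaults", {
  # parameter sets in the regime used for clinical images
  y <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("K: 4", "j: 3", "d: 13", "delta: 26"), y)
  cfg <- load_config(y)
  expect_s3_class(cfg, "analysis_config")
  expect_identical(cfg$fit_axis, "auto")
  expect_identical(cfg$seed, 0L)

  jn <- withr::local_tempfile(fileext = ".json")
  writeLines('{"K": 6, "j": 5, "d": 13, "delta": 18, "seed": 2}', jn)
  cfg2 <- load_config(jn)
  expect_identical(cfg2$K, 6L)
  expect_identical(cfg2$seed, 2L)

  writeLines(c("K: 4", "j: 5", "d: 13", "delta: 26"), y)
  expect_error(load_config(y), class = "validation_error")
  writeLines(c("K: 4", "j: 3", "d: -2", "delta: 26"), y)
  expect_error(load_config(y), class = "validation_error")
  writeLines(c("K: 4", "j: 3", "d: 13", "delta: -1"), y)
  expect_error(load_config(y), class = "validation_error")
  writeLines(c("K: 4", "j: 3", "d: 13", "delta: 26", "bogus: 1"), y)
  expect_error(load_config(y), class = "validation_error")
})

test_that("config round trip preserves all fields", {
  cfg <- analysis_config(5, 4, 14, 26, roi = c(10, 90, 5, 60),
                         plate_length_L = 320, fit_axis = "y", seed = 9L)
  y <- withr::local_tempfile(fileext = ".yaml")
  save_config(cfg, y)
  cfg2 <- load_config(y)
  expect_equal(unclass(cfg2), unclass(cfg))
})

test_that("ROI outside the image is rejected", {
  img <- gray_image(matrix(runif(100), 10, 10), normalize = TRUE)
  cfg <- analysis_config(2, 2, 3, 5, roi = c(0, 20, 0, 5))
  expect_error(extract_landmark_points(img, cfg), class = "validation_error")
})

test_that("uncompressed monochrome DICOM pixel data is read", {
  # build a minimal explicit-VR little-endian part-10 file in code
  u16le <- function(x) as.raw(c(x %% 256, x %/% 256))
  elem_us <- function(group, el, val)
    c(u16le(group), u16le(el), charToRaw("US"), u16le(2L), u16le(val))
  H <- 9L; W <- 11L
  vals <- matrix(seq_len(H * W) * 13L %% 601L, H, W)
  pix <- writeBin(as.integer(t(vals)), raw(), size = 2L, endian = "little")
  ts <- charToRaw("1.2.840.10008.1.2.1")
  if (length(ts) %% 2) ts <- c(ts, as.raw(0))
  body <- c(
    c(u16le(0x0002L), u16le(0x0010L), charToRaw("UI"), u16le(length(ts)), ts),
    elem_us(0x0028L, 0x0002L, 1L),      # samples per pixel
    elem_us(0x0028L, 0x0010L, H),       # rows
    elem_us(0x0028L, 0x0011L, W),       # columns
    elem_us(0x0028L, 0x0100L, 16L),     # bits allocated
    elem_us(0x0028L, 0x0103L, 0L),      # pixel representation
    c(u16le(0x7fe0L), u16le(0x0010L), charToRaw("OW"), u16le(0L),
      u16le(length(pix) %% 65536L), u16le(length(pix) %/% 65536L), pix))
  tmp <- withr::local_tempfile(fileext = ".dcm")
  con <- file(tmp, "wb")
  writeBin(c(raw(128), charToRaw("DICM"), body), con)
  close(con)
  img <- load_image(tmp)
  expect_identical(dim(img$pixels), c(H, W))
  expect_equal(img$pixels,
               (vals - min(vals)) / (max(vals) - min(vals)),
               tolerance = 1e-12, ignore_attr = TRUE)
})
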