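make_test_pyramid <- function(base = 64L, n_levels = 3L, spacing0 = 0.5) {
  set.seed(99)
  build_pyramid(array(runif(base * base * 3), c(base, base, 3)),
                spacing0 = spacing0, n_levels = n_levels)
}

test_that("closest_level picks the level nearest the target spacing", {
  # scanner with 0.2431 um base spacing: 0.5 um target resolves to 0.4861
  p <- image_pyramid(rep(list(array(0.5, c(8, 8, 3))), 4),
                     spacings = c(0.2431, 0.4861, 0.9722, 1.9444),
                     validate = FALSE)
  lv <- closest_level(p, 0.5)
  expect_equal(lv$level_index, 1L)
  expect_equal(lv$spacing, 0.4861)
  # scanner with 0.5034 um base spacing: 0.5 um target stays at level 0
  p2 <- image_pyramid(rep(list(array(0.5, c(8, 8, 3))), 3),
                      spacings = 0.5034 * 2^(0:2), validate = FALSE)
  expect_equal(closest_level(p2, 0.5)$level_index, 0L)
  # single-level pyramid: only candidate
  p3 <- image_pyramid(list(array(0.5, c(8, 8, 3))), spacings = 2)
  expect_equal(closest_level(p3, 0.01)$level_index, 0L)
  # exact tie between two levels resolves to the finer one
  p4 <- image_pyramid(rep(list(array(0.5, c(8, 8, 3))), 2),
                      spacings = c(1, 2), validate = FALSE)
  expect_equal(closest_level(p4, 1.5)$level_index, 0L)
})

test_that("closest_level rejects unusable input", {
  p <- make_test_pyramid()
  expect_error(closest_level(list(), 0.5), "levels")
  expect_error(closest_level(p, -1), "positive")
  expect_error(closest_level(p, 0), "positive")
})

test_that("pyramid invariants are validated", {
  lv0 <- array(0.5, c(16, 16, 3))
  lv1 <- array(0.5, c(8, 8, 3))
  expect_error(image_pyramid(list(lv0, lv1), spacings = c(1, 3)), "double")
  expect_error(image_pyramid(list(lv0, array(0.5, c(4, 4, 3))),
                             spacings = c(1, 2)), "half")
  expect_error(image_pyramid(list(array(0.5, c(8, 8, 2))), spacings = 1),
               "RGB")
  expect_silent(image_pyramid(list(lv0, lv1), spacings = c(1, 2)))
})

test_that("read_region returns tiles, pads with white, and is deterministic", {
  p <- make_test_pyramid()
  full <- read_region(p, 0L, c(0, 0), c(64, 64))
  expect_equal(dim(full), c(64, 64, 3))
  expect_equal(full, p$levels[[1]])
  # tile straddling the right edge: requested size kept, out-of-extent white
  t1 <- read_region(p, 0L, c(56, 0), c(16, 16))
  expect_equal(dim(t1), c(16, 16, 3))
  expect_equal(t1[, 9:16, ], array(1, c(16, 8, 3)))
  expect_equal(t1[, 1:8, ], p$levels[[1]][1:16, 57:64, ])
  # determinism
  expect_identical(read_region(p, 0L, c(5, 7), c(20, 10)),
                   read_region(p, 0L, c(5, 7), c(20, 10)))
  expect_error(read_region(p, 0L, c(100, 0), c(8, 8)), "outside")
})

test_that("raw-storage pyramids read back identically through read_region", {
  set.seed(5)
  lv0 <- array(round(runif(32 * 32 * 3) * 255) / 255, c(32, 32, 3))
  pd <- build_pyramid(lv0, 1, 2, storage = "double")
  pr <- build_pyramid(lv0, 1, 2, storage = "raw")
  expect_equal(read_region(pr, 0L, c(0, 0), c(32, 32)),
               read_region(pd, 0L, c(0, 0), c(32, 32)), tolerance = 1e-9)
})

test_that("pyramid TIFF round trip preserves pixels and spacing", {
  p <- make_test_pyramid(base = 40L)
  path <- tempfile(fileext = ".tif")
  write_pyramid_tiff(p, path)
  r <- read_pyramid_tiff(path)
  expect_equal(length(r$levels), 3L)
  expect_equal(r$spacings, p$spacings)
  # 8-bit quantisation bound on the round trip
  expect_lt(max(abs(r$levels[[1]] - p$levels[[1]])), 1 / 255 + 1e-9)
  unlink(c(path, paste0(path, ".spacing.json")))
})

test_that("reading without spacing metadata requires pixel_spacing_um", {
  p <- make_test_pyramid(base = 16L, n_levels = 1L)
  path <- tempfile(fileext = ".tif")
  write_pyramid_tiff(p, path)
  unlink(paste0(path, ".spacing.json"))
  expect_error(read_pyramid_tiff(path), "pixel_spacing_um")
  r <- read_pyramid_tiff(path, pixel_spacing_um = 0.25)
  expect_equal(r$spacings, 0.25)
  unlink(path)
})

test_that("mask pyramid round trip is bit-exact at level 0", {
  set.seed(3)
  m <- binary_mask(matrix(rbinom(512 * 512, 1, 0.3), 512), spacing = 2)
  path <- tempfile(fileext = ".tif")
  write_mask_pyramid(m, path, n_levels = 3L)
  r <- read_mask_pyramid(path)
  expect_identical(r[[1]]$data, m$data)
  expect_equal(r[[1]]$spacing, 2)
  # all-zero mask stays all-zero at every level
  z <- binary_mask(matrix(0L, 64, 64), spacing = 1)
  write_mask_pyramid(z, path, n_levels = 3L)
  rz <- read_mask_pyramid(path)
  for (k in 1:3) expect_true(all(rz[[k]]$data == 0L))
  unlink(c(path, paste0(path, ".spacing.json")))
})

test_that("mask pyramids downsample by 2x2 majority vote", {
  # checkerboard: every 2x2 block has two tissue pixels, a tie, which the
  # declared rule resolves to tissue; verified against brute force below
  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2L)
  m <- binary_mask(cb, spacing = 1)
  path <- tempfile(fileext = ".tif")
  write_mask_pyramid(m, path, n_levels = 2L)
  r <- read_mask_pyramid(path)
  brute <- matrix(0L, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    blk <- cb[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)]
    brute[i, j] <- as.integer(sum(blk) >= 2)
  }
  expect_identical(r[[2]]$data, brute)
  expect_true(all(r[[2]]$data == 1L))
  # a block with a single foreground pixel votes background
  one <- matrix(0L, 4, 4); one[1, 1] <- 1L
  write_mask_pyramid(binary_mask(one, spacing = 1), path, n_levels = 2L)
  expect_true(all(read_mask_pyramid(path)[[2]]$data == 0L))
  unlink(c(path, paste0(path, ".spacing.json")))
})

test_that("writing to an unwritable path signals an I/O error", {
  m <- binary_mask(matrix(0L, 8, 8), spacing = 1)
  expect_error(write_mask_pyramid(m, "/nonexistent-dir/x/y.tif"))
  p <- make_test_pyramid(base = 16L, n_levels = 1L)
  expect_error(write_pyramid_tiff(p, "/nonexistent-dir/x/y.tif"))
})
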