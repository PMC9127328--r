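test_that("micrograph construction enforces its invariants", {
  px <- matrix(1, 32, 32)
  m <- micrograph(px, 25, "APP", "fixed")
  expect_s3_class(m, "micrograph")
  expect_equal(dim(m), c(32L, 32L))
  expect_error(micrograph(matrix(1, 8, 8), 25), "16 x 16")
  expect_error(micrograph(px - 2, 25), "non-negative")
  expect_error(micrograph({p <- px; p[1] <- NA; p}, 25), "finite")
  expect_error(micrograph(px, 0), "positive")
  expect_error(micrograph(px, -25), "positive")
})

test_that("16-bit TIFF write/read round trip is bit exact", {
  set.seed(42)
  px <- matrix(sample(0:65535, 64 * 64, replace = TRUE), 64, 64)
  img <- micrograph(px, 25, "A")
  f <- withr::local_tempfile(fileext = ".tif")
  write_micrograph(img, f)
  back <- read_micrograph(f, 25, "A")
  expect_identical(as.integer(back$pixels), as.integer(px))
  expect_equal(back$pixel_size_nm, 25)
})

test_that("constant and single-hot-pixel images read back exactly", {
  f <- withr::local_tempfile(fileext = ".tif")
  write_micrograph(micrograph(matrix(0, 64, 64), 25), f)
  expect_true(all(read_micrograph(f, 25)$pixels == 0))
  px <- matrix(0, 64, 64); px[10, 20] <- 65535
  write_micrograph(micrograph(px, 25), f)
  expect_equal(max(read_micrograph(f, 25)$pixels), 65535)
})

test_that("unreadable and RGB inputs are rejected with a diagnostic", {
  expect_error(read_micrograph("no/such/file.tif", 25), "no/such/file.tif")
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(array(0.5, c(32, 32, 3)), f)
  expect_error(read_micrograph(f, 25), "RGB")
  f2 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.5, 32, 32), f2)
  expect_error(read_micrograph(f2, -1), "positive")
})

test_that("rectangular ROIs validate bounds and report area", {
  r <- roi_rect(0, 0, 10, 10)
  mask <- sheetquant:::roi_mask(r, 64, 64)
  expect_equal(sum(mask), 100)
  expect_error(sheetquant:::roi_mask(roi_rect(60, 60, 10, 10), 64, 64),
               "outside image bounds")
  expect_equal(sheetquant:::roi_area_um2(roi_rect(0, 0, 40, 40), 64, 64,
                                         25), 1)
})

test_that("ROI JSON round trip preserves shapes and roles", {
  rois <- list(roi_rect(2, 3, 10, 12, "membrane"),
               roi_polygon(cbind(c(5, 20, 20, 5), c(5, 5, 20, 20)),
                           "background"))
  f <- withr::local_tempfile(fileext = ".json")
  write_rois(rois, f)
  back <- load_rois(f, image_dim = c(64, 64))
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$width, 12)
  expect_equal(back[[1]]$role, "membrane")
  expect_equal(back[[2]]$vertices, rois[[2]]$vertices,
               ignore_attr = TRUE)
  # bounds check fires on load
  big <- list(roi_rect(0, 0, 100, 100))
  write_rois(big, f)
  expect_error(load_rois(f, image_dim = c(64, 64)), "outside image bounds")
})

test_that("CSV ROIs load and polygon masks use the even-odd rule", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(row0 = 0, col0 = 0, height = 8, width = 4,
                       role = "bleach"), f, row.names = FALSE)
  r <- load_rois(f)[[1]]
  expect_equal(r$shape, "rect")
  expect_equal(sum(sheetquant:::roi_mask(r, 32, 32)), 32)
  tri <- roi_polygon(cbind(c(0, 20, 0), c(0, 0, 20)))
  area <- sum(sheetquant:::roi_mask(tri, 32, 32))
  expect_gt(area, 150)  # ~ half of 20x20
  expect_lt(area, 250)
})

test_that("two-channel operations reject unregistered inputs", {
  a <- micrograph(matrix(1, 32, 32), 25)
  b <- micrograph(matrix(1, 32, 32), 30)
  expect_error(pearson(a, b, roi_rect(0, 0, 16, 16)), "pixel sizes")
  c2 <- micrograph(matrix(1, 32, 48), 25)
  expect_error(pearson(a, c2, roi_rect(0, 0, 16, 16)), "shapes differ")
})

test_that("analysis config validates and round-trips through YAML", {
  cfg <- analysis_config(maxima_threshold_au = 3.5, rng_seed = 9L)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, f)
  back <- read_config(f)
  expect_equal(unclass(back), unclass(cfg))
  expect_error(analysis_config(r2_min = 1.2), "r2_min")
  expect_error(analysis_config(blur_sigma_px = -1), "positive")
  expect_error(analysis_config(linescan_length_px = 14), "odd")
})
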