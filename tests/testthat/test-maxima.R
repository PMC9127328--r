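cfg5 <- analysis_config(maxima_threshold_au = 5)

test_that("an all-zero image yields an empty set with density zero", {
  img <- micrograph(matrix(0, 64, 64), 25)
  set <- detect_maxima(img, cfg = cfg5)
  expect_equal(nrow(set$maxima), 0L)
  expect_equal(maxima_density(set), 0)
})

test_that("a symmetric spot is localized to subpixel accuracy", {
  img <- gauss_spot_image(64, center = c(20.30, 41.70))
  set <- detect_maxima(img, cfg = cfg5)
  expect_equal(nrow(set$maxima), 1L)
  expect_lt(abs(set$maxima$row_subpx - 20.30), 0.1)
  expect_lt(abs(set$maxima$col_subpx - 41.70), 0.1)
  expect_equal(set$maxima$row_nm, set$maxima$row_subpx * 25)
})

test_that("detection is equivariant under integer pixel shifts", {
  set.seed(8)
  base <- matrix(0, 96, 96)
  centers <- cbind(c(25.3, 60.7, 40.1), c(30.8, 44.2, 70.5))
  for (i in 1:3)
    base <- base + 80 * outer(
      exp(-((seq_len(96) - 1) - centers[i, 1])^2 / (2 * 1.5^2)),
      exp(-((seq_len(96) - 1) - centers[i, 2])^2 / (2 * 1.5^2)))
  shift <- c(3L, 5L)
  shifted <- matrix(0, 96, 96)
  shifted[(1 + shift[1]):96, (1 + shift[2]):96] <-
    base[1:(96 - shift[1]), 1:(96 - shift[2])]
  s1 <- detect_maxima(micrograph(base, 25), cfg = cfg5)
  s2 <- detect_maxima(micrograph(shifted, 25), cfg = cfg5)
  expect_equal(nrow(s2$maxima), nrow(s1$maxima))
  o1 <- order(s1$maxima$row_subpx); o2 <- order(s2$maxima$row_subpx)
  expect_equal(s2$maxima$row_subpx[o2], s1$maxima$row_subpx[o1] + shift[1],
               tolerance = 1e-9)
  expect_equal(s2$maxima$col_subpx[o2], s1$maxima$col_subpx[o1] + shift[2],
               tolerance = 1e-9)
})

test_that("raising the threshold never increases the maxima count", {
  sim <- simulate_sheet(sheet_sim_spec(rng_seed = 21L))
  roi <- sim_interior_roi(sim)
  counts <- vapply(c(2, 5, 10, 20, 40), function(th)
    nrow(detect_maxima(sim$img_b, roi,
                       analysis_config(maxima_threshold_au = th))$maxima),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("density is maxima count over ROI area in square microns", {
  # 100 spots on a grid in a 400x400 px ROI at 25 nm/px = 100 um^2
  px <- matrix(0, 420, 420)
  pos <- seq(30, 390, by = 40)
  grid <- expand.grid(r = pos, c = pos)
  for (i in seq_len(nrow(grid)))
    px[grid$r[i], grid$c[i]] <- 200
  img <- micrograph(pmax(as.matrix(EBImage::gblur(px, 1.5)), 0) * 10, 25)
  set <- detect_maxima(img, roi_rect(10, 10, 400, 400), cfg5)
  expect_equal(nrow(set$maxima), 100L)
  expect_equal(set$area_um2, 100)
  expect_equal(maxima_density(set), 1.0)
})

test_that("simulated fields are recovered with high recall and precision", {
  rec <- prec <- numeric(5)
  for (seed in 1:5) {
    sim <- simulate_sheet(sheet_sim_spec(assoc_fraction = 0,
                                         rng_seed = seed))
    set <- detect_maxima(sim$img_b, sim_interior_roi(sim), cfg5)
    det <- cbind(set$maxima$row_nm, set$maxima$col_nm)
    k <- match_count(sim$truth$positions_b_nm, det,
                     sim$truth$spec$psf_fwhm_nm)
    rec[seed] <- k / nrow(sim$truth$positions_b_nm)
    prec[seed] <- k / nrow(det)
  }
  # individual fields dip slightly below 0.9 recall when two true emitters
  # fall within the resolution limit and merge into one maximum
  expect_gte(mean(rec), 0.9)
  expect_gte(min(rec), 0.85)
  expect_gte(mean(prec), 0.9)
})

test_that("density of a 2.2/um^2 field is estimated within 15%", {
  est <- vapply(1:10, function(seed) {
    sim <- simulate_sheet(sheet_sim_spec(maxima_per_um2_B = 2.2,
                                         assoc_fraction = 0,
                                         rng_seed = 100L + seed))
    maxima_density(detect_maxima(sim$img_b, sim_interior_roi(sim), cfg5))
  }, numeric(1))
  expect_lt(abs(mean(est) - 2.2) / 2.2, 0.15)
})

test_that("FWHM fitting recovers the analytic width of a Gaussian spot", {
  sigma_nm <- 40
  img <- gauss_spot_image(64, center = c(31.4, 32.6),
                          sigma_px = sigma_nm / 25, background = 2)
  set <- fit_fwhm(img, detect_maxima(img, cfg = cfg5))
  expected <- 2 * sqrt(2 * log(2)) * sigma_nm
  expect_equal(nrow(set$maxima), 1L)
  expect_lt(abs(set$maxima$fwhm_nm - expected) / expected, 0.02)
  expect_gte(set$maxima$fwhm_r2, 0.99)
})

test_that("flat profiles are excluded as unfittable", {
  img <- micrograph(matrix(10, 32, 32), 25)
  set <- detect_maxima(img, cfg = analysis_config(maxima_threshold_au = 2))
  expect_gt(nrow(set$maxima), 0L)
  ann <- fit_fwhm(img, set)
  inner <- ann$maxima[is.na(ann$maxima$excluded_reason) |
                        ann$maxima$excluded_reason != "border", ]
  expect_true(all(inner$excluded_reason == "low_r2"))
  expect_true(all(is.na(inner$fwhm_nm)))
})

test_that("off-centre line-scan peaks are excluded as noncentered", {
  # constant-row ridge: a faint bump the detector locks onto, with the
  # dominant peak 7 px away so the scan's fitted centre sits near the edge
  n <- 40
  f <- 12 * exp(-((1:n) - 24)^2 / 2) + 100 * exp(-((1:n) - 17)^2 / 8)
  img <- micrograph(matrix(rep(f, each = n), n, n), 25)
  set <- detect_maxima(img, cfg = analysis_config(maxima_threshold_au = 3))
  ann <- fit_fwhm(img, set)
  # rows whose 15 px vertical scan also fits inside the image
  bump <- ann$maxima[ann$maxima$col_px == 23 & ann$maxima$row_px >= 10 &
                       ann$maxima$row_px <= 29, ]
  expect_gt(nrow(bump), 0L)
  expect_true(all(bump$excluded_reason == "noncentered"))
})

test_that("maxima near the image border are flagged and not localized", {
  g <- function(r0, c0) outer(
    exp(-((seq_len(64) - 1) - r0)^2 / (2 * 1.5^2)),
    exp(-((seq_len(64) - 1) - c0)^2 / (2 * 1.5^2)))
  img <- micrograph(100 * g(1, 29) + 100 * g(31, 32), 25)
  set <- detect_maxima(img, cfg = cfg5)
  border <- set$maxima[which(set$maxima$excluded_reason == "border"), ]
  expect_equal(nrow(border), 1L)
  expect_true(is.na(border$row_subpx))
  expect_equal(sum(is.na(set$maxima$excluded_reason)), 1L)
})
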