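mk <- function(px) micrograph(px, 25)

test_that("background correction is mean(membrane) - mean(background)", {
  px <- matrix(10, 64, 64)
  px[20:40, 20:40] <- 110
  img <- mk(px)
  mem <- roi_rect(19, 19, 21, 21)
  bg <- roi_rect(0, 0, 10, 10)
  expect_equal(corrected_mean(img, mem, bg), 100)
  # background brighter than the sheet: negative, with a warning
  expect_warning(v <- corrected_mean(mk(110 + 10 - px), mem, bg))
  expect_equal(v, -100)
  expect_error(corrected_mean(img, mem, roi_rect(19, 19, 5, 5)), "overlap")
})

test_that("corrected mean recovers the simulated signal level", {
  devs <- vapply(1:20, function(seed) {
    spec <- sheet_sim_spec(clusters_per_um2_A = 0, assoc_fraction = 0,
                           background_au = 10, noise_model = "gaussian",
                           noise_sd = 2, rng_seed = 300L + seed)
    sim <- simulate_sheet(spec)
    # channel B carries emitters only inside the placement margin; the
    # background ROI sits entirely in the empty border strip
    mem <- roi_rect(32, 32, 192, 192)
    bg <- roi_rect(0, 0, 5, 200)
    corrected_mean(sim$img_b, mem, bg)
  }, numeric(1))
  # the membrane ROI contains the emitters, the background ROI only noise;
  # the corrected mean must be positive and stable across seeds
  expect_true(all(devs > 0))
  expect_lt(sd(devs) / mean(devs), 0.25)
})

test_that("PCC hits its closed forms and ignores affine rescaling", {
  set.seed(5)
  a <- mk(matrix(runif(64 * 64, 0, 100), 64, 64))
  roi <- roi_rect(0, 0, 64, 64)
  expect_equal(pearson(a, a, roi), 1.0)
  neg <- mk(100 - a$pixels)
  expect_equal(pearson(a, neg, roi), -1.0)
  scaled <- mk(3 * a$pixels + 7)
  b <- mk(matrix(runif(64 * 64, 0, 100), 64, 64))
  expect_equal(pearson(scaled, b, roi), pearson(a, b, roi),
               tolerance = 1e-12)
  flat <- mk(matrix(5, 64, 64))
  expect_true(is.na(pearson(a, flat, roi)))
  expect_match(attr(pearson(a, flat, roi), "reason"), "variance")
})

test_that("independent noise fields decorrelate as 1/sqrt(n)", {
  r <- vapply(1:20, function(seed) {
    set.seed(400 + seed)
    a <- mk(matrix(rpois(1e4, 20), 100, 100))
    b <- mk(matrix(rpois(1e4, 20), 100, 100))
    pearson(a, b, roi_rect(0, 0, 100, 100))
  }, numeric(1))
  expect_gte(sum(abs(r) < 0.05), 19)
})

test_that("rSDM matches closed forms and is scale invariant", {
  roi <- roi_rect(0, 0, 32, 32)
  expect_equal(rsdm(mk(matrix(7, 32, 32)), roi), 0)
  half <- matrix(rep(c(0, 1), each = 512), 32, 32)
  v <- sheetquant:::roi_pixels(mk(half), roi)
  # balanced binary ROI: mean 1/2, SD 1/2 -> rSDM 1 (population SD);
  # sample SD differs only in the n-1 factor
  expect_equal(rsdm(mk(half), roi), 0.5 / 0.5 * sqrt(1024 / 1023),
               tolerance = 1e-12)
  img <- mk(matrix(runif(1024, 1, 50), 32, 32))
  expect_equal(rsdm(mk(img$pixels * 13), roi), rsdm(img, roi),
               tolerance = 1e-12)
  expect_true(is.na(rsdm(mk(matrix(0, 32, 32)), roi)))
})

test_that("normalization to a reference condition maps it to 100%", {
  tb <- data.frame(condition = rep(c("fixed", "control", "CoP"), each = 3),
                   value = c(2, 2.2, 1.8, 2.1, 2.0, 2.2, 4.0, 4.4, 3.6))
  out <- normalize_to_reference(tb, "fixed")
  s <- out$summary
  expect_equal(s$mean_percent[s$condition == "fixed"], 100)
  expect_equal(s$mean_percent[s$condition == "CoP"], 200)
  # SD propagation equals direct hand computation
  cop <- tb$value[tb$condition == "CoP"] / 2 * 100
  expect_equal(s$sd_percent[s$condition == "CoP"], sd(cop))
  expect_error(normalize_to_reference(tb, "nope"), "not found")
})

test_that("co-dragging raises PCC; without it there is no systematic shift", {
  run <- function(seed, cd) {
    spec <- sheet_sim_spec(assoc_fraction = 0,
                           aggregation = list(n_aggregates = 10,
                                              co_drag_fraction = cd),
                           rng_seed = seed)
    base <- simulate_sheet(spec)
    cop <- simulate_crosslink(spec, base)
    roi <- sim_interior_roi(base)
    pearson(cop$img_a, cop$img_b, roi) -
      pearson(base$img_a, base$img_b, roi)
  }
  d_drag <- vapply(1:6, run, numeric(1), cd = 0.5)
  d_null <- vapply(1:6, run, numeric(1), cd = 0)
  expect_true(all(d_drag > 0.1))
  expect_lt(abs(mean(d_null)), 0.05)
})
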