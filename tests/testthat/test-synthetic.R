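test_that("background-only field reproduces the stated background level", {
  spec <- sheet_sim_spec(clusters_per_um2_A = 0, assoc_fraction = 0,
                         background_au = 10, noise_model = "gaussian",
                         noise_sd = 1, rng_seed = 11L)
  sim <- simulate_sheet(spec)
  # SE of the mean over 256^2 pixels is ~0.004; 10x that is still strict
  expect_lt(abs(mean(sim$img_a$pixels) - 10), 0.05)
  expect_equal(nrow(sim$truth$positions_a_nm), 0L)
})

test_that("degenerate association places every B point on an A centre", {
  spec <- sheet_sim_spec(assoc_fraction = 1, assoc_radius_nm = 0,
                         rng_seed = 2L)
  sim <- simulate_sheet(spec)
  d <- nn_oracle(sim$truth$positions_b_nm, sim$truth$positions_a_nm)
  expect_true(all(d < 1e-9))
  expect_true(all(sim$truth$assoc_flags_b))
})

test_that("true B counts follow the Poisson expectation for the density", {
  spec <- sheet_sim_spec(maxima_per_um2_B = 3, assoc_fraction = 0,
                         rng_seed = 1L)
  sim <- simulate_sheet(spec)
  lambda <- 3 * sim$truth$area_um2
  expect_lt(abs(nrow(sim$truth$positions_b_nm) - lambda), 3 * sqrt(lambda))
})

test_that("the same seed reproduces the field bit-identically", {
  spec <- sheet_sim_spec(rng_seed = 7L)
  s1 <- simulate_sheet(spec)
  s2 <- simulate_sheet(spec)
  expect_identical(s1$img_a$pixels, s2$img_a$pixels)
  expect_identical(s1$img_b$pixels, s2$img_b$pixels)
  expect_identical(s1$truth$positions_b_nm, s2$truth$positions_b_nm)
})

test_that("an unresolvable density triggers a warning", {
  spec <- sheet_sim_spec(maxima_per_um2_B = 300, rng_seed = 1L)
  expect_warning(simulate_sheet(spec), "unresolvable")
})

test_that("cross-linking rejects impossible aggregate counts", {
  spec <- sheet_sim_spec(aggregation = list(n_aggregates = 1e5,
                                            co_drag_fraction = 0.5),
                         rng_seed = 3L)
  sim <- simulate_sheet(spec)
  expect_error(simulate_crosslink(spec, sim), "must be smaller")
  spec2 <- sheet_sim_spec(rng_seed = 3L)
  expect_error(simulate_crosslink(spec2, sim), "aggregation")
})

test_that("full co-dragging moves every B point within a PSF of an aggregate", {
  spec <- sheet_sim_spec(aggregation = list(n_aggregates = 8,
                                            co_drag_fraction = 1),
                         rng_seed = 4L)
  sim <- simulate_sheet(spec)
  cop <- simulate_crosslink(spec, sim)
  d <- nn_oracle(cop$truth$positions_b_nm, cop$truth$aggregate_centers_nm)
  expect_true(all(d <= spec$psf_fwhm_nm))
})

test_that("aggregation raises the clustering readout (rSDM) of channel A", {
  ratios <- vapply(1:5, function(seed) {
    spec <- sheet_sim_spec(aggregation = list(n_aggregates = 10,
                                              co_drag_fraction = 0),
                           rng_seed = seed)
    sim <- simulate_sheet(spec)
    cop <- simulate_crosslink(spec, sim)
    roi <- sim_interior_roi(sim)
    rsdm(cop$img_a, roi) / rsdm(sim$img_a, roi)
  }, numeric(1))
  expect_true(all(ratios > 1))
})

test_that("noiseless FRAP traces sample the hyperbola exactly", {
  rate <- 1.77; dt <- 1 / rate
  t_half <- 5 * dt  # sampled exactly at the 5th postbleach frame
  tr <- normalize_trace(simulate_frap(t_half, offset = 0.2, recovery = 0.6,
                                      noise_sd = 0, seed = 1L))
  post <- tr$normalized[-(1:3)]
  expect_equal(post[5], 0.2 + 0.6 / 2, tolerance = 1e-12)
  expect_equal(tr$normalized[1:3], rep(1, 3), tolerance = 1e-12)
  # late-time plateau approaches offset + recovery
  t_fast <- normalize_trace(simulate_frap(0.01, offset = 0.2,
                                          recovery = 0.6, noise_sd = 0,
                                          seed = 1L))
  expect_equal(tail(t_fast$normalized, 1), 0.8, tolerance = 1e-3)
  expect_error(simulate_frap(-2), "positive")
})

test_that("lane simulation is exact at zero noise and zero for empty bands", {
  tb <- data.frame(lane = c("Ly", "Ly"), band = c("sAPPalpha", "APP_mature"),
                   true_au = c(120, 0))
  lanes <- simulate_lanes(tb, background_au = 50, noise_sd = 0)
  bm <- band_measurements(lanes)
  expect_equal(bm$corrected_au, c(120, 0))
})
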