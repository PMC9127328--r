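#' Simulation specification for a two-channel membrane sheet
#'
#' Describes a synthetic membrane-sheet field: channel A carries clustered
#' emitters (protein clusters of 20-30 molecules concentrated on a spot of
#' 65-85 nm, the regime reported for APP), channel B carries point-like
#' maxima at a stated density, a fraction of which is planted within
#' `assoc_radius_nm` of an A cluster centre. Defaults reproduce the imaging
#' conditions of the assay: 25 nm pixels, a point-spread function of 60-90 nm
#' FWHM (default 75), maxima densities of 2-5 per square micron, Poisson
#' counting noise over a low background.
#'
#' @param image_size_px integer pair `c(rows, cols)`.
#' @param pixel_size_nm physical pixel size (nm).
#' @param psf_fwhm_nm full width at half maximum of the isotropic Gaussian
#'   point-spread function (nm); must be at least one pixel.
#' @param clusters_per_um2_A channel-A cluster density (per square micron).
#' @param cluster_diameter_nm_A cluster spot size (nm); molecules scatter
#'   around the centre with SD = diameter/4, so ~95% fall inside it.
#' @param molecules_per_cluster_A integer range `c(lo, hi)`; per-cluster
#'   count drawn uniformly.
#' @param maxima_per_um2_B channel-B maxima density (per square micron).
#' @param assoc_fraction fraction of B maxima planted near an A centre.
#' @param assoc_radius_nm planting radius: associated B maxima are uniform
#'   in a disc of this radius around a random A centre.
#' @param background_au constant background level (a.u.).
#' @param noise_model `"poisson"` (counting noise, variance = signal) or
#'   `"gaussian"` (additive, SD = `noise_sd`).
#' @param noise_sd Gaussian noise SD (a.u.), used when
#'   `noise_model = "gaussian"`.
#' @param molecule_amp_au peak amplitude contributed by one channel-A
#'   molecule (a.u.).
#' @param b_amp_au peak amplitude of one channel-B emitter (a.u.).
#' @param aggregation optional list `(n_aggregates, co_drag_fraction)` used
#'   by [simulate_crosslink()].
#' @param rng_seed integer seed; the same seed gives bit-identical output.
#' @return An object of class `sheet_sim_spec`.
#' @export
sheet_sim_spec <- function(image_size_px = c(256L, 256L),
                           pixel_size_nm = 25,
                           psf_fwhm_nm = 75,
                           clusters_per_um2_A = 3.0,
                           cluster_diameter_nm_A = 75,
                           molecules_per_cluster_A = c(20L, 30L),
                           maxima_per_um2_B = 3.0,
                           assoc_fraction = 0.3,
                           assoc_radius_nm = 40,
                           background_au = 2,
                           noise_model = c("poisson", "gaussian"),
                           noise_sd = 1,
                           molecule_amp_au = 4,
                           b_amp_au = 50,
                           aggregation = NULL,
                           rng_seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(image_size_px) == 2L, all(image_size_px >= 32),
            pixel_size_nm > 0, psf_fwhm_nm > 0,
            clusters_per_um2_A >= 0, maxima_per_um2_B > 0,
            cluster_diameter_nm_A > 0,
            length(molecules_per_cluster_A) == 2L,
            molecules_per_cluster_A[1] >= 1,
            assoc_fraction >= 0, assoc_fraction <= 1,
            assoc_radius_nm >= 0, background_au >= 0, noise_sd >= 0,
            molecule_amp_au > 0, b_amp_au > 0)
  if (psf_fwhm_nm < pixel_size_nm)
    stop("psf_fwhm_nm must be at least one pixel (undersampled PSF)")
  structure(list(
    image_size_px = as.integer(image_size_px),
    pixel_size_nm = pixel_size_nm, psf_fwhm_nm = psf_fwhm_nm,
    clusters_per_um2_A = clusters_per_um2_A,
    cluster_diameter_nm_A = cluster_diameter_nm_A,
    molecules_per_cluster_A = as.integer(molecules_per_cluster_A),
    maxima_per_um2_B = maxima_per_um2_B,
    assoc_fraction = assoc_fraction, assoc_radius_nm = assoc_radius_nm,
    background_au = background_au, noise_model = noise_model,
    noise_sd = noise_sd, molecule_amp_au = molecule_amp_au,
    b_amp_au = b_amp_au, aggregation = aggregation,
    rng_seed = as.integer(rng_seed)), class = "sheet_sim_spec")
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Add isotropic Gaussian spots analytically (exact, no splat blurring).
# pos_px: matrix of continuous (row, col) positions, 0-based; amp: scalar or
# per-emitter peak amplitudes.
render_emitters <- function(nrow_px, ncol_px, pos_px, amp, sigma_px) {
  img <- matrix(0, nrow_px, ncol_px)
  if (is.null(pos_px) || nrow(pos_px) == 0L) return(img)
  amp <- rep_len(amp, nrow(pos_px))
  half <- ceiling(5 * sigma_px)
  for (i in seq_len(nrow(pos_px))) {
    r0 <- pos_px[i, 1]; c0 <- pos_px[i, 2]
    rows <- max(0L, floor(r0) - half):min(nrow_px - 1L, ceiling(r0) + half)
    cols <- max(0L, floor(c0) - half):min(ncol_px - 1L, ceiling(c0) + half)
    patch <- amp[i] *
      outer(exp(-(rows - r0)^2 / (2 * sigma_px^2)),
            exp(-(cols - c0)^2 / (2 * sigma_px^2)))
    img[rows + 1L, cols + 1L] <- img[rows + 1L, cols + 1L] + patch
  }
  img
}

apply_noise <- function(signal, spec) {
  img <- signal + spec$background_au
  if (spec$noise_model == "poisson")
    img[] <- stats::rpois(length(img), img)
  else if (spec$noise_sd > 0)
    img[] <- pmax(0, img + stats::rnorm(length(img), 0, spec$noise_sd))
  img
}

# Uniform point in a disc of radius r (nm), as a (row, col) offset.
runif_disc <- function(n, r) {
  th <- stats::runif(n, 0, 2 * pi)
  rad <- r * sqrt(stats::runif(n))
  cbind(rad * cos(th), rad * sin(th))
}

#' Simulate a two-channel membrane-sheet image pair with ground truth
#'
#' Channel A: cluster centres from a homogeneous Poisson process at the
#' stated density; per-cluster molecule counts uniform in the stated range;
#' molecule positions Gaussian around the centre (SD = diameter/4); all
#' emitters convolved with the Gaussian PSF. Channel B: point emitters at
#' the stated density, a planted fraction of which lies within
#' `assoc_radius_nm` of a random A centre. Emitters are placed with a margin
#' of twice the PSF FWHM from the field edge, so interior ROIs see the
#' nominal density without border clipping. Background and noise are then
#' applied. Deterministic given `rng_seed`.
#'
#' @param spec a [sheet_sim_spec()].
#' @return A list with elements `img_a`, `img_b` (micrographs) and `truth`,
#'   a list holding `positions_a_nm` / `positions_b_nm` (matrices of true
#'   centres, nm), `molecules_per_cluster`, `assoc_flags_b`, the placement
#'   margin and area, and the spec.
#' @export
simulate_sheet <- function(spec) {
  stopifnot(inherits(spec, "sheet_sim_spec"))
  set.seed(spec$rng_seed)
  H <- spec$image_size_px[1]; W <- spec$image_size_px[2]
  ps <- spec$pixel_size_nm
  sigma_px <- fwhm_to_sigma(spec$psf_fwhm_nm) / ps
  margin_px <- 2 * spec$psf_fwhm_nm / ps
  lo <- margin_px; hi_r <- H - 1 - margin_px; hi_c <- W - 1 - margin_px
  if (hi_r <= lo || hi_c <= lo) stop("image too small for the PSF margin")
  area_um2 <- (hi_r - lo) * (hi_c - lo) * (ps / 1000)^2

  psf_area_um2 <- pi * (spec$psf_fwhm_nm / 2000)^2
  if (max(spec$clusters_per_um2_A, spec$maxima_per_um2_B) * psf_area_um2 > 1)
    warning("maxima density exceeds one per PSF area: field is unresolvable")

  # channel A: clustered emitters
  n_clust <- stats::rpois(1, spec$clusters_per_um2_A * area_um2)
  centers_a <- cbind(stats::runif(n_clust, lo, hi_r),
                     stats::runif(n_clust, lo, hi_c))
  mpc <- if (n_clust > 0)
    sample(seq(spec$molecules_per_cluster_A[1],
               spec$molecules_per_cluster_A[2]), n_clust, replace = TRUE)
  else integer(0)
  scatter_sd_px <- (spec$cluster_diameter_nm_A / 4) / ps
  mols <- if (n_clust > 0) do.call(rbind, lapply(seq_len(n_clust), function(i)
    cbind(stats::rnorm(mpc[i], centers_a[i, 1], scatter_sd_px),
          stats::rnorm(mpc[i], centers_a[i, 2], scatter_sd_px))))
  else matrix(0, 0, 2)
  sig_a <- render_emitters(H, W, mols, spec$molecule_amp_au, sigma_px)

  # channel B: points, a planted fraction near A centres
  n_b <- stats::rpois(1, spec$maxima_per_um2_B * area_um2)
  assoc <- stats::runif(n_b) < spec$assoc_fraction
  if (n_clust == 0L && any(assoc)) {
    warning("no A clusters to associate with; assoc_fraction ignored")
    assoc[] <- FALSE
  }
  pos_b <- cbind(stats::runif(n_b, lo, hi_r), stats::runif(n_b, lo, hi_c))
  if (any(assoc)) {
    # one planted point per host cluster where possible: two planted B on
    # the same A cluster would merge under the PSF and the planted
    # fraction could not be recovered by any detector
    host <- sample.int(n_clust, sum(assoc), replace = sum(assoc) > n_clust)
    off_px <- runif_disc(sum(assoc), spec$assoc_radius_nm) / ps
    p <- centers_a[host, , drop = FALSE] + off_px
    p[, 1] <- pmin(pmax(p[, 1], lo), hi_r)
    p[, 2] <- pmin(pmax(p[, 2], lo), hi_c)
    pos_b[assoc, ] <- p
  }
  sig_b <- render_emitters(H, W, pos_b, spec$b_amp_au, sigma_px)

  img_a <- micrograph(apply_noise(sig_a, spec), ps, "A", "control")
  img_b <- micrograph(apply_noise(sig_b, spec), ps, "B", "control")
  truth <- list(positions_a_nm = centers_a * ps,
                positions_b_nm = pos_b * ps,
                molecules_per_cluster = mpc,
                assoc_flags_b = assoc,
                margin_px = margin_px, area_um2 = area_um2, spec = spec)
  list(img_a = img_a, img_b = img_b, truth = truth)
}

#' Simulate antibody cross-linking (coaggregation assay)
#'
#' Models the cross-link condition: all channel-A molecules are reassigned
#' to a small number of aggregate sites (fewer, brighter maxima, a more
#' clustered intensity pattern), and a fraction `co_drag_fraction` of
#' channel-B maxima is dragged to its nearest aggregate. `co_drag_fraction
#' = 0` models a partner that does not coaggregate; values > 0 raise the
#' Pearson correlation between the channels.
#'
#' @param spec a [sheet_sim_spec()] with `aggregation =
#'   list(n_aggregates =, co_drag_fraction =)` set.
#' @param sim the output of [simulate_sheet()] for the same spec (the
#'   pre-aggregation field).
#' @return Same shape as [simulate_sheet()]: `img_a`, `img_b`, `truth`
#'   (with `aggregate_centers_nm` added).
#' @export
simulate_crosslink <- function(spec, sim) {
  stopifnot(inherits(spec, "sheet_sim_spec"))
  agg <- spec$aggregation
  if (is.null(agg)) stop("spec$aggregation must be set for simulate_crosslink")
  n_agg <- agg$n_aggregates; co_drag <- agg$co_drag_fraction
  stopifnot(n_agg >= 1, co_drag >= 0, co_drag <= 1)
  tr <- sim$truth
  n_clust <- nrow(tr$positions_a_nm)
  if (n_agg >= n_clust)
    stop("n_aggregates (", n_agg, ") must be smaller than the number of A clusters (",
         n_clust, ")")
  set.seed(spec$rng_seed + 7919L)
  H <- spec$image_size_px[1]; W <- spec$image_size_px[2]
  ps <- spec$pixel_size_nm
  sigma_px <- fwhm_to_sigma(spec$psf_fwhm_nm) / ps
  scatter_sd_px <- (spec$cluster_diameter_nm_A / 4) / ps

  centers_px <- tr$positions_a_nm / ps
  agg_idx <- sample.int(n_clust, n_agg)
  agg_px <- centers_px[agg_idx, , drop = FALSE]

  # every cluster's molecules dumped onto one random aggregate site
  host <- sample.int(n_agg, n_clust, replace = TRUE)
  mols <- do.call(rbind, lapply(seq_len(n_clust), function(i) {
    k <- tr$molecules_per_cluster[i]
    cbind(stats::rnorm(k, agg_px[host[i], 1], scatter_sd_px),
          stats::rnorm(k, agg_px[host[i], 2], scatter_sd_px))
  }))
  sig_a <- render_emitters(H, W, mols, spec$molecule_amp_au, sigma_px)

  pos_b <- tr$positions_b_nm / ps
  dragged <- stats::runif(nrow(pos_b)) < co_drag
  if (any(dragged)) {
    d2 <- outer(pos_b[dragged, 1], agg_px[, 1], "-")^2 +
      outer(pos_b[dragged, 2], agg_px[, 2], "-")^2
    nearest <- max.col(-d2, ties.method = "first")
    jit <- runif_disc(sum(dragged), spec$psf_fwhm_nm / 4) / ps
    pos_b[dragged, ] <- agg_px[nearest, , drop = FALSE] + jit
  }
  sig_b <- render_emitters(H, W, pos_b, spec$b_amp_au, sigma_px)

  img_a <- micrograph(apply_noise(sig_a, spec), ps, "A", "CoP")
  img_b <- micrograph(apply_noise(sig_b, spec), ps, "B", "CoP")
  truth <- tr
  truth$aggregate_centers_nm <- agg_px * ps
  truth$positions_b_nm <- pos_b * ps
  truth$dragged_b <- dragged
  list(img_a = img_a, img_b = img_b, truth = truth)
}

#' Simulate a FRAP recovery trace
#'
#' Samples the hyperbolic recovery model `y(t) = offset + recovery * t / (t
#' + t_half)` at the acquisition rate, prefixed by prebleach frames at 1.0,
#' and wraps it into raw bleach/background/reference channels so the full
#' normalization path can be exercised. The default layout matches the
#' acquisition protocol: 3 prebleach and 117 postbleach frames at 1.77 Hz.
#'
#' @param t_half_s half-time of recovery (s), must be positive.
#' @param offset immobile baseline right after the bleach (normalized units).
#' @param recovery maximal recovery amplitude (normalized units).
#' @param n_frames number of postbleach frames.
#' @param rate_hz acquisition rate.
#' @param noise_sd Gaussian noise SD on the normalized trace.
#' @param n_prebleach number of prebleach frames.
#' @param seed integer seed.
#' @return A [frap_trace()] with attribute `truth` (the model parameters).
#' @export
simulate_frap <- function(t_half_s, offset = 0.2, recovery = 0.6,
                          n_frames = 117L, rate_hz = 1.77, noise_sd = 0.02,
                          n_prebleach = 3L, seed = 1L) {
  if (t_half_s <= 0) stop("t_half_s must be positive")
  stopifnot(n_frames >= 10L, rate_hz > 0)
  set.seed(seed)
  dt <- 1 / rate_hz
  n <- n_prebleach + n_frames
  times <- (seq_len(n) - 1) * dt
  t_post <- seq_len(n_frames) * dt  # first postbleach frame at t = dt
  y <- c(rep(1, n_prebleach),
         offset + recovery * t_post / (t_post + t_half_s))
  y <- y + stats::rnorm(n, 0, noise_sd)
  level <- 200; bg <- 20
  trace <- frap_trace(times_s = times,
                      bleach = y * level + bg,
                      background = rep(bg, n),
                      reference = level + stats::rnorm(n, 0, noise_sd * level / 4),
                      n_prebleach = n_prebleach)
  attr(trace, "truth") <- list(t_half_s = t_half_s, offset = offset,
                               recovery = recovery)
  trace
}

#' Simulate western-blot lane measurements
#'
#' Produces integrated band and matched local-background readings for each
#' lane/band pair, with multiplicative-style Gaussian measurement noise
#' (SD = `noise_sd` times the quantity measured).
#'
#' @param true_bands data frame with columns `lane`, `band`, `true_au`.
#' @param background_au local background level under each band ROI.
#' @param noise_sd relative measurement noise (0 = exact).
#' @param seed integer seed.
#' @return Data frame with columns `lane`, `band`, `integrated_au`,
#'   `background_au` suitable for [band_measurements()].
#' @export
simulate_lanes <- function(true_bands, background_au = 100, noise_sd = 0,
                           seed = 1L) {
  stopifnot(all(c("lane", "band", "true_au") %in% names(true_bands)))
  set.seed(seed)
  n <- nrow(true_bands)
  integ <- true_bands$true_au + background_au +
    stats::rnorm(n, 0, noise_sd * pmax(true_bands$true_au, background_au))
  bg <- background_au + stats::rnorm(n, 0, noise_sd * background_au)
  data.frame(lane = true_bands$lane, band = true_bands$band,
             integrated_au = integ, background_au = bg,
             stringsAsFactors = FALSE)
}
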