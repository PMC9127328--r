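#' Analysis configuration
#'
#' Bundles the tunable parameters of the detection and association pipeline.
#' Defaults follow the published procedure: Gaussian pre-smoothing with
#' sigma = 1 px, a per-channel mask threshold of a few a.u. (the published
#' range is 1 to 5 a.u., depending on experiment and channel), 15 x 3 px
#' line scans for FWHM sizing with an R-squared floor of 0.8, and a 50 nm
#' close-association cutoff.
#'
#' @param blur_sigma_px Gaussian smoothing sigma applied before the mask
#'   threshold (pixels).
#' @param maxima_threshold_au mask threshold on the smoothed image (a.u.).
#' @param close_cutoff_nm distance below which a query maximum counts as
#'   closely associated with a target maximum (nm).
#' @param linescan_length_px,linescan_width_px line-scan geometry for the
#'   FWHM fit; length must be odd.
#' @param r2_min minimum Gaussian-fit R-squared for a FWHM to be accepted.
#' @param histogram_bin_nm bin width of distance histograms (nm); the
#'   default is one STED pixel.
#' @param rng_seed integer seed used by every stochastic pipeline step.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(blur_sigma_px = 1, maxima_threshold_au = 2,
                            close_cutoff_nm = 50, linescan_length_px = 15L,
                            linescan_width_px = 3L, r2_min = 0.8,
                            histogram_bin_nm = 25, rng_seed = 1L) {
  cfg <- list(blur_sigma_px = blur_sigma_px,
              maxima_threshold_au = maxima_threshold_au,
              close_cutoff_nm = close_cutoff_nm,
              linescan_length_px = as.integer(linescan_length_px),
              linescan_width_px = as.integer(linescan_width_px),
              r2_min = r2_min, histogram_bin_nm = histogram_bin_nm,
              rng_seed = as.integer(rng_seed))
  for (nm in setdiff(names(cfg), "rng_seed"))
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] <= 0)
      stop("`", nm, "` must be a positive scalar")
  if (cfg$r2_min >= 1) stop("`r2_min` must lie in (0, 1)")
  if (cfg$linescan_length_px %% 2L == 0L)
    stop("`linescan_length_px` must be odd")
  structure(cfg, class = "analysis_config")
}

#' Read / write an analysis configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_config()] returns an `analysis_config`;
#'   [write_config()] returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(analysis_config, vals)
}

#' @rdname read_config
#' @param cfg an `analysis_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "analysis_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
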