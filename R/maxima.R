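#' Detect intensity maxima with subpixel localization
#'
#' The detection procedure mirrors the established membrane-sheet analysis:
#'
#' 1. a working copy of the image is smoothed with a Gaussian
#'    (`cfg$blur_sigma_px`, default 1 px) to suppress pixel noise;
#' 2. a binary mask is made by thresholding the smoothed image at
#'    `cfg$maxima_threshold_au`;
#' 3. within each connected mask component the local maxima of the smoothed
#'    image are identified ("pixel maxima"), with a minimum separation of
#'    2 px and plateau ties broken by the smallest `(row, col)`;
#' 4. a 5-pixel-diameter circular ROI (the 13-pixel digital disc) is placed
#'    on each pixel maximum and the mean intensity inside it is measured on
#'    the *unsmoothed* image;
#' 5. the subpixel position is the intensity centre of mass within that
#'    disc, computed on raw intensities after subtracting the local disc
#'    minimum (so flat background cannot drag the centroid);
#' 6. the maxima density is the count divided by the ROI area in square
#'    microns.
#'
#' Maxima closer than 2 px to the image border are flagged
#' `excluded_reason = "border"` and are not localized; maxima whose disc
#' mean does not exceed the threshold are dropped. Detection is
#' deterministic and order-independent.
#'
#' @param img a [micrograph()].
#' @param roi an [roi_rect()]/[roi_polygon()]; default is the whole image.
#' @param cfg an [analysis_config()].
#' @return An object of class `maxima_set`: list with `maxima` (data frame:
#'   `row_px`, `col_px` integer pixel maxima, `row_subpx`, `col_subpx`
#'   continuous positions, `row_nm`, `col_nm`, `intensity_au`, `fwhm_nm`,
#'   `fwhm_r2`, `excluded_reason`), `density_per_um2`, `roi`,
#'   `pixel_size_nm`, `area_um2`.
#' @export
detect_maxima <- function(img, roi = NULL, cfg = analysis_config()) {
  stopifnot(inherits(img, "micrograph"), inherits(cfg, "analysis_config"))
  px <- img$pixels
  H <- nrow(px); W <- ncol(px)
  if (is.null(roi)) roi <- roi_rect(0, 0, H, W)
  mask_roi <- roi_mask(roi, H, W)
  area_um2 <- sum(mask_roi) * (img$pixel_size_nm / 1000)^2

  sm <- if (cfg$blur_sigma_px > 0)
    as.matrix(EBImage::gblur(px, sigma = cfg$blur_sigma_px,
                             boundary = "replicate"))
  else px
  above <- sm > cfg$maxima_threshold_au
  if (!any(above))
    return(new_maxima_set(empty_maxima_df(), roi, img$pixel_size_nm,
                          area_um2))
  comp <- as.matrix(EBImage::bwlabel(above))

  # local maxima of the smoothed image within the mask (8-neighbourhood,
  # >= so plateaus survive to the tie-break below)
  pad <- matrix(-Inf, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- sm
  ctr <- pad[2:(H + 1L), 2:(W + 1L)]
  is_max <- above
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- pad[(2:(H + 1L)) + dr, (2:(W + 1L)) + dc]
    is_max <- is_max & (ctr >= nb)
  }
  cand <- which(is_max, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(new_maxima_set(empty_maxima_df(), roi, img$pixel_size_nm,
                          area_um2))
  vals <- sm[cand]
  # deterministic order: intensity desc, then smallest (row, col)
  ord <- order(-vals, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  # greedy non-maximum suppression, minimum separation 2 px
  keep <- logical(nrow(cand))
  acc_r <- numeric(0); acc_c <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    if (length(acc_r) == 0L ||
        all((acc_r - cand[i, 1])^2 + (acc_c - cand[i, 2])^2 >= 4)) {
      keep[i] <- TRUE
      acc_r <- c(acc_r, cand[i, 1]); acc_c <- c(acc_c, cand[i, 2])
    }
  }
  cand <- cand[keep, , drop = FALSE]

  # keep maxima whose pixel lies inside the ROI
  in_roi <- mask_roi[cand]
  cand <- cand[in_roi, , drop = FALSE]
  if (nrow(cand) == 0L)
    return(new_maxima_set(empty_maxima_df(), roi, img$pixel_size_nm,
                          area_um2))

  disc <- disc_offsets()
  out <- lapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1]; c <- cand[i, 2]  # 1-based
    if (r <= 2L || r >= H - 1L || c <= 2L || c >= W - 1L)
      return(data.frame(row_px = r - 1L, col_px = c - 1L,
                        row_subpx = NA_real_, col_subpx = NA_real_,
                        intensity_au = NA_real_,
                        excluded_reason = "border",
                        stringsAsFactors = FALSE))
    rr <- r + disc[, 1]; cc <- c + disc[, 2]
    w_raw <- px[cbind(rr, cc)]
    mean_int <- mean(w_raw)
    if (mean_int <= cfg$maxima_threshold_au) return(NULL)
    w <- w_raw - min(w_raw)
    if (sum(w) <= 0) {
      com_r <- r - 1; com_c <- c - 1  # flat disc: fall back to the pixel
    } else {
      com_r <- sum(w * (rr - 1)) / sum(w)
      com_c <- sum(w * (cc - 1)) / sum(w)
    }
    data.frame(row_px = r - 1L, col_px = c - 1L,
               row_subpx = com_r, col_subpx = com_c,
               intensity_au = mean_int, excluded_reason = NA_character_,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(df)) df <- empty_maxima_df()
  df <- df[order(df$row_px, df$col_px), , drop = FALSE]
  rownames(df) <- NULL
  df$row_nm <- df$row_subpx * img$pixel_size_nm
  df$col_nm <- df$col_subpx * img$pixel_size_nm
  df$fwhm_nm <- NA_real_
  df$fwhm_r2 <- NA_real_
  new_maxima_set(df, roi, img$pixel_size_nm, area_um2)
}

# the 13-pixel digital disc of diameter 5 (dr^2 + dc^2 <= 4)
disc_offsets <- function() {
  g <- expand.grid(dr = -2:2, dc = -2:2)
  as.matrix(g[g$dr^2 + g$dc^2 <= 4, ])
}

empty_maxima_df <- function() {
  data.frame(row_px = integer(0), col_px = integer(0),
             row_subpx = numeric(0), col_subpx = numeric(0),
             intensity_au = numeric(0), excluded_reason = character(0),
             row_nm = numeric(0), col_nm = numeric(0),
             fwhm_nm = numeric(0), fwhm_r2 = numeric(0),
             stringsAsFactors = FALSE)
}

new_maxima_set <- function(df, roi, pixel_size_nm, area_um2) {
  n_loc <- sum(is.na(df$excluded_reason))
  structure(list(maxima = df, roi = roi, pixel_size_nm = pixel_size_nm,
                 area_um2 = area_um2,
                 density_per_um2 = n_loc / area_um2),
            class = "maxima_set")
}

#' @export
print.maxima_set <- function(x, ...) {
  n_ok <- sum(is.na(x$maxima$excluded_reason))
  cat(sprintf(
    "<maxima_set> %d maxima (%d excluded) over %.2f um^2 -> %.3f /um^2\n",
    nrow(x$maxima), nrow(x$maxima) - n_ok, x$area_um2, x$density_per_um2))
  invisible(x)
}

# Localized positions (nm) of the non-excluded maxima, as a matrix.
maxima_positions_nm <- function(set) {
  stopifnot(inherits(set, "maxima_set"))
  ok <- is.na(set$maxima$excluded_reason)
  cbind(set$maxima$row_nm[ok], set$maxima$col_nm[ok])
}

#' Maxima density over the analyzed ROI
#'
#' Count of localized maxima normalized to the ROI area; the area is the
#' ROI pixel count times the squared pixel size.
#'
#' @param set a `maxima_set`.
#' @return Density in maxima per square micron.
#' @export
maxima_density <- function(set) {
  stopifnot(inherits(set, "maxima_set"))
  set$density_per_um2
}

#' Size maxima by Gaussian line-scan FWHM fits
#'
#' For each localized maximum, a vertical and a horizontal line scan
#' (default 15 x 3 px, averaged across the 3-px width) is centred on the
#' pixel maximum and fitted to a Gaussian plus constant offset. The FWHM of
#' the better-fitting profile (higher R-squared) is reported in nm. A
#' maximum is excluded when the best R-squared falls below `cfg$r2_min`
#' (`"low_r2"`) or the fitted peak centre lies outside the middle third of
#' the scan (`"noncentered"`); scans that do not fit inside the image are
#' excluded as `"border"`.
#'
#' @param img the [micrograph()] the maxima came from (fits use raw
#'   intensities).
#' @param set a `maxima_set` from [detect_maxima()].
#' @param cfg an [analysis_config()].
#' @return The `maxima_set` with `fwhm_nm`, `fwhm_r2` and
#'   `excluded_reason` filled in.
#' @export
fit_fwhm <- function(img, set, cfg = analysis_config()) {
  stopifnot(inherits(img, "micrograph"), inherits(set, "maxima_set"))
  px <- img$pixels
  H <- nrow(px); W <- ncol(px)
  L <- cfg$linescan_length_px; wd <- cfg$linescan_width_px
  hl <- (L - 1L) %/% 2L; hw <- (wd - 1L) %/% 2L
  df <- set$maxima
  for (i in seq_len(nrow(df))) {
    if (!is.na(df$excluded_reason[i])) next
    r <- df$row_px[i] + 1L; c <- df$col_px[i] + 1L  # 1-based
    if (r - hl < 1L || r + hl > H || c - hl < 1L || c + hl > W ||
        r - hw < 1L || r + hw > H || c - hw < 1L || c + hw > W) {
      df$excluded_reason[i] <- "border"
      next
    }
    prof_h <- colMeans(px[(r - hw):(r + hw), (c - hl):(c + hl), drop = FALSE])
    prof_v <- rowMeans(px[(r - hl):(r + hl), (c - hw):(c + hw), drop = FALSE])
    fit_h <- fit_gauss_profile(prof_h)
    fit_v <- fit_gauss_profile(prof_v)
    best <- if (fit_h$r2 >= fit_v$r2) fit_h else fit_v
    df$fwhm_r2[i] <- best$r2
    if (!best$ok || best$r2 < cfg$r2_min) {
      df$excluded_reason[i] <- "low_r2"
    } else if (best$mu < (L - 1) / 3 || best$mu > 2 * (L - 1) / 3) {
      df$excluded_reason[i] <- "noncentered"
    } else {
      df$fwhm_nm[i] <- 2 * sqrt(2 * log(2)) * best$sigma * img$pixel_size_nm
    }
  }
  new_maxima_set(df, set$roi, set$pixel_size_nm, set$area_um2)
}

# Gaussian + offset fit of a 1D profile; returns sigma/mu in profile
# coordinates (0-based), R^2 against the data, and a convergence flag.
fit_gauss_profile <- function(y) {
  x <- seq_along(y) - 1
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) return(list(ok = FALSE, r2 = -Inf, sigma = NA, mu = NA))
  start <- list(b = min(y), a = max(y) - min(y),
                mu = which.max(y) - 1, s = 2)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ b + a * exp(-(x - mu)^2 / (2 * s^2)),
                      start = start,
                      lower = c(b = -Inf, a = 0, mu = -1, s = 0.3),
                      upper = c(b = Inf, a = Inf, mu = max(x) + 1,
                                s = length(y)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(ok = FALSE, r2 = -Inf, sigma = NA, mu = NA))
  cf <- stats::coef(fit)
  r2 <- 1 - sum(stats::resid(fit)^2) / sst
  list(ok = TRUE, r2 = r2, sigma = unname(cf["s"]), mu = unname(cf["mu"]))
}

#' Write / read a maxima table as CSV
#'
#' @param set a `maxima_set`.
#' @param path output CSV path.
#' @export
write_maxima <- function(set, path) {
  stopifnot(inherits(set, "maxima_set"))
  utils::write.csv(set$maxima, path, row.names = FALSE)
  invisible(path)
}
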