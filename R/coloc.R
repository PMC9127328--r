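#' Background-corrected mean intensity
#'
#' Mean intensity of the membrane ROI minus the mean of a background ROI
#' placed next to the membrane sheet. A negative result is returned as is
#' (with a warning) — it signals that the background ROI was brighter than
#' the sheet.
#'
#' @param img a [micrograph()].
#' @param membrane_roi,background_roi disjoint ROIs inside the image.
#' @return Background-corrected mean intensity (a.u.).
#' @export
corrected_mean <- function(img, membrane_roi, background_roi) {
  stopifnot(inherits(img, "micrograph"))
  H <- nrow(img$pixels); W <- ncol(img$pixels)
  mm <- roi_mask(membrane_roi, H, W)
  bm <- roi_mask(background_roi, H, W)
  if (any(mm & bm)) stop("membrane and background ROIs overlap")
  val <- mean(img$pixels[mm]) - mean(img$pixels[bm])
  if (val < 0)
    warning("background exceeds membrane signal: corrected mean is negative")
  val
}

#' Pearson correlation between two channels in an ROI
#'
#' Standard Pearson correlation of pixel intensities over the ROI, the ROI
#' being placed in one reference channel and propagated unchanged to the
#' other. No intensity thresholding is applied.
#'
#' @param img_a,img_b registered [micrograph()]s.
#' @param roi the ROI (at least 2 pixels).
#' @return Correlation in `[-1, 1]`, or `NA` with attribute `reason` when
#'   either channel has zero variance in the ROI.
#' @export
pearson <- function(img_a, img_b, roi) {
  check_registered(img_a, img_b)
  m <- roi_mask(roi, nrow(img_a$pixels), ncol(img_a$pixels))
  if (sum(m) < 2L) stop("ROI must contain at least 2 pixels")
  a <- img_a$pixels[m]; b <- img_b$pixels[m]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "zero variance in at least one channel"
    return(out)
  }
  stats::cor(a, b)
}

#' Relative standard deviation of the mean (rSDM)
#'
#' SD of the pixel intensities in an ROI divided by their mean: a
#' scale-free readout of signal clustering. A uniform ROI gives 0;
#' concentrating the same integrated intensity onto fewer, brighter maxima
#' raises it.
#'
#' @param img a [micrograph()].
#' @param roi the ROI.
#' @return rSDM (unitless), or `NA` with attribute `reason` when the ROI
#'   mean is not positive.
#' @export
rsdm <- function(img, roi) {
  stopifnot(inherits(img, "micrograph"))
  v <- roi_pixels(img, roi)
  mu <- mean(v)
  if (mu <= 0) {
    out <- NA_real_
    attr(out, "reason") <- "ROI mean intensity is not positive"
    return(out)
  }
  stats::sd(v) / mu
}

#' Normalize per-replicate values to a reference condition
#'
#' Expresses every replicate value as a percentage of the reference
#' condition's mean (the reference maps to 100% by construction) and
#' summarizes each condition as mean +/- SD across replicates.
#'
#' @param values data frame with columns `condition` and `value` (one row
#'   per replicate, e.g. per experiment).
#' @param reference_condition label of the 100% condition (e.g.
#'   `"fixed"`).
#' @return List with `per_replicate` (input plus `percent_of_reference`)
#'   and `summary` (condition, n, mean and SD of the percentages).
#' @export
normalize_to_reference <- function(values, reference_condition) {
  stopifnot(all(c("condition", "value") %in% names(values)))
  ref <- values$value[values$condition == reference_condition]
  if (length(ref) == 0L)
    stop("reference condition '", reference_condition, "' not found")
  ref_mean <- mean(ref)
  if (ref_mean == 0) stop("reference mean is zero; cannot normalize")
  values$percent_of_reference <- values$value / ref_mean * 100
  agg <- do.call(rbind, lapply(split(values, values$condition), function(g)
    data.frame(condition = g$condition[1], n = nrow(g),
               mean_percent = mean(g$percent_of_reference),
               sd_percent = stats::sd(g$percent_of_reference),
               stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  list(per_replicate = values, summary = agg,
       reference_condition = reference_condition)
}

#' Per-sheet colocalization statistics
#'
#' Computes the coaggregation readouts for one membrane sheet: the
#' background-corrected mean intensities, the Pearson correlation between
#' the channels and the rSDM of each channel, over the membrane ROI.
#'
#' @param img_a,img_b registered [micrograph()]s.
#' @param membrane_roi the membrane-sheet ROI.
#' @param background_roi optional background ROI for corrected means.
#' @return One-row data frame with `condition`, `pcc`, `rsdm_a`, `rsdm_b`
#'   and (when a background ROI is given) `mean_a`, `mean_b`.
#' @export
sheet_stats <- function(img_a, img_b, membrane_roi, background_roi = NULL) {
  check_registered(img_a, img_b)
  out <- data.frame(condition = img_a$condition,
                    pcc = as.numeric(pearson(img_a, img_b, membrane_roi)),
                    rsdm_a = as.numeric(rsdm(img_a, membrane_roi)),
                    rsdm_b = as.numeric(rsdm(img_b, membrane_roi)),
                    stringsAsFactors = FALSE)
  if (!is.null(background_roi)) {
    out$mean_a <- corrected_mean(img_a, membrane_roi, background_roi)
    out$mean_b <- corrected_mean(img_b, membrane_roi, background_roi)
  }
  out
}
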