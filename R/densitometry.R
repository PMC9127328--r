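#' Western-blot band measurements
#'
#' Validates a band-intensity table and computes background-corrected
#' intensities. Each band ROI has a matched background ROI of identical
#' area placed in the same lane, and the corrected intensity is their
#' difference. Input is a measurement table, not gel images (band ROIs are
#' drawn by hand in the acquisition software).
#'
#' @param tbl data frame with columns `lane`, `band`, `integrated_au`,
#'   `background_au`. Recognized band labels for the cleavage assay:
#'   `sAPPalpha`, `APP_mature`, `APP_immature` (anything else is carried
#'   through as `other`).
#' @return The table with a `corrected_au` column added.
#' @export
band_measurements <- function(tbl) {
  need <- c("lane", "band", "integrated_au", "background_au")
  if (!all(need %in% names(tbl)))
    stop("band table must have columns: ", paste(need, collapse = ", "))
  stopifnot(is.numeric(tbl$integrated_au), is.numeric(tbl$background_au))
  tbl$corrected_au <- tbl$integrated_au - tbl$background_au
  tbl
}

#' alpha-cleavage ratio from corrected band intensities
#'
#' The soluble ectodomain signal, summed over the lysate and supernatant
#' lanes, is divided by the full-length signal (sum of mature and immature
#' bands):
#' `(sAPPalpha_Ly + sAPPalpha_Sn) / (APP_mature + APP_immature)`.
#'
#' @param bands a [band_measurements()] table for one construct and
#'   replicate; `sAPPalpha` rows may appear once (a single compartment) or
#'   twice (lysate + supernatant) and are summed.
#' @return The cleavage ratio (unitless), or `NA` with attribute `reason`
#'   when the full-length denominator is not positive.
#' @export
cleavage_ratio <- function(bands) {
  if (!"corrected_au" %in% names(bands)) bands <- band_measurements(bands)
  pick <- function(lbl) {
    v <- bands$corrected_au[bands$band == lbl]
    if (length(v) == 0L) stop("band '", lbl, "' missing from table")
    sum(v)
  }
  num <- pick("sAPPalpha")
  den <- pick("APP_mature") + pick("APP_immature")
  if (den <= 0) {
    out <- NA_real_
    attr(out, "reason") <- "full-length APP intensity is not positive"
    return(out)
  }
  num / den
}

#' Express cleavage ratios as percent of wildtype
#'
#' Each replicate's ratio is divided by the wildtype ratio of the same
#' replicate and scaled to percent (wildtype = 100%), then summarized as
#' mean +/- SD per construct.
#'
#' @param ratios data frame with columns `construct`, `replicate`,
#'   `ratio`.
#' @param wt_label construct label of the wildtype reference.
#' @return List with `per_replicate` (adds `percent_of_wt`) and `summary`
#'   (construct, n, mean, SD).
#' @export
percent_of_wildtype <- function(ratios, wt_label = "APP") {
  stopifnot(all(c("construct", "replicate", "ratio") %in% names(ratios)))
  wt <- ratios[ratios$construct == wt_label, c("replicate", "ratio")]
  if (nrow(wt) == 0L) stop("wildtype construct '", wt_label, "' not found")
  names(wt)[2] <- "wt_ratio"
  merged <- merge(ratios, wt, by = "replicate")
  if (any(merged$wt_ratio <= 0))
    stop("wildtype ratio must be positive in every replicate")
  merged$percent_of_wt <- merged$ratio / merged$wt_ratio * 100
  agg <- do.call(rbind, lapply(split(merged, merged$construct), function(g)
    data.frame(construct = g$construct[1], n = nrow(g),
               mean_percent = mean(g$percent_of_wt),
               sd_percent = stats::sd(g$percent_of_wt),
               stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  list(per_replicate = merged, summary = agg, wt_label = wt_label)
}
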