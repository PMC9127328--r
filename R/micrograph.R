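#' Micrograph: a single-channel 2D fluorescence image
#'
#' A `micrograph` couples a rectangular matrix of non-negative intensities
#' (arbitrary units, a.u.) with the physical pixel size in nanometres and
#' free-text channel/condition labels. All downstream operations consume
#' this type; none read files directly.
#'
#' Coordinate convention used throughout the package: positions are 0-based
#' `(row, col)` with the centre of pixel `(i, j)` at continuous coordinate
#' `(i, j)`; physical positions are `px * pixel_size_nm`.
#'
#' @param pixels numeric matrix of intensities, at least 16 x 16, finite and
#'   non-negative.
#' @param pixel_size_nm positive scalar, physical edge length of one pixel.
#' @param channel free-text channel label (e.g. `"APP"`, `"ADAM10"`).
#' @param condition free-text condition label (e.g. `"fixed"`, `"control"`,
#'   `"CoP"`).
#' @return An object of class `micrograph`.
#' @export
micrograph <- function(pixels, pixel_size_nm, channel = "unknown",
                       condition = "none") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 16L || ncol(pixels) < 16L)
    stop("micrograph must be at least 16 x 16 pixels, got ",
         nrow(pixels), " x ", ncol(pixels))
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("micrograph intensities must be finite")
  if (any(pixels < 0))
    stop("micrograph intensities must be non-negative")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    stop("`pixel_size_nm` must be a positive scalar")
  structure(
    list(pixels = pixels, pixel_size_nm = as.numeric(pixel_size_nm),
         channel = as.character(channel), condition = as.character(condition)),
    class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf(
    "<micrograph> %d x %d px @ %g nm/px | channel: %s | condition: %s\n",
    nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm, x$channel, x$condition))
  cat(sprintf("  intensity range [%g, %g] a.u.\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.micrograph <- function(x) dim(x$pixels)

#' Read a grayscale TIFF into micrographs
#'
#' Reads a single-plane or multi-page grayscale TIFF. Integer-typed TIFFs are
#' read bit-exactly (detector counts as stored); RGB images are rejected.
#'
#' @param path path to a readable TIFF file.
#' @param pixel_size_nm physical pixel size in nm (25 for STED/confocal data,
#'   64.5 for the epifluorescence camera, by default must be supplied).
#' @param channel channel label applied to every page, or a character vector
#'   with one label per page.
#' @param condition condition label.
#' @return A `micrograph` for a single-page file, otherwise a list of
#'   `micrograph`s (one per page).
#' @export
read_micrograph <- function(path, pixel_size_nm, channel = "unknown",
                            condition = "none") {
  if (!file.exists(path))
    stop("cannot read micrograph: file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop("cannot read micrograph '", path, "': ",
                           conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  chans <- rep_len(channel, length(pages))
  out <- lapply(seq_along(pages), function(i) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] == 1L) p <- p[, , 1L]
      else stop("RGB/multi-sample TIFF not supported: ", path)
    }
    micrograph(p, pixel_size_nm, chans[i], condition)
  })
  if (length(out) == 1L) out[[1L]] else out
}

#' Write a micrograph to a 16-bit grayscale TIFF
#'
#' Integer intensities in `[0, 65535]` round-trip bit-exactly through
#' [read_micrograph()].
#'
#' @param img a `micrograph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(img, path) {
  stopifnot(inherits(img, "micrograph"))
  px <- img$pixels
  if (max(px) > 65535)
    stop("intensities exceed 16-bit range; rescale before writing")
  tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

# Guard for every two-channel operation: equal shape and pixel size.
check_registered <- function(a, b) {
  stopifnot(inherits(a, "micrograph"), inherits(b, "micrograph"))
  if (!identical(dim(a$pixels), dim(b$pixels)))
    stop("channels are not registered: image shapes differ (",
         paste(dim(a$pixels), collapse = "x"), " vs ",
         paste(dim(b$pixels), collapse = "x"), ")")
  if (a$pixel_size_nm != b$pixel_size_nm)
    stop("channels are not registered: pixel sizes differ")
  invisible(TRUE)
}
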