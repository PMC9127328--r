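#' Regions of interest
#'
#' ROIs delimit the membrane sheet, a background region next to it, the
#' bleached FRAP region or an unbleached reference. Rectangles are 0-based
#' half-open in `(row, col)` pixel coordinates; polygons are closed vertex
#' lists in the same continuous coordinate system (pixel centres at
#' integers).
#'
#' @param row0,col0 top-left corner (0-based).
#' @param height,width extent in pixels; the rectangle covers rows
#'   `row0 .. row0+height-1` and columns `col0 .. col0+width-1`.
#' @param role one of `"membrane"`, `"background"`, `"bleach"`,
#'   `"reference"`.
#' @return An object of class `roi`.
#' @export
roi_rect <- function(row0, col0, height, width, role = "membrane") {
  stopifnot(height >= 1, width >= 1, row0 >= 0, col0 >= 0)
  structure(list(shape = "rect", row0 = as.numeric(row0),
                 col0 = as.numeric(col0), height = as.numeric(height),
                 width = as.numeric(width), role = match_role(role)),
            class = "roi")
}

#' @rdname roi_rect
#' @param vertices two-column matrix of `(row, col)` polygon vertices
#'   (0-based, continuous); the polygon is closed implicitly.
#' @export
roi_polygon <- function(vertices, role = "membrane") {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("polygon ROI needs a two-column (row, col) matrix with >= 3 vertices")
  structure(list(shape = "polygon", vertices = vertices,
                 role = match_role(role)),
            class = "roi")
}

match_role <- function(role)
  match.arg(role, c("membrane", "background", "bleach", "reference"))

#' @export
print.roi <- function(x, ...) {
  if (x$shape == "rect")
    cat(sprintf("<roi> rect (%g,%g) %gx%g px [%s]\n",
                x$row0, x$col0, x$height, x$width, x$role))
  else
    cat(sprintf("<roi> polygon, %d vertices [%s]\n",
                nrow(x$vertices), x$role))
  invisible(x)
}

# Logical mask of the ROI on an image grid; TRUE where the pixel centre is
# inside. Polygon membership uses mgcv's even-odd rule.
roi_mask <- function(roi, nrow_px, ncol_px) {
  stopifnot(inherits(roi, "roi"))
  m <- matrix(FALSE, nrow_px, ncol_px)
  if (roi$shape == "rect") {
    rows <- seq.int(roi$row0 + 1L, roi$row0 + roi$height)
    cols <- seq.int(roi$col0 + 1L, roi$col0 + roi$width)
    if (min(rows) < 1L || max(rows) > nrow_px ||
        min(cols) < 1L || max(cols) > ncol_px)
      stop("ROI extends outside image bounds")
    m[rows, cols] <- TRUE
  } else {
    v <- roi$vertices
    if (min(v) < -0.5 || max(v[, 1]) > nrow_px - 0.5 ||
        max(v[, 2]) > ncol_px - 0.5)
      stop("ROI extends outside image bounds")
    bnd <- rbind(v, v[1L, , drop = FALSE])
    grid <- cbind(rep(seq_len(nrow_px) - 1, ncol_px),
                  rep(seq_len(ncol_px) - 1, each = nrow_px))
    inside <- mgcv::in.out(bnd, grid)
    m[] <- inside
  }
  if (!any(m)) stop("ROI covers no pixel")
  m
}

# ROI area in um^2 given the pixel size.
roi_area_um2 <- function(roi, nrow_px, ncol_px, pixel_size_nm) {
  sum(roi_mask(roi, nrow_px, ncol_px)) * (pixel_size_nm / 1000)^2
}

# Pixel values of an image inside an ROI.
roi_pixels <- function(img, roi) {
  stopifnot(inherits(img, "micrograph"))
  img$pixels[roi_mask(roi, nrow(img$pixels), ncol(img$pixels))]
}

# Flip an ROI together with a both-axes image flip (180 degree rotation).
flip_roi <- function(roi, nrow_px, ncol_px) {
  if (roi$shape == "rect")
    roi_rect(nrow_px - roi$row0 - roi$height,
             ncol_px - roi$col0 - roi$width,
             roi$height, roi$width, roi$role)
  else
    roi_polygon(cbind(nrow_px - 1 - roi$vertices[, 1],
                      ncol_px - 1 - roi$vertices[, 2]), roi$role)
}

roi_to_list <- function(r) {
  if (r$shape == "rect")
    list(shape = "rect", row0 = r$row0, col0 = r$col0,
         height = r$height, width = r$width, role = r$role)
  else
    list(shape = "polygon", rows = r$vertices[, 1], cols = r$vertices[, 2],
         role = r$role)
}

#' Load ROIs from a JSON or CSV file
#'
#' JSON holds a list of objects with fields `shape` (`"rect"` or
#' `"polygon"`), `role`, and either `row0/col0/height/width` or
#' `rows`/`cols` vertex arrays. CSV holds rectangles only, with columns
#' `row0, col0, height, width, role`.
#'
#' @param path file path ending in `.json` or `.csv`.
#' @param image_dim optional `c(nrow, ncol)`; when given, every ROI is
#'   checked to lie inside the image and out-of-bounds ROIs are rejected.
#' @return A list of `roi` objects.
#' @export
load_rois <- function(path, image_dim = NULL) {
  if (!file.exists(path)) stop("ROI file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE)
    rois <- lapply(raw, function(r) {
      if (identical(r$shape, "rect"))
        roi_rect(r$row0, r$col0, r$height, r$width, r$role)
      else
        roi_polygon(cbind(unlist(r$rows), unlist(r$cols)), r$role)
    })
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    tb <- utils::read.csv(path, stringsAsFactors = FALSE)
    rois <- lapply(seq_len(nrow(tb)), function(i)
      roi_rect(tb$row0[i], tb$col0[i], tb$height[i], tb$width[i], tb$role[i]))
  } else stop("unsupported ROI file format: ", path)
  if (!is.null(image_dim))
    for (r in rois) roi_mask(r, image_dim[1], image_dim[2])  # bounds check
  rois
}

#' Write ROIs to JSON
#'
#' Round-trips losslessly through [load_rois()].
#'
#' @param rois list of `roi` objects.
#' @param path output `.json` path.
#' @export
write_rois <- function(rois, path) {
  jsonlite::write_json(lapply(rois, roi_to_list), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
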