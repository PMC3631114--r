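#' Calibrated 8-bit grayscale image
#'
#' Container pairing a 2D integer intensity raster (0--255) with the
#' physical pixel-area calibration of the acquisition. The default
#' calibration, 2.971 um^2 per pixel, is the confocal setting the rest of
#' the package assumes when none is given; a 2048-px field at that
#' calibration spans 3.53 mm.
#'
#' Matrix rows are image rows (y), columns are x. Reported centroids use
#' (x = column, y = row) pixel coordinates.
#'
#' @param intensities integer matrix with values in 0..255.
#' @param pixel_area_um2 positive scalar, physical area of one pixel in
#'   square micrometres.
#' @return An object of class `calibrated_image`: a list with elements
#'   `intensities` and `pixel_area_um2`.
#' @examples
#' img <- calibrated_image(matrix(200L, 64, 64))
#' field_of_view_mm(ncol(img$intensities), img$pixel_area_um2)
#' @export
calibrated_image <- function(intensities, pixel_area_um2 = 2.971) {
  if (!is.matrix(intensities)) stop("`intensities` must be a matrix")
  if (length(intensities) == 0L) stop("image must be non-empty")
  if (anyNA(intensities)) stop("image contains NA intensities")
  m <- round(intensities)
  if (any(m < 0 | m > 255)) stop("intensities must lie in [0, 255]")
  m <- matrix(as.integer(m), nrow(intensities), ncol(intensities))
  if (!is.numeric(pixel_area_um2) || length(pixel_area_um2) != 1L ||
      !is.finite(pixel_area_um2) || pixel_area_um2 <= 0) {
    stop("`pixel_area_um2` must be a positive scalar")
  }
  structure(list(intensities = m, pixel_area_um2 = as.numeric(pixel_area_um2)),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("calibrated_image: %d x %d px, %.4g um^2/px (field %.3g x %.3g mm)\n",
              d[1], d[2], x$pixel_area_um2,
              field_of_view_mm(d[2], x$pixel_area_um2),
              field_of_view_mm(d[1], x$pixel_area_um2)))
  invisible(x)
}

#' Physical side length of a pixel field
#'
#' Converts a pixel extent and a pixel-area calibration into millimetres:
#' `n_px * sqrt(pixel_area_um2) / 1000`. At the default calibration a
#' 2048-pixel field is 3.53 mm wide.
#'
#' @param n_px number of pixels along the side.
#' @param pixel_area_um2 pixel area in um^2.
#' @return Side length in mm.
#' @export
field_of_view_mm <- function(n_px, pixel_area_um2 = 2.971) {
  stopifnot(n_px > 0, pixel_area_um2 > 0)
  n_px * sqrt(pixel_area_um2) / 1000
}

#' Read an 8-bit grayscale image with calibration
#'
#' Reads a single-channel TIFF or PNG. Multi-channel rasters are rejected
#' rather than silently converted.
#'
#' @param path file path ending in .tif/.tiff/.png.
#' @param pixel_area_um2 calibration to attach (um^2 per pixel).
#' @return A [calibrated_image].
#' @export
read_calibrated_image <- function(path, pixel_area_um2 = 2.971) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", ext)
  )
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3] == 1L) raw <- raw[, , 1L]
    else stop("multi-channel image not supported; supply 8-bit grayscale")
  }
  calibrated_image(round(raw * 255), pixel_area_um2)
}

#' Write a calibrated image to TIFF or PNG
#'
#' @param img a [calibrated_image].
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_calibrated_image <- function(img, path) {
  stopifnot(inherits(img, "calibrated_image"))
  m <- img$intensities / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(m, path, bits.per.sample = 8L),
    png = png::writePNG(m, path),
    stop("unsupported image format: ", ext)
  )
  invisible(path)
}

# Reflect-pad a matrix by k pixels on every side (edge row/col duplicated,
# scipy-style "reflect"); used so filter border conventions are ours, not
# the filtering backend's.
pad_reflect <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  if (k >= nr || k >= nc) stop("padding exceeds image size")
  ri <- c(k:1, 1:nr, nr:(nr - k + 1))
  ci <- c(k:1, 1:nc, nc:(nc - k + 1))
  m[ri, ci, drop = FALSE]
}

# Gaussian blur with reflect padding. EBImage::gblur does the (FFT)
# convolution; padding by the kernel half-width keeps its circular
# boundary out of the returned field.
gaussian_blur <- function(m, sigma) {
  stopifnot(sigma > 0)
  k <- min(ceiling(3 * sigma), min(dim(m)) - 1L)
  p <- pad_reflect(m, k)
  f <- EBImage::gblur(EBImage::Image(p), sigma = sigma, radius = 2L * k + 1L)
  out <- EBImage::imageData(f)
  out[(k + 1):(k + nrow(m)), (k + 1):(k + ncol(m)), drop = FALSE]
}
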