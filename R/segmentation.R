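#' 5x5 median denoising
#'
#' Removes salt-and-pepper noise by replacing every pixel with the median
#' of its square neighborhood (default 5x5). Borders use reflect padding
#' so no artificial dark rim is created at the field edge.
#'
#' @param img a [calibrated_image].
#' @param size odd window side length in pixels (default 5).
#' @return A denoised [calibrated_image]; calibration unchanged.
#' @export
median_denoise <- function(img, size = 5L) {
  stopifnot(inherits(img, "calibrated_image"))
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L) stop("`size` must be a positive odd integer")
  if (size == 1L) return(img)
  k <- (size - 1L) %/% 2L
  m <- img$intensities
  p <- pad_reflect(m, k)
  f <- EBImage::medianFilter(EBImage::Image(p / 255), size = k)
  out <- round(EBImage::imageData(f) * 255)
  out <- out[(k + 1):(k + nrow(m)), (k + 1):(k + ncol(m)), drop = FALSE]
  calibrated_image(out, img$pixel_area_um2)
}

#' Brightness equalization by division
#'
#' Corrects smooth uneven illumination: the image is divided, pixel by
#' pixel, by a strongly Gaussian-blurred copy of itself, so that only
#' structure smaller than the blur scale survives. The ratio is mapped to
#' the 0--255 scale with ratio 1 at gray level 128 and clipped, which
#' keeps a fixed threshold on the 8-bit scale meaningful: after
#' equalization, threshold 50 selects pixels darker than ~39% of their
#' local background. Blurred pixels are floored at 1 before the division.
#'
#' @param img a [calibrated_image].
#' @param blur_sigma_px Gaussian sigma in pixels. Must be much larger
#'   than the objects of interest; default 50.
#' @return An equalized [calibrated_image].
#' @export
equalize_brightness <- function(img, blur_sigma_px = 50) {
  stopifnot(inherits(img, "calibrated_image"), blur_sigma_px > 0)
  orig <- img$intensities
  bl <- gaussian_blur(orig, blur_sigma_px)
  bl[bl < 1] <- 1
  out <- round(pmin(pmax(128 * orig / bl, 0), 255))
  calibrated_image(out, img$pixel_area_um2)
}

#' Fixed-threshold segmentation with border-object exclusion
#'
#' Thresholds the image at a fixed gray level, labels connected
#' components, and removes every component touching the raster border
#' (objects visible only in part carry no usable morphometry).
#'
#' @param img a [calibrated_image].
#' @param threshold gray level in 0..255 (default 50). With
#'   `polarity = "dark_objects"` the foreground is `intensity < threshold`;
#'   with `"bright_objects"` it is `intensity > threshold`.
#' @param polarity `"dark_objects"` (default; pores are non-fluorescent
#'   voids) or `"bright_objects"`.
#' @param connectivity 8 (default) or 4.
#' @param min_object_px smallest retained component, in pixels. Default 1:
#'   no size filter, single-pixel objects are kept.
#' @return A `labeled_mask`: list with `labels` (integer matrix, 0 =
#'   background, objects numbered 1..n with no gaps in raster-scan order),
#'   `n_objects`, `border_excluded_count` and `pixel_area_um2`.
#' @export
threshold_segment <- function(img, threshold = 50L,
                              polarity = c("dark_objects", "bright_objects"),
                              connectivity = 8L, min_object_px = 1L) {
  stopifnot(inherits(img, "calibrated_image"))
  polarity <- match.arg(polarity)
  threshold <- as.integer(threshold)
  if (threshold < 0L || threshold > 255L) stop("`threshold` must be in [0, 255]")
  m <- img$intensities
  fg <- if (polarity == "dark_objects") m < threshold else m > threshold
  lab <- label_components(fg, connectivity)
  nr <- nrow(lab); nc <- ncol(lab)
  border_labels <- setdiff(unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc])), 0L)
  lab[lab %in% border_labels] <- 0L
  if (min_object_px > 1L) {
    sz <- tabulate(lab[lab > 0L])
    lab[lab %in% which(sz < min_object_px)] <- 0L
  }
  lab <- renumber_labels(lab)
  structure(list(labels = lab,
                 n_objects = max(lab),
                 border_excluded_count = length(border_labels),
                 pixel_area_um2 = img$pixel_area_um2,
                 connectivity = as.integer(connectivity)),
            class = "labeled_mask")
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf("labeled_mask: %d x %d px, %d objects (%d border-excluded)\n",
              nrow(x$labels), ncol(x$labels), x$n_objects,
              x$border_excluded_count))
  invisible(x)
}

# Connected-component labeling of a logical matrix; components are found
# on the pixel-adjacency graph (igraph), 8- or 4-connected, and numbered
# in column-major first-occurrence order.
label_components <- function(fg, connectivity = 8L) {
  stopifnot(is.logical(fg), connectivity %in% c(4L, 8L))
  nr <- nrow(fg); nc <- ncol(fg)
  idx <- which(fg)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(lab)
  rank <- integer(nr * nc)
  rank[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- lapply(offs, function(d) {
    rr <- r + d[1]; c2 <- cc + d[2]
    ok <- rr >= 1L & rr <= nr & c2 >= 1L & c2 <= nc
    nidx <- (c2[ok] - 1L) * nr + rr[ok]
    keep <- fg[nidx]
    cbind(rank[idx[ok][keep]], rank[nidx[keep]])
  })
  el <- do.call(rbind, edges)
  g <- if (nrow(el) > 0L) {
    igraph::graph_from_edgelist(el, directed = FALSE)
  } else {
    igraph::make_empty_graph(n = length(idx), directed = FALSE)
  }
  if (igraph::vcount(g) < length(idx)) {
    g <- igraph::add_vertices(g, length(idx) - igraph::vcount(g))
  }
  lab[idx] <- as.integer(igraph::components(g)$membership)
  renumber_labels(lab)
}

# Renumber positive labels 1..n in column-major first-occurrence order.
renumber_labels <- function(lab) {
  idx <- which(lab > 0L)
  if (length(idx) == 0L) return(lab)
  u <- unique(lab[idx])
  map <- integer(max(u))
  map[u] <- seq_along(u)
  lab[idx] <- map[lab[idx]]
  lab
}

#' Full segmentation protocol
#'
#' Composition of the three processing stages:
#' [median_denoise()] (5x5) -> [equalize_brightness()] ->
#' [threshold_segment()]. The protocol is deterministic: identical input
#' and configuration always yield identical masks.
#'
#' @param img a [calibrated_image].
#' @param config list as produced by [segmentation_config()]; individual
#'   entries may be overridden.
#' @return A `labeled_mask` (see [threshold_segment()]).
#' @examples
#' spec <- image_spec(width_px = 128, height_px = 128, n_objects = 3,
#'                    axis_length_range_px = c(8, 12), seed = 7)
#' syn <- generate_pore_image(spec)
#' mask <- segment_pores(syn$image)
#' mask$n_objects
#' @export
segment_pores <- function(img, config = segmentation_config()) {
  cfg <- utils::modifyList(segmentation_config(), config)
  img |>
    median_denoise(size = cfg$median_size) |>
    equalize_brightness(blur_sigma_px = cfg$blur_sigma_px) |>
    threshold_segment(threshold = cfg$threshold, polarity = cfg$polarity,
                      connectivity = cfg$connectivity,
                      min_object_px = cfg$min_object_px)
}

#' Segmentation configuration defaults
#'
#' Defaults follow the protocol constants: 5x5 median window, fixed
#' threshold 50 on the equalized 0--255 scale, dark objects,
#' 8-connectivity, no minimum size. The blur sigma is the one free
#' parameter: it must sit well above the pore scale and below the field
#' size (default 50 px).
#'
#' @param median_size odd median window side (px).
#' @param blur_sigma_px Gaussian sigma of the equalization blur (px).
#' @param threshold fixed gray-level threshold.
#' @param polarity `"dark_objects"` or `"bright_objects"`.
#' @param connectivity 8 or 4.
#' @param min_object_px minimum retained component size (px).
#' @return Named list of settings.
#' @export
segmentation_config <- function(median_size = 5L, blur_sigma_px = 50,
                                threshold = 50L, polarity = "dark_objects",
                                connectivity = 8L, min_object_px = 1L) {
  list(median_size = median_size, blur_sigma_px = blur_sigma_px,
       threshold = threshold, polarity = polarity,
       connectivity = connectivity, min_object_px = min_object_px)
}

#' Write a label mask as 16-bit TIFF with a JSON sidecar
#'
#' @param mask a `labeled_mask`.
#' @param path output TIFF path; the sidecar is written at `path` with a
#'   `.json` extension appended.
#' @return `path`, invisibly.
#' @export
write_labeled_mask <- function(mask, path) {
  stopifnot(inherits(mask, "labeled_mask"))
  if (mask$n_objects > 65535L) stop("too many labels for 16-bit output")
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L)
  side <- list(n_objects = mask$n_objects,
               border_excluded_count = mask$border_excluded_count,
               pixel_area_um2 = mask$pixel_area_um2,
               connectivity = mask$connectivity)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
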