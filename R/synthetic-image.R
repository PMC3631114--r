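#' Specification for a synthetic pore image
#'
#' Describes a calibrated 8-bit microscopy-like field: dark elliptical
#' pore-like objects with optional radial boundary roughness on a bright
#' tissue background, modulated by a smooth illumination surface and
#' corrupted by salt-and-pepper noise. Defaults emulate the acquisition
#' the analysis assumes (2048 x 2048 px at 2.971 um^2/pixel) with pore
#' sizes spanning the osteonal-canal to lacunar scale.
#'
#' @param width_px,height_px image size in pixels.
#' @param pixel_area_um2 calibration (um^2 per pixel).
#' @param n_objects number of interior objects to draw.
#' @param axis_length_range_px range of the semi-major axis in pixels.
#' @param axis_ratio_range range of semi-major/semi-minor ratio (>= 1).
#' @param roughness_amplitude relative radial boundary perturbation in
#'   `[0, 0.5)`; 0 draws exact ellipses.
#' @param background_level,object_level gray levels in 0..255; objects
#'   must be darker than the background.
#' @param illumination_gradient_amplitude relative amplitude in `[0, 1)`
#'   of the smooth multiplicative illumination surface.
#' @param noise_fraction fraction in `[0, 0.2]` of pixels replaced by 0 or
#'   255 (salt-and-pepper).
#' @param n_border_objects number of extra objects deliberately drawn
#'   across the raster border (for exercising border exclusion).
#' @param seed integer seed; generation is fully reproducible.
#' @return A validated list of class `image_spec`.
#' @export
image_spec <- function(width_px = 2048L, height_px = 2048L,
                       pixel_area_um2 = 2.971, n_objects = 40L,
                       axis_length_range_px = c(10, 25),
                       axis_ratio_range = c(1, 3),
                       roughness_amplitude = 0.15,
                       background_level = 200L, object_level = 40L,
                       illumination_gradient_amplitude = 0.2,
                       noise_fraction = 0.02,
                       n_border_objects = 0L, seed = 1L) {
  spec <- list(width_px = as.integer(width_px), height_px = as.integer(height_px),
               pixel_area_um2 = pixel_area_um2, n_objects = as.integer(n_objects),
               axis_length_range_px = as.numeric(axis_length_range_px),
               axis_ratio_range = as.numeric(axis_ratio_range),
               roughness_amplitude = roughness_amplitude,
               background_level = as.integer(background_level),
               object_level = as.integer(object_level),
               illumination_gradient_amplitude = illumination_gradient_amplitude,
               noise_fraction = noise_fraction,
               n_border_objects = as.integer(n_border_objects),
               seed = as.integer(seed))
  with(spec, {
    stopifnot(width_px > 0, height_px > 0, pixel_area_um2 > 0, n_objects >= 0,
              length(axis_length_range_px) == 2, all(axis_length_range_px > 0),
              axis_length_range_px[1] <= axis_length_range_px[2],
              length(axis_ratio_range) == 2, all(axis_ratio_range >= 1),
              axis_ratio_range[1] <= axis_ratio_range[2],
              roughness_amplitude >= 0, roughness_amplitude < 0.5,
              background_level >= 0, background_level <= 255,
              object_level >= 0, object_level <= 255,
              illumination_gradient_amplitude >= 0,
              illumination_gradient_amplitude < 1,
              noise_fraction >= 0, noise_fraction <= 0.2,
              n_border_objects >= 0)
  })
  if (spec$object_level >= spec$background_level) {
    stop("object_level must be below background_level (pores are dark)")
  }
  class(spec) <- "image_spec"
  spec
}

# Radial profile of one object: base oriented-ellipse radius times a
# low-order cosine perturbation r(theta) = r0(theta) * (1 + amp * sum_k
# a_k cos(k theta + phi_k)), k = 3..8, with sum |a_k| = 1 so the relative
# perturbation never exceeds `amp` and the boundary stays star-shaped.
object_radius_fun <- function(a, b, phi, amp, coef = NULL, phase = NULL) {
  force(a); force(b); force(phi); force(amp)
  ks <- 3:8
  if (is.null(coef)) coef <- rep(0, length(ks))
  function(theta) {
    r0 <- a * b / sqrt((b * cos(theta - phi))^2 + (a * sin(theta - phi))^2)
    pert <- rep(0, length(theta))
    if (amp > 0) {
      for (i in seq_along(ks)) pert <- pert + coef[i] * cos(ks[i] * theta + phase[i])
    }
    r0 * (1 + amp * pert)
  }
}

#' Generate a synthetic calibrated pore image with ground truth
#'
#' Objects are star-shaped regions defined by an analytic radial boundary
#' (oriented ellipse times a bounded cosine perturbation) rasterized by
#' pixel-center inclusion, so the true enclosed area is computable by
#' quadrature and the digitization error is quantifiable. The clean
#' raster is multiplied by a low-order polynomial illumination surface
#' normalized to mean 1, then a fraction of pixels is replaced by 0 or
#' 255. Interior objects are pairwise non-overlapping and keep at least
#' 2 px clearance from the border; placement failing 1000 draws signals
#' an overcrowded spec.
#'
#' @param spec an [image_spec()].
#' @return List with elements `image` (a [calibrated_image]) and `truth`,
#'   a data.frame with one row per interior object: centroid, semi-axes,
#'   orientation, exact area (um^2), elongation, and an attribute
#'   `boundary_radii_px` (list column of the exact radial profiles at 720
#'   angles). Border objects, if requested, are listed in attribute
#'   `border_truth`.
#' @export
generate_pore_image <- function(spec) {
  stopifnot(inherits(spec, "image_spec"))
  set.seed(spec$seed)
  h <- spec$height_px; w <- spec$width_px
  img <- matrix(spec$background_level, h, w)

  draw <- function(cx, cy, rfun, level) {
    # rasterize by pixel-center inclusion over the bounding box
    rmax <- max(rfun(seq(0, 2 * pi, length.out = 720)))
    r0 <- max(1L, floor(cy - rmax - 1)); r1 <- min(h, ceiling(cy + rmax + 1))
    c0 <- max(1L, floor(cx - rmax - 1)); c1 <- min(w, ceiling(cx + rmax + 1))
    if (r0 > r1 || c0 > c1) return(img)
    rows <- r0:r1; cols <- c0:c1
    dy <- rows - cy
    dx <- rep(cols - cx, each = length(rows))
    dyv <- rep(dy, times = length(cols))
    dist <- sqrt(dx^2 + dyv^2)
    theta <- atan2(dyv, dx)
    inside <- dist <= rfun(theta)
    sub <- img[rows, cols, drop = FALSE]
    sub[inside] <- level
    img[rows, cols] <- sub
    img
  }

  n_total <- spec$n_objects
  truth <- vector("list", n_total)
  placed <- matrix(numeric(0), 0, 3)  # cx, cy, clearance radius
  margin <- 2
  theta_grid <- seq(0, 2 * pi, length.out = 721)[-721]

  for (i in seq_len(n_total)) {
    ok <- FALSE
    for (attempt in seq_len(1000L)) {
      a <- runif(1, spec$axis_length_range_px[1], spec$axis_length_range_px[2])
      ratio <- runif(1, spec$axis_ratio_range[1], spec$axis_ratio_range[2])
      b <- a / ratio
      phi <- runif(1, 0, pi)
      coef <- phase <- NULL
      if (spec$roughness_amplitude > 0) {
        coef <- runif(6, -1, 1)
        coef <- coef / sum(abs(coef))
        phase <- runif(6, 0, 2 * pi)
      }
      rmax <- a * (1 + spec$roughness_amplitude)
      lo_x <- margin + rmax + 1; hi_x <- w - margin - rmax
      lo_y <- margin + rmax + 1; hi_y <- h - margin - rmax
      if (lo_x >= hi_x || lo_y >= hi_y) next
      cx <- runif(1, lo_x, hi_x); cy <- runif(1, lo_y, hi_y)
      if (nrow(placed) > 0) {
        dd <- sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2)
        if (any(dd < placed[, 3] + rmax + 2)) next
      }
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place object ", i,
                  " without overlap in 1000 attempts; spec is overcrowded")
    rfun <- object_radius_fun(a, b, phi, spec$roughness_amplitude, coef, phase)
    img <- draw(cx, cy, rfun, spec$object_level)
    placed <- rbind(placed, c(cx, cy, rmax))
    radii <- rfun(theta_grid)
    # exact enclosed area of a star-shaped boundary: (1/2) integral r^2 dtheta
    area_px2 <- 0.5 * mean(radii^2) * 2 * pi
    truth[[i]] <- data.frame(
      object = i, centroid_x_px = cx, centroid_y_px = cy,
      semi_major_px = a, semi_minor_px = b, orientation_rad = phi,
      true_area_um2 = area_px2 * spec$pixel_area_um2,
      true_elongation = a / b)
    attr(truth[[i]], "radii") <- radii
  }

  border_truth <- NULL
  if (spec$n_border_objects > 0) {
    bt <- vector("list", spec$n_border_objects)
    for (i in seq_len(spec$n_border_objects)) {
      a <- runif(1, spec$axis_length_range_px[1], spec$axis_length_range_px[2])
      b <- a / runif(1, spec$axis_ratio_range[1], spec$axis_ratio_range[2])
      side <- sample(4L, 1L)
      cx <- switch(side, runif(1, 0, 1), w + runif(1, -1, 0),
                   runif(1, a + 4, w - a - 4), runif(1, a + 4, w - a - 4))
      cy <- switch(side, runif(1, a + 4, h - a - 4), runif(1, a + 4, h - a - 4),
                   runif(1, 0, 1), h + runif(1, -1, 0))
      rfun <- object_radius_fun(a, b, 0, 0)
      img <- draw(cx, cy, rfun, spec$object_level)
      bt[[i]] <- data.frame(object = i, centroid_x_px = cx, centroid_y_px = cy,
                            semi_major_px = a, semi_minor_px = b)
    }
    border_truth <- do.call(rbind, bt)
  }

  # smooth multiplicative illumination surface (quadratic, mean 1)
  if (spec$illumination_gradient_amplitude > 0) {
    u <- matrix(rep(seq(-1, 1, length.out = w), each = h), h, w)
    v <- matrix(rep(seq(-1, 1, length.out = h), times = w), h, w)
    cf <- runif(5, -1, 1)
    g <- cf[1] * u + cf[2] * v + cf[3] * u * v + cf[4] * u^2 + cf[5] * v^2
    g <- g / max(abs(g))
    field <- 1 + spec$illumination_gradient_amplitude * g
    field <- field / mean(field)
    img <- img * field
  }
  img <- round(pmin(pmax(img, 0), 255))

  if (spec$noise_fraction > 0) {
    n_noise <- round(spec$noise_fraction * length(img))
    at <- sample.int(length(img), n_noise)
    img[at] <- sample(c(0, 255), n_noise, replace = TRUE)
  }

  truth_df <- if (n_total > 0) {
    radii_list <- lapply(truth, attr, "radii")
    out <- do.call(rbind, truth)
    attr(out, "boundary_radii_px") <- radii_list
    out
  } else {
    data.frame(object = integer(), centroid_x_px = numeric(),
               centroid_y_px = numeric(), semi_major_px = numeric(),
               semi_minor_px = numeric(), orientation_rad = numeric(),
               true_area_um2 = numeric(), true_elongation = numeric())
  }
  if (!is.null(border_truth)) attr(truth_df, "border_truth") <- border_truth
  list(image = calibrated_image(img, spec$pixel_area_um2), truth = truth_df)
}

#' Write a ground-truth object table as CSV
#'
#' @param truth the `truth` element returned by [generate_pore_image()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  write.csv(as.data.frame(truth), path, row.names = FALSE)
  invisible(path)
}
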