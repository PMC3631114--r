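test_that("circularity and shape roughness hit their analytic anchors", {
  # circle: C = 0 exactly from exact area and perimeter
  expect_equal(circularity(pi * 50^2, 2 * pi * 50), 0)
  # square of side s: C = 1 - pi/4
  expect_equal(circularity(4^2, 4 * 4), 1 - pi / 4, tolerance = 1e-12)
  # clamping keeps the documented range for near-degenerate input
  expect_gte(circularity(1.001 * pi, 2 * pi), 0)
  # equal radii give SR = 1 exactly
  expect_identical(shape_roughness(rep(2.5, 360)), 1)
  # SR is scale-free in the radii
  r <- runif(50, 1, 3)
  expect_equal(shape_roughness(r), shape_roughness(10 * r), tolerance = 1e-12)
})

test_that("digitized disks are measured as near-perfect circles", {
  for (r in c(30, 40, 50)) {
    mask <- threshold_segment(disk_image(r), 50)
    o <- measure_object(mask, 1)
    expect_lte(o$circularity, 0.05)
    # 4-fold symmetry makes the moment matrix isotropic: E = 1 exactly
    expect_equal(o$elongation, 1, tolerance = 1e-9)
    expect_gte(o$shape_roughness, 0.95)
    # perimeter estimator converges to the analytic circumference
    expect_equal(o$perimeter_um, 2 * pi * r, tolerance = 0.02)
    # area is pixel count times calibration, exactly
    expect_identical(o$area_um2, o$pixel_count * 1)
  }
})

test_that("a rasterized 80x40 ellipse has elongation 2", {
  mask <- threshold_segment(ellipse_image(80, 40), 50)
  o <- measure_object(mask, 1)
  expect_equal(o$elongation, 2, tolerance = 0.025)
})

test_that("SR equals an exhaustive contour-scan oracle on varied objects", {
  specs <- list(
    threshold_segment(disk_image(25), 50),
    threshold_segment(ellipse_image(30, 12, angle = 0.6), 50),
    threshold_segment(ellipse_image(18, 17, angle = 1.2), 50)
  )
  roughs <- generate_pore_image(image_spec(
    width_px = 300, height_px = 300, n_objects = 6,
    axis_length_range_px = c(10, 18), roughness_amplitude = 0.25,
    noise_fraction = 0, illumination_gradient_amplitude = 0, seed = 8))
  specs <- c(specs, list(threshold_segment(roughs$image, 50)))
  for (mask in specs) {
    for (l in seq_len(mask$n_objects)) {
      o <- measure_object(mask, l)
      radii <- attr(o, "boundary_radii_um")
      # independent scan: sort every contour-vertex distance, take the
      # extremes and the central value(s) by hand
      s <- sort(radii)
      n <- length(s)
      med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
      sr_oracle <- (med * s[1] / s[n]^2)^(1 / 3)
      expect_equal(o$shape_roughness, sr_oracle, tolerance = 1e-9)
    }
  }
})

test_that("single-pixel and collinear objects use the documented conventions", {
  m <- matrix(200L, 20, 20)
  m[5, 5] <- 10L
  m[10, 3:9] <- 10L  # a 7-px horizontal run
  mask <- threshold_segment(calibrated_image(m, 2.971), 50)
  sl <- measure_slice(mask)
  single <- sl$objects[sl$objects$pixel_count == 1, ]
  expect_equal(single$area_um2, 2.971)
  expect_equal(single$elongation, 1)
  expect_equal(single$circularity, 0)
  expect_equal(single$shape_roughness, 1)
  expect_equal(single$flag, "single_pixel")
  run <- sl$objects[sl$objects$pixel_count == 7, ]
  expect_equal(run$elongation, 7)
  expect_equal(run$flag, "collinear")
})

test_that("unknown labels are rejected", {
  mask <- threshold_segment(disk_image(5), 50)
  expect_error(measure_object(mask, 99), "not present")
})

test_that("shape descriptors are calibration-invariant, area scales linearly", {
  img <- ellipse_image(22, 11, angle = 0.4)
  for (pa in c(1, 2.971, 10)) {
    mask <- threshold_segment(calibrated_image(img$intensities, pa), 50)
    o <- measure_object(mask, 1)
    if (pa == 1) base <- o
    expect_equal(o$elongation, base$elongation, tolerance = 1e-9)
    expect_equal(o$circularity, base$circularity, tolerance = 1e-9)
    expect_equal(o$shape_roughness, base$shape_roughness, tolerance = 1e-9)
    expect_equal(o$area_um2, base$area_um2 * pa, tolerance = 1e-12)
  }
})

test_that("descriptors are robust to object rotation", {
  vals <- t(vapply(seq(0, pi, length.out = 7), function(ang) {
    mask <- threshold_segment(ellipse_image(30, 20, angle = ang, size = 81), 50)
    o <- measure_object(mask, 1)
    c(o$elongation, o$circularity + 1, o$shape_roughness)
  }, numeric(3)))
  spread <- apply(vals, 2, function(v) diff(range(v)) / mean(v))
  expect_true(all(spread < 0.03))
})

test_that("mean SR falls and mean C rises with boundary roughness", {
  mean_desc <- function(amp) {
    sl <- measure_slice(segment_pores(generate_pore_image(image_spec(
      width_px = 384, height_px = 384, n_objects = 10,
      axis_length_range_px = c(10, 16), axis_ratio_range = c(1, 1.5),
      roughness_amplitude = amp, noise_fraction = 0,
      illumination_gradient_amplitude = 0, seed = 33))$image))
    c(sr = mean(sl$objects$shape_roughness), c = mean(sl$objects$circularity))
  }
  d <- vapply(c(0, 0.12, 0.25, 0.38), mean_desc, numeric(2))
  expect_true(all(diff(d["sr", ]) < 0))
  expect_true(all(diff(d["c", ]) > 0))
})

test_that("slice morphometry computes pore fraction and histograms", {
  m <- matrix(200L, 100, 100)
  m[40:49, 40:49] <- 10L  # one 10x10 object
  sl <- measure_slice(threshold_segment(calibrated_image(m, 2.971), 50))
  expect_equal(sl$total_pore_fraction, 0.01)  # calibration-free ratio
  # calibration changes nothing in the fraction
  sl2 <- measure_slice(threshold_segment(calibrated_image(m, 1), 50))
  expect_equal(sl2$total_pore_fraction, 0.01)

  empty <- measure_slice(threshold_segment(calibrated_image(
    matrix(200L, 50, 50)), 50))
  expect_equal(empty$total_pore_fraction, 0)
  expect_equal(nrow(empty$objects), 0)
  expect_equal(nrow(empty$histograms$area_um2), 0)

  # histogram contract: right-open bins at the stated widths, frequencies
  # sum to one
  syn <- generate_pore_image(image_spec(width_px = 256, height_px = 256,
                                        n_objects = 8,
                                        axis_length_range_px = c(6, 12),
                                        noise_fraction = 0,
                                        illumination_gradient_amplitude = 0,
                                        seed = 13))
  sl3 <- measure_slice(threshold_segment(syn$image, 50))
  hs <- histogram_spec()
  for (nm in names(hs$widths)) {
    h <- sl3$histograms[[nm]]
    expect_equal(sum(h$rel_freq), 1, tolerance = 1e-12)
    expect_equal(unique(round(h$bin_right - h$bin_left, 10)),
                 unname(hs$widths[nm]))
    expect_equal(h$bin_left[1], unname(hs$origins[nm]))
    expect_equal(sum(h$count), nrow(sl3$objects))
  }
})

test_that("pore fraction matches ground truth on clean synthetic slices", {
  syn <- generate_pore_image(image_spec(width_px = 384, height_px = 384,
                                        n_objects = 15,
                                        axis_length_range_px = c(10, 18),
                                        axis_ratio_range = c(1, 1.8),
                                        roughness_amplitude = 0,
                                        noise_fraction = 0,
                                        illumination_gradient_amplitude = 0,
                                        seed = 4))
  sl <- measure_slice(segment_pores(syn$image))
  truth_frac <- sum(syn$truth$true_area_um2) / sl$observed_area_um2
  expect_equal(sl$total_pore_fraction, truth_frac, tolerance = 0.02)
})

test_that("group summaries pool objects and slices correctly", {
  m <- matrix(200L, 60, 60)
  m[10:19, 10:19] <- 10L   # ~100 px
  m[35:51, 35:51] <- 10L   # ~289 px
  sl <- measure_slice(threshold_segment(calibrated_image(m, 1), 50))
  slices <- list(list(morphometry = sl, histology = "AM", treatment = "F"))
  g <- summarize_groups(slices)
  expect_equal(g$n_objects, 2)
  expect_equal(g$area_mean, mean(c(100, 289)))
  expect_equal(g$area_sd, sd(c(100, 289)))

  # two-point hand check: A = 100 and 300 -> mean 200, sample SD 141.42
  expect_equal(sd(c(100, 300)), 141.42, tolerance = 1e-3)

  # identical object sets give identical summary rows
  slices2 <- list(list(morphometry = sl, histology = "AM", treatment = "F"),
                  list(morphometry = sl, histology = "AM", treatment = "C"))
  g2 <- summarize_groups(slices2)
  expect_equal(g2$area_mean[1], g2$area_mean[2])
  expect_equal(g2$shape_roughness_mean[1], g2$shape_roughness_mean[2])

  # pooled mean equals brute-force mean over the concatenated object lists
  both <- rbind(sl$objects, sl$objects)
  slices3 <- list(list(morphometry = sl, histology = "AM", treatment = "F"),
                  list(morphometry = sl, histology = "AM", treatment = "F"))
  g3 <- summarize_groups(slices3)
  expect_equal(g3$area_mean, mean(both$area_um2))
  expect_equal(g3$n_slices, 2)

  # a missing factor combination warns and is omitted
  slices4 <- list(list(morphometry = sl, histology = "AM", treatment = "F"),
                  list(morphometry = sl, histology = "PL", treatment = "C"))
  expect_warning(g4 <- summarize_groups(slices4), "omitted")
  expect_equal(nrow(g4), 2)
})
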