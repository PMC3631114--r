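# Shared fixtures, all built in code.

# Calibrated image containing a centered digitized disk.
disk_image <- function(r, size = 2 * r + 21, bg = 220L, fg = 10L,
                       pixel_area = 1) {
  m <- matrix(bg, size, size)
  c0 <- (size + 1) / 2
  m[(row(m) - c0)^2 + (col(m) - c0)^2 <= r^2] <- fg
  calibrated_image(m, pixel_area)
}

# Calibrated image with an axis-aligned digitized ellipse (semi-axes a, b).
ellipse_image <- function(a, b, angle = 0, size = 2 * max(a, b) + 21,
                          bg = 220L, fg = 10L, pixel_area = 1) {
  m <- matrix(bg, size, size)
  c0 <- (size + 1) / 2
  x <- row(m) - c0; y <- col(m) - c0
  xr <- x * cos(angle) + y * sin(angle)
  yr <- -x * sin(angle) + y * cos(angle)
  m[(xr / a)^2 + (yr / b)^2 <= 1] <- fg
  calibrated_image(m, pixel_area)
}

# Match ground-truth objects to measured objects by nearest centroid.
# Returns per-truth-row: matched index, distance, relative A and E errors.
match_truth <- function(truth, objects, max_dist = 3) {
  out <- data.frame(dist = numeric(nrow(truth)), a_err = NA_real_,
                    e_err = NA_real_)
  for (i in seq_len(nrow(truth))) {
    dd <- sqrt((objects$centroid_x - truth$centroid_x_px[i])^2 +
               (objects$centroid_y - truth$centroid_y_px[i])^2)
    j <- which.min(dd)
    out$dist[i] <- dd[j]
    if (dd[j] <= max_dist) {
      out$a_err[i] <- abs(objects$area_um2[j] - truth$true_area_um2[i]) /
        truth$true_area_um2[i]
      out$e_err[i] <- abs(objects$elongation[j] - truth$true_elongation[i]) /
        truth$true_elongation[i]
    }
  }
  out
}

# Brute-force 5x5 median with reflect padding, the oracle for the
# denoising stage.
brute_median5 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(2:1, 1:nr, nr:(nr - 1)); ci <- c(2:1, 1:nc, nc:(nc - 1))
  p <- m[ri, ci]
  out <- matrix(0L, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    out[i, j] <- median(p[i:(i + 4), j:(j + 4)])
  }
  out
}
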