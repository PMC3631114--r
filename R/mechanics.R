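#' Mechanical compression record
#'
#' Displacement--force series with sample geometry. Strain is engineering
#' strain on the initial (post-demineralization) height; stress is force
#' over the initial cross-section.
#'
#' @param displacement_mm,force_n equal-length numeric series. The
#'   recording convention is that acquisition is triggered at the force
#'   passing 0.1 N and deformation is counted from the trigger.
#' @param sample_height_mm,cross_section_mm2 positive sample geometry.
#' @param direction `"L"` (loaded parallel to the bone long axis) or
#'   `"T"` (transverse).
#' @return A `mechanical_record` list.
#' @export
mechanical_record <- function(displacement_mm, force_n, sample_height_mm,
                              cross_section_mm2, direction = c("T", "L")) {
  direction <- match.arg(direction)
  stopifnot(length(displacement_mm) == length(force_n),
            length(force_n) > 0,
            sample_height_mm > 0, cross_section_mm2 > 0)
  structure(list(displacement_mm = as.numeric(displacement_mm),
                 force_n = as.numeric(force_n),
                 sample_height_mm = sample_height_mm,
                 cross_section_mm2 = cross_section_mm2,
                 direction = direction),
            class = "mechanical_record")
}

#' Read a compression record from CSV
#'
#' Expects columns `displacement_mm` and `force_n` (header required).
#'
#' @param path CSV path.
#' @inheritParams mechanical_record
#' @return A `mechanical_record`.
#' @export
read_mechanical_record <- function(path, sample_height_mm, cross_section_mm2,
                                   direction = c("T", "L")) {
  d <- read.csv(path)
  if (!all(c("displacement_mm", "force_n") %in% names(d))) {
    stop("CSV must have columns displacement_mm, force_n")
  }
  mechanical_record(d$displacement_mm, d$force_n, sample_height_mm,
                    cross_section_mm2, match.arg(direction))
}

#' Secant modulus of one bending cycle
#'
#' Euler--Bernoulli three-point bending at the cycle peak:
#' `E = (F/delta) * L^3 / (48 I)` with `I = w h^3 / 12`, evaluated at the
#' maximum deflection of the cycle (peak-force point if the deflection
#' ramp is non-monotone there).
#'
#' @param deflection_mm,force_n the cycle's loading ramp.
#' @param span_mm support span (mm).
#' @param width_mm,height_mm rectangular cross-section (mm).
#' @return Secant modulus in MPa.
#' @examples
#' # F/delta = 100 N/mm, span 32 mm, 5 x 5 mm beam -> 1310.7 MPa
#' secant_modulus(c(0.5, 1), c(50, 100), 32, 5, 5)
#' @export
secant_modulus <- function(deflection_mm, force_n, span_mm = 32,
                           width_mm = 5, height_mm = 5) {
  stopifnot(length(deflection_mm) == length(force_n),
            span_mm > 0, width_mm > 0, height_mm > 0)
  i_peak <- which.max(deflection_mm)
  if (deflection_mm[i_peak] <= 0) stop("cycle has no positive deflection")
  if (force_n[i_peak] < max(force_n)) i_peak <- which.max(force_n)
  inertia <- width_mm * height_mm^3 / 12
  (force_n[i_peak] / deflection_mm[i_peak]) * span_mm^3 / (48 * inertia)
}

#' Percent modulus change over a fatigue protocol
#'
#' `100 * (M_first - M_last) / M_first`: positive when stiffness was lost.
#'
#' @param m_first_mpa,m_last_mpa secant moduli of the first and last
#'   complete cycle.
#' @return Percent change.
#' @examples
#' percent_modulus_change(142.3, 134.2)  # ~5.7
#' @export
percent_modulus_change <- function(m_first_mpa, m_last_mpa) {
  stopifnot(m_first_mpa > 0)
  100 * (m_first_mpa - m_last_mpa) / m_first_mpa
}

#' Fatigue summary over a series of bending cycles
#'
#' Computes the secant modulus of the first and the last *complete* cycle
#' (a cycle is complete when it reaches at least 95% of the target
#' deflection) and the percent modulus change. A sample failing
#' mid-protocol keeps its last complete cycle and is flagged.
#'
#' @param cycles list of per-cycle data.frames with columns
#'   `deflection_mm`, `force_n`.
#' @param span_mm,width_mm,height_mm beam geometry (defaults 32, 5, 5 mm).
#' @param max_deflection_mm target deflection per cycle (default 0.9 mm).
#' @param n_cycles_target nominal protocol length (default 300).
#' @return List: `m_first_mpa`, `m_last_mpa`, `percent_change`,
#'   `n_complete`, `failed_early`.
#' @export
fatigue_summary <- function(cycles, span_mm = 32, width_mm = 5, height_mm = 5,
                            max_deflection_mm = 0.9, n_cycles_target = 300L) {
  stopifnot(length(cycles) >= 2)
  complete <- vapply(cycles, function(cy) {
    max(cy$deflection_mm) >= 0.95 * max_deflection_mm
  }, logical(1))
  if (sum(complete) < 2) stop("fewer than 2 complete cycles")
  idx <- which(complete)
  m_first <- secant_modulus(cycles[[idx[1]]]$deflection_mm,
                            cycles[[idx[1]]]$force_n,
                            span_mm, width_mm, height_mm)
  last <- idx[length(idx)]
  m_last <- secant_modulus(cycles[[last]]$deflection_mm,
                           cycles[[last]]$force_n,
                           span_mm, width_mm, height_mm)
  list(m_first_mpa = m_first, m_last_mpa = m_last,
       percent_change = percent_modulus_change(m_first, m_last),
       n_complete = sum(complete),
       failed_early = sum(complete) < n_cycles_target)
}

#' Compression descriptors with direction-specific truncation
#'
#' Fills the derived quantities of a [mechanical_record]:
#' * strain = displacement / initial height; stress = force /
#'   cross-section;
#' * work = trapezoidal integral of force over displacement (N mm = mJ)
#'   from the recording trigger to the evaluation point;
#' * direction `"T"`: the ultimate point is the global force maximum
#'   (transverse compression always reaches failure); stress, strain and
#'   work are evaluated there. A record whose force maximum sits at the
#'   end of the series signals no-failure.
#' * direction `"L"`: longitudinal samples do not fail within the applied
#'   deformation, so descriptors are evaluated at 50% strain by linear
#'   interpolation; a record shorter than 50% strain signals
#'   insufficient range.
#'
#' For `"T"` records reaching 50% strain before failure the 50%-strain
#' descriptors are reported too (NA otherwise).
#'
#' @param rec a `mechanical_record`.
#' @return The record with elements `stress_mpa`, `strain`,
#'   `ultimate_stress_mpa`, `ultimate_strain`, `work_mj`,
#'   `stress_at_50pct_mpa`, `work_at_50pct_mj` filled.
#' @export
compression_descriptors <- function(rec) {
  stopifnot(inherits(rec, "mechanical_record"))
  d <- rec$displacement_mm; f <- rec$force_n
  h <- rec$sample_height_mm; a <- rec$cross_section_mm2
  strain <- d / h
  stress <- f / a
  rec$strain <- strain
  rec$stress_mpa <- stress

  work_to_disp <- function(d_stop) {
    keep <- d <= d_stop + 1e-12
    dd <- d[keep]; ff <- f[keep]
    if (max(d) > d_stop && d_stop > max(dd)) {
      f_stop <- approx(d, f, xout = d_stop, ties = "ordered")$y
      dd <- c(dd, d_stop); ff <- c(ff, f_stop)
    }
    pracma::trapz(dd, ff)
  }

  at50 <- function() {
    d50 <- 0.5 * h
    f50 <- approx(d, f, xout = d50, ties = "ordered")$y
    list(stress = f50 / a, work = work_to_disp(d50))
  }

  if (rec$direction == "T") {
    imax <- which.max(f)
    if (imax == length(f)) {
      stop("no interior force maximum: transverse record shows no failure")
    }
    rec$ultimate_stress_mpa <- stress[imax]
    rec$ultimate_strain <- strain[imax]
    rec$work_mj <- pracma::trapz(d[1:imax], f[1:imax])
    if (strain[imax] >= 0.5) {
      s50 <- at50()
      rec$stress_at_50pct_mpa <- s50$stress
      rec$work_at_50pct_mj <- s50$work
    } else {
      rec$stress_at_50pct_mpa <- NA_real_
      rec$work_at_50pct_mj <- NA_real_
    }
  } else {
    if (max(strain) < 0.5) {
      stop("insufficient range: longitudinal record ends before 50% strain")
    }
    s50 <- at50()
    rec$stress_at_50pct_mpa <- s50$stress
    rec$work_at_50pct_mj <- s50$work
    rec$ultimate_stress_mpa <- NA_real_
    rec$ultimate_strain <- NA_real_
    rec$work_mj <- s50$work
  }
  rec
}

#' Specification for a synthetic compression curve
#'
#' Emulates unconfined compression of a ~5 mm demineralized cube at
#' constant strain rate: stress grows as
#' `stress_scale_mpa * strain^nonlinearity_exponent`. Transverse (`T`)
#' curves fail at `failure_strain` with a force drop of at least 50%
#' within 2% strain; longitudinal (`L`) curves stay monotone (no failure)
#' up to the 3 mm machine travel.
#'
#' @param sample_height_mm,cross_section_mm2 sample geometry (defaults
#'   4.85 mm and 24 mm^2, post-demineralization dimensions).
#' @param direction `"T"` or `"L"`.
#' @param failure_strain strain at the force peak, `T` only (default 0.5).
#' @param stress_scale_mpa stress at 100% strain extrapolated from the
#'   power law (default 60).
#' @param nonlinearity_exponent power-law exponent >= 1 (default 2).
#' @param noise_sd force noise SD in N (default 0.05).
#' @param n_points samples over the travel (default 600).
#' @param max_displacement_mm machine travel (default 3 mm).
#' @param trigger_n recording trigger force (default 0.1 N).
#' @param seed integer seed.
#' @return A validated list of class `curve_spec`.
#' @export
curve_spec <- function(sample_height_mm = 4.85, cross_section_mm2 = 24,
                       direction = c("T", "L"), failure_strain = 0.5,
                       stress_scale_mpa = 60, nonlinearity_exponent = 2,
                       noise_sd = 0.05, n_points = 600L,
                       max_displacement_mm = 3, trigger_n = 0.1, seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(sample_height_mm > 0, cross_section_mm2 > 0,
            failure_strain > 0, failure_strain < 1,
            stress_scale_mpa > 0, nonlinearity_exponent >= 1,
            noise_sd >= 0, n_points >= 10, max_displacement_mm > 0,
            trigger_n >= 0)
  structure(list(sample_height_mm = sample_height_mm,
                 cross_section_mm2 = cross_section_mm2,
                 direction = direction, failure_strain = failure_strain,
                 stress_scale_mpa = stress_scale_mpa,
                 nonlinearity_exponent = nonlinearity_exponent,
                 noise_sd = noise_sd, n_points = as.integer(n_points),
                 max_displacement_mm = max_displacement_mm,
                 trigger_n = trigger_n, seed = as.integer(seed)),
            class = "curve_spec")
}

#' Generate a synthetic compression record
#'
#' Samples the stress model of [curve_spec()] at uniform displacement
#' steps, adds Gaussian force noise, and emits the record from the first
#' sample whose force exceeds the trigger (deformation counted from the
#' trigger sample, matching the acquisition convention).
#'
#' @param spec a [curve_spec()].
#' @return A `mechanical_record`; the spec is attached as attribute
#'   `spec`.
#' @export
generate_compression_curve <- function(spec) {
  stopifnot(inherits(spec, "curve_spec"))
  set.seed(spec$seed)
  h <- spec$sample_height_mm
  d <- seq(0, spec$max_displacement_mm, length.out = spec$n_points)
  strain <- d / h
  stress <- spec$stress_scale_mpa * strain^spec$nonlinearity_exponent
  if (spec$direction == "T") {
    ef <- spec$failure_strain
    s_fail <- spec$stress_scale_mpa * ef^spec$nonlinearity_exponent
    post <- strain > ef
    drop <- pmin(1, (strain[post] - ef) / 0.02)
    stress[post] <- s_fail * (1 - 0.75 * drop) * exp(-(strain[post] - ef))
  }
  force <- stress * spec$cross_section_mm2
  if (spec$noise_sd > 0) force <- pmax(0, force + rnorm(length(force), 0, spec$noise_sd))
  i0 <- which(force > spec$trigger_n)[1]
  if (is.na(i0)) stop("curve never exceeds the trigger force")
  d_out <- d[i0:length(d)] - d[i0]
  f_out <- force[i0:length(d)]
  rec <- mechanical_record(d_out, f_out, h, spec$cross_section_mm2,
                           spec$direction)
  attr(rec, "spec") <- spec
  rec
}

#' Write a mechanical record to CSV
#'
#' @param rec a `mechanical_record`.
#' @param path output CSV path (columns `displacement_mm`, `force_n`).
#' @return `path`, invisibly.
#' @export
write_mechanical_record <- function(rec, path) {
  write.csv(data.frame(displacement_mm = rec$displacement_mm,
                       force_n = rec$force_n), path, row.names = FALSE)
  invisible(path)
}
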