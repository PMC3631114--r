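#' Acoustic-emission record
#'
#' A sampled AE voltage series, optionally with a synchronized force
#' channel (used for load- or strain-based cutoffs).
#'
#' @param waveform numeric voltage samples.
#' @param sampling_rate_hz sampling rate (default 44000 S/s).
#' @param force_channel optional data.frame with `time_s`, `force_n` and
#'   optionally `strain`, synchronized with the waveform.
#' @return An `ae_record` list.
#' @export
ae_record <- function(waveform, sampling_rate_hz = 44000,
                      force_channel = NULL) {
  stopifnot(is.numeric(waveform), length(waveform) > 0, sampling_rate_hz > 0)
  if (!is.null(force_channel)) {
    stopifnot(is.data.frame(force_channel),
              all(c("time_s", "force_n") %in% names(force_channel)))
  }
  structure(list(waveform = as.numeric(waveform),
                 sampling_rate_hz = sampling_rate_hz,
                 force_channel = force_channel),
            class = "ae_record")
}

#' @export
print.ae_record <- function(x, ...) {
  cat(sprintf("ae_record: %.2f s at %g S/s%s\n",
              length(x$waveform) / x$sampling_rate_hz, x$sampling_rate_hz,
              if (is.null(x$force_channel)) "" else " (+force channel)"))
  invisible(x)
}

# Baseline noise RMS: RMS over the quietest decile of 0.1 s bins, robust
# when emission starts immediately.
baseline_rms <- function(v, fs) {
  bin <- pmax(1L, round(0.1 * fs))
  nb <- max(1L, floor(length(v) / bin))
  rms <- vapply(seq_len(nb), function(i) {
    sqrt(mean(v[((i - 1L) * bin + 1L):(i * bin)]^2))
  }, numeric(1))
  q <- quantile(rms, 0.1, names = FALSE, type = 7)
  sel <- rms <= q
  if (!any(sel)) sel <- which.min(rms)
  sqrt(mean(rms[sel]^2))
}

#' Detect AE events by threshold crossing with dead time
#'
#' Standard AE hit logic: the detection threshold is
#' `threshold_factor x baseline RMS` (baseline estimated from the
#' quietest decile of 0.1 s bins); an event opens when `|v|` crosses the
#' threshold and closes when `|v|` stays below it for `dead_time_s`.
#' Sub-threshold gaps shorter than the dead time are merged into one
#' event. Event energy is the sum of squared samples over the event span
#' (arbitrary units).
#'
#' @param rec an [ae_record].
#' @param threshold_factor multiple of the baseline RMS (default 5).
#' @param dead_time_s closing dead time in seconds (default 0.002).
#' @return data.frame of events: `onset_s`, `end_s`, `peak_amplitude_v`,
#'   `energy_au`; the threshold used is attached as attribute
#'   `threshold_v`. A detected rate above 50 events/s triggers a warning
#'   (threshold likely below the noise floor).
#' @export
detect_events <- function(rec, threshold_factor = 5, dead_time_s = 0.002) {
  stopifnot(inherits(rec, "ae_record"), threshold_factor > 0, dead_time_s > 0)
  v <- rec$waveform; fs <- rec$sampling_rate_hz
  empty <- data.frame(onset_s = numeric(), end_s = numeric(),
                      peak_amplitude_v = numeric(), energy_au = numeric())
  if (all(v == 0)) return(empty)
  thr <- threshold_factor * baseline_rms(v, fs)
  above <- abs(v) >= thr
  if (!any(above)) {
    attr(empty, "threshold_v") <- thr
    return(empty)
  }
  dead <- max(1L, round(dead_time_s * fs))
  r <- rle(above)
  # merge interior sub-threshold gaps shorter than the dead time
  interior <- which(!r$values & r$lengths < dead)
  interior <- interior[interior > 1L & interior < length(r$values)]
  r$values[interior] <- TRUE
  r <- rle(inverse.rle(r))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values
  ev_start <- starts[sel]; ev_end <- ends[sel]
  events <- data.frame(
    onset_s = (ev_start - 1L) / fs,
    end_s = ev_end / fs,
    peak_amplitude_v = vapply(seq_along(ev_start), function(i) {
      max(abs(v[ev_start[i]:ev_end[i]]))
    }, numeric(1)),
    energy_au = vapply(seq_along(ev_start), function(i) {
      sum(v[ev_start[i]:ev_end[i]]^2)
    }, numeric(1))
  )
  dur <- length(v) / fs
  if (nrow(events) / dur > 50 || mean(above) > 0.1) {
    warning("threshold appears to sit below the noise floor (event rate > 50/s or > 10% of samples above threshold)")
  }
  attr(events, "threshold_v") <- thr
  events
}

#' Bin AE events and accumulate to a cutoff
#'
#' Assigns events to 0.1 s bins by onset time and accumulates event
#' counts and energies from the start of the record to a cutoff:
#' * `"pct95_max_load"`: the first time, on the rising branch of the
#'   force channel, at which force reaches 95% of its maximum (avoids
#'   signals from the final fracture of a transverse test);
#' * `"strain_50pct"`: the time at which strain reaches 0.50
#'   (longitudinal tests, which never fracture);
#' * `"none"`: the full record.
#'
#' A cutoff lying beyond the record accumulates over the full record with
#' a warning.
#'
#' @param rec an [ae_record] with a force channel when `cutoff != "none"`.
#' @param events event table from [detect_events()].
#' @param cutoff cutoff rule.
#' @return The record with `bins` (data.frame `t_start`, `event_count`,
#'   `energy_au`), `cumulative_events`, `cumulative_energy_au` and
#'   `cutoff_s` filled.
#' @export
bin_and_accumulate <- function(rec, events,
                               cutoff = c("none", "pct95_max_load",
                                          "strain_50pct")) {
  stopifnot(inherits(rec, "ae_record"))
  cutoff <- match.arg(cutoff)
  duration <- length(rec$waveform) / rec$sampling_rate_hz
  nb <- max(1L, ceiling(duration / 0.1 - 1e-9))
  if (nrow(events) > 0 && is.unsorted(events$onset_s)) {
    events <- events[order(events$onset_s), ]
  }

  cutoff_s <- duration
  if (cutoff != "none") {
    fc <- rec$force_channel
    if (is.null(fc)) stop("cutoff '", cutoff, "' needs a force channel")
    if (cutoff == "pct95_max_load") {
      imax <- which.max(fc$force_n)
      j <- which(fc$force_n[1:imax] >= 0.95 * fc$force_n[imax])[1]
      cutoff_s <- fc$time_s[j]
    } else {
      if (is.null(fc$strain)) stop("strain_50pct cutoff needs a strain column")
      if (max(fc$strain) < 0.5) {
        cutoff_s <- Inf
      } else {
        cutoff_s <- approx(fc$strain, fc$time_s, xout = 0.5,
                           ties = "ordered")$y
      }
    }
    if (!is.finite(cutoff_s) || cutoff_s > duration) {
      warning("cutoff time beyond the record; accumulating over the full record")
      cutoff_s <- duration
    }
  }

  if (nrow(events) > 0) {
    bi <- pmin(floor(events$onset_s / 0.1) + 1L, nb)
    counts <- tabulate(bi, nbins = nb)
    energies <- numeric(nb)
    agg <- rowsum(events$energy_au, bi)
    energies[as.integer(rownames(agg))] <- agg[, 1]
    sel <- events$onset_s <= cutoff_s
  } else {
    counts <- integer(nb); energies <- numeric(nb); sel <- logical(0)
  }
  rec$bins <- data.frame(t_start = (seq_len(nb) - 1L) * 0.1,
                         event_count = counts, energy_au = energies)
  rec$cumulative_events <- sum(sel)
  rec$cumulative_energy_au <- if (any(sel)) sum(events$energy_au[sel]) else 0
  rec$cutoff_s <- cutoff_s
  rec$cutoff_rule <- cutoff
  rec
}

#' Specification for a synthetic AE waveform
#'
#' Gaussian baseline noise plus exponentially decaying sinusoidal bursts
#' at Poisson onset times. A fraction of bursts carries energy 5--15
#' times the basic signal (the high-energy population superimposed on the
#' near-continuous low-energy emission seen in demineralized matrix).
#'
#' @param sampling_rate_hz default 44000.
#' @param duration_s record length in seconds.
#' @param baseline_noise_sd noise SD in volts (default 0.01).
#' @param event_rate_hz mean burst rate (default 20/s).
#' @param event_energy_scale basic burst peak amplitude in volts
#'   (default 0.12, ~12x the default noise RMS).
#' @param high_energy_fraction fraction of high-energy bursts (default 0.1).
#' @param high_energy_multiplier energy multiplier for the high
#'   population; a scalar or a range to sample from (default c(5, 15)).
#' @param burst_decay_s burst energy decay time constant (default 2 ms).
#' @param event_times_s optional explicit onset times overriding the
#'   Poisson draw (useful for fixtures).
#' @param seed integer seed.
#' @return A validated list of class `ae_spec`.
#' @export
ae_spec <- function(sampling_rate_hz = 44000, duration_s = 10,
                    baseline_noise_sd = 0.01, event_rate_hz = 20,
                    event_energy_scale = 0.12, high_energy_fraction = 0.1,
                    high_energy_multiplier = c(5, 15), burst_decay_s = 0.002,
                    event_times_s = NULL, seed = 1L) {
  if (length(high_energy_multiplier) == 1L) {
    high_energy_multiplier <- rep(high_energy_multiplier, 2L)
  }
  stopifnot(sampling_rate_hz > 0, duration_s > 0, baseline_noise_sd >= 0,
            event_rate_hz >= 0, event_energy_scale > 0,
            high_energy_fraction >= 0, high_energy_fraction <= 1,
            length(high_energy_multiplier) == 2L,
            all(high_energy_multiplier >= 1),
            burst_decay_s > 0)
  structure(list(sampling_rate_hz = sampling_rate_hz, duration_s = duration_s,
                 baseline_noise_sd = baseline_noise_sd,
                 event_rate_hz = event_rate_hz,
                 event_energy_scale = event_energy_scale,
                 high_energy_fraction = high_energy_fraction,
                 high_energy_multiplier = high_energy_multiplier,
                 burst_decay_s = burst_decay_s,
                 event_times_s = event_times_s, seed = as.integer(seed)),
            class = "ae_spec")
}

#' Generate a synthetic AE waveform with ground truth
#'
#' @param spec an [ae_spec()].
#' @return An `ae_record` with attribute `truth`: data.frame of injected
#'   events (`onset_s`, `energy_au` = exact sum of squared burst samples,
#'   `peak_v`, `is_high`).
#' @export
generate_ae_waveform <- function(spec) {
  stopifnot(inherits(spec, "ae_spec"))
  set.seed(spec$seed)
  fs <- spec$sampling_rate_hz
  n <- round(fs * spec$duration_s)
  v <- if (spec$baseline_noise_sd > 0) rnorm(n, 0, spec$baseline_noise_sd) else numeric(n)

  if (!is.null(spec$event_times_s)) {
    onsets <- sort(spec$event_times_s)
  } else if (spec$event_rate_hz > 0) {
    n_ev <- rpois(1, spec$event_rate_hz * spec$duration_s)
    onsets <- sort(runif(n_ev, 0, max(spec$duration_s - 5 * spec$burst_decay_s, 0)))
  } else {
    onsets <- numeric(0)
  }
  stopifnot(!anyDuplicated(onsets))

  truth <- data.frame(onset_s = numeric(), energy_au = numeric(),
                      peak_v = numeric(), is_high = logical())
  tau <- spec$burst_decay_s
  len <- round(fs * 5 * tau)
  for (t0 in onsets) {
    f0 <- runif(1, 2000, 8000)
    amp <- spec$event_energy_scale * runif(1, 0.8, 1.2)
    is_high <- runif(1) < spec$high_energy_fraction
    mult <- if (is_high) runif(1, spec$high_energy_multiplier[1],
                               spec$high_energy_multiplier[2]) else 1
    amp <- amp * sqrt(mult)
    i0 <- min(round(t0 * fs) + 1L, n)
    i1 <- min(i0 + len - 1L, n)
    tt <- (seq(i0, i1) - i0) / fs
    burst <- amp * exp(-tt / tau) * sin(2 * pi * f0 * tt)
    v[i0:i1] <- v[i0:i1] + burst
    truth <- rbind(truth, data.frame(onset_s = (i0 - 1L) / fs,
                                     energy_au = sum(burst^2),
                                     peak_v = max(abs(burst)),
                                     is_high = is_high))
  }
  rec <- ae_record(v, fs)
  attr(rec, "truth") <- truth
  rec
}

#' Write an AE waveform to single-column CSV
#'
#' @param rec an `ae_record`.
#' @param path output CSV path (column `voltage_v`); the sampling rate is
#'   stored in a JSON sidecar at `path` + `.json`.
#' @return `path`, invisibly.
#' @export
write_ae_waveform <- function(rec, path) {
  write.csv(data.frame(voltage_v = rec$waveform), path, row.names = FALSE)
  jsonlite::write_json(list(sampling_rate_hz = rec$sampling_rate_hz),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an AE waveform from CSV (+ JSON sidecar)
#'
#' @param path CSV path written by [write_ae_waveform()], or any
#'   single-column CSV; `sampling_rate_hz` overrides the sidecar.
#' @param sampling_rate_hz sampling rate; required when no sidecar exists.
#' @return An `ae_record`.
#' @export
read_ae_waveform <- function(path, sampling_rate_hz = NULL) {
  d <- read.csv(path)
  if (ncol(d) != 1L) stop("waveform CSV must have a single column")
  if (is.null(sampling_rate_hz)) {
    side <- paste0(path, ".json")
    if (!file.exists(side)) stop("no sampling rate given and no sidecar found")
    sampling_rate_hz <- jsonlite::read_json(side)$sampling_rate_hz
  }
  ae_record(d[[1]], sampling_rate_hz)
}
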