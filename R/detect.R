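#' Raw recording container
#'
#' Sensors-by-samples voltage matrix with its recording metadata.
#'
#' @param samples numeric matrix, sensors x samples, in uV.
#' @param sampling_rate sampling rate (Hz).
#' @param sensor_ids integer sensor identifiers (0-based by convention).
#' @param subarray integer subarray id per sensor.
#' @param adc_bits ADC resolution (bits).
#' @param adc_range ADC input range (uV), \code{c(lo, hi)}.
#' @param valid logical per-sensor validity flags.
#' @param seed seed provenance (informational).
#' @return an object of class \code{raw_recording}.
#' @export
raw_recording <- function(samples, sampling_rate, sensor_ids = NULL,
                          subarray = NULL, adc_bits = 10,
                          adc_range = c(-512, 512), valid = NULL, seed = NA) {
  samples <- as.matrix(samples)
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  n <- nrow(samples)
  if (is.null(sensor_ids)) sensor_ids <- seq_len(n) - 1L
  if (length(sensor_ids) != n) {
    stop("length of 'sensor_ids' must equal the number of matrix rows", call. = FALSE)
  }
  if (is.null(subarray)) subarray <- rep(1L, n)
  if (is.null(valid)) valid <- rep(TRUE, n)
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         sensor_ids = as.integer(sensor_ids), subarray = as.integer(subarray),
         adc_bits = as.integer(adc_bits), adc_range = as.numeric(adc_range),
         valid = as.logical(valid), seed = seed),
    class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat("<raw_recording>", nrow(x$samples), "sensors x", ncol(x$samples),
      sprintf("samples @ %g Hz (%.1f s)\n", x$sampling_rate,
              ncol(x$samples) / x$sampling_rate))
  invisible(x)
}

#' Bandpass filter specification
#'
#' The high-density preset is a 300-7000 Hz third-order Butterworth applied
#' forward-backward (zero phase) so spike timing is preserved; the
#' low-density preset is 200-2500 Hz.
#'
#' @param low_cut low band edge (Hz).
#' @param high_cut high band edge (Hz).
#' @param order filter order.
#' @param zero_phase apply forward-backward (no time shift)?
#' @return an object of class \code{filter_spec}.
#' @export
filter_spec <- function(low_cut = 300, high_cut = 7000, order = 3,
                        zero_phase = TRUE) {
  stopifnot_scalar(low_cut, "low_cut", positive = TRUE)
  stopifnot_scalar(high_cut, "high_cut", positive = TRUE)
  if (low_cut >= high_cut) stop("'low_cut' must be below 'high_cut'", call. = FALSE)
  structure(list(low_cut = low_cut, high_cut = high_cut,
                 order = as.integer(order), zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' @rdname filter_spec
#' @export
ld_filter_spec <- function() filter_spec(200, 2500)

butter_coefs <- function(spec, sampling_rate) {
  nyq <- sampling_rate / 2
  if (spec$high_cut >= nyq) {
    stop(sprintf("high band edge %g Hz is at or above Nyquist (%g Hz)",
                 spec$high_cut, nyq), call. = FALSE)
  }
  bf <- signal::butter(spec$order, c(spec$low_cut, spec$high_cut) / nyq,
                       type = "pass")
  list(b = bf$b, a = bf$a)
}

# Zero-phase (or single-pass) application of an IIR filter to one trace.
apply_filter <- function(x, coefs, zero_phase = TRUE) {
  if (zero_phase) iir_filtfilt(coefs$b, coefs$a, x) else iir_filter(coefs$b, coefs$a, x)
}

#' Bandpass-filter a raw recording
#'
#' Applies the Butterworth bandpass per sensor. In zero-phase mode the
#' filter runs forward and backward so in-band features keep their timing.
#'
#' @param rec a \code{\link{raw_recording}}.
#' @param spec a \code{\link{filter_spec}}.
#' @return a \code{\link{raw_recording}} with filtered samples.
#' @export
bandpass_filter <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "raw_recording"), inherits(spec, "filter_spec"))
  coefs <- butter_coefs(spec, rec$sampling_rate)
  out <- rec
  for (i in seq_len(nrow(rec$samples))) {
    out$samples[i, ] <- apply_filter(rec$samples[i, ], coefs, spec$zero_phase)
  }
  out
}

#' Estimate the noise scale of a trace
#'
#' \code{"mad"} returns the unscaled median absolute deviation
#' \code{median(|x - median(x)|)} (no Gaussian consistency factor: for
#' Gaussian noise of standard deviation sigma it converges to 0.6745 sigma);
#' \code{"sd"} returns the sample standard deviation.
#'
#' @param trace numeric vector (uV).
#' @param method \code{"mad"} or \code{"sd"}.
#' @return noise scale (uV).
#' @export
estimate_noise_scale <- function(trace, method = c("mad", "sd")) {
  method <- match.arg(method)
  if (!length(trace)) stop("empty trace", call. = FALSE)
  if (method == "mad") mad_unscaled(trace) else sd(trace)
}

#' Spike detector specification
#'
#' Negative-threshold peak detection. The high-density convention is a
#' threshold of -8 times the per-sensor unscaled MAD; the low-density
#' (multiwell) convention is -5.5 times the per-electrode standard
#' deviation, recomputed in 1 s bins (\code{bin_for_threshold}).
#'
#' @param noise_method \code{"mad"} or \code{"sd"}.
#' @param multiplier threshold multiplier; defaults to 8 for MAD and 5.5 for
#'   SD.
#' @param dead_time minimum separation between detected spikes (s); within a
#'   dead-time window only the deepest peak is kept.
#' @param bin_for_threshold optional bin length (s) over which the noise
#'   scale and threshold are recomputed (adaptive mode).
#' @return an object of class \code{detector_spec}.
#' @export
detector_spec <- function(noise_method = c("mad", "sd"), multiplier = NULL,
                          dead_time = 1e-3, bin_for_threshold = NULL) {
  noise_method <- match.arg(noise_method)
  if (is.null(multiplier)) multiplier <- if (noise_method == "mad") 8 else 5.5
  stopifnot_scalar(multiplier, "multiplier", positive = TRUE)
  stopifnot_scalar(dead_time, "dead_time")
  if (dead_time < 0) stop("'dead_time' must be >= 0", call. = FALSE)
  structure(list(noise_method = noise_method, multiplier = multiplier,
                 polarity = "negative", dead_time = dead_time,
                 bin_for_threshold = bin_for_threshold),
            class = "detector_spec")
}

#' @rdname detector_spec
#' @export
ld_detector_spec <- function() {
  detector_spec("sd", multiplier = 5.5, bin_for_threshold = 1)
}

dedupe_dead_time <- function(idx, amps, dead_samples) {
  if (length(idx) < 2L || dead_samples <= 0) return(idx)
  ord <- order(amps)              # deepest (most negative) first
  accepted <- integer(0)
  for (k in ord) {
    if (!length(accepted) || all(abs(idx[accepted] - idx[k]) > dead_samples)) {
      accepted <- c(accepted, k)
    }
  }
  sort(idx[accepted])
}

#' Detect spikes on one filtered trace
#'
#' Returns the local minima strictly below \code{-multiplier * noise_scale}.
#' Within any dead-time window only the deepest peak is kept. Times are the
#' peak sample index divided by the sampling rate, with t = 0 at trace
#' start.
#'
#' @param trace bandpass-filtered trace (uV).
#' @param sampling_rate sampling rate (Hz).
#' @param spec a \code{\link{detector_spec}}.
#' @param noise_scale precomputed noise scale; when \code{NULL} it is
#'   estimated from the trace with \code{spec$noise_method} (per bin when
#'   \code{spec$bin_for_threshold} is set).
#' @return list with \code{times} (s) and \code{amplitudes} (uV).
#' @export
detect_spikes <- function(trace, sampling_rate, spec = detector_spec(),
                          noise_scale = NULL) {
  stopifnot(inherits(spec, "detector_spec"))
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  n <- length(trace)
  dead_samples <- round(spec$dead_time * sampling_rate)
  if (is.null(spec$bin_for_threshold) || !is.null(noise_scale)) {
    if (is.null(noise_scale)) {
      noise_scale <- estimate_noise_scale(trace, spec$noise_method)
    }
    thr <- -spec$multiplier * noise_scale
    idx <- local_minima_below(trace, thr)
  } else {
    bin_samples <- max(1L, round(spec$bin_for_threshold * sampling_rate))
    starts <- seq.int(1L, n, by = bin_samples)
    idx <- integer(0)
    for (s0 in starts) {
      s1 <- min(n, s0 + bin_samples - 1L)
      seg <- trace[s0:s1]
      ns <- estimate_noise_scale(seg, spec$noise_method)
      if (ns <= 0) next
      idx <- c(idx, local_minima_below(seg, -spec$multiplier * ns) + s0 - 1L)
    }
  }
  idx <- dedupe_dead_time(idx, trace[idx], dead_samples)
  list(times = (idx - 1L) / sampling_rate, amplitudes = trace[idx])
}

#' Sensor quality control: saturated-sensor detection
#'
#' A sensor is invalid when the fraction of its samples lying within
#' \code{rail_tolerance_lsb} least-significant bits of either ADC rail
#' exceeds \code{max_saturated_fraction}. Invalid sensors are excluded from
#' all downstream metrics.
#'
#' @param rec a \code{\link{raw_recording}}.
#' @param rail_tolerance_lsb tolerance around the rails, in LSB.
#' @param max_saturated_fraction maximum tolerated fraction of rail samples.
#' @return logical vector of per-sensor validity.
#' @export
qc_sensors <- function(rec, rail_tolerance_lsb = 1, max_saturated_fraction = 0.01) {
  stopifnot(inherits(rec, "raw_recording"))
  lsb <- diff(rec$adc_range) / 2^rec$adc_bits
  tol <- rail_tolerance_lsb * lsb
  unname(apply(rec$samples, 1, function(x) {
    frac <- mean(x >= rec$adc_range[2] - tol | x <= rec$adc_range[1] + tol)
    frac <= max_saturated_fraction
  }))
}

saturation_fraction <- function(x, adc_range, adc_bits, rail_tolerance_lsb = 1) {
  tol <- rail_tolerance_lsb * diff(adc_range) / 2^adc_bits
  mean(x >= adc_range[2] - tol | x <= adc_range[1] + tol)
}

#' Classify active sensors
#'
#' A sensor is active when its detected spike rate is strictly above
#' \code{rate_threshold} and the sensor is valid.
#'
#' @param trains a \code{\link{spike_train_set}}.
#' @param rate_threshold activity threshold (Hz).
#' @return the train set with updated \code{active} flags and
#'   \code{rate_threshold}.
#' @export
classify_active <- function(trains, rate_threshold = 0.05) {
  stopifnot(inherits(trains, "spike_train_set"))
  if (trains$duration <= 0) stop("zero or negative recording duration", call. = FALSE)
  trains$rates <- vapply(trains$times, length, integer(1)) / trains$duration
  trains$active <- trains$rates > rate_threshold & trains$valid
  trains$rate_threshold <- rate_threshold
  trains
}

#' End-to-end network activity detection on a simulated raw recording
#'
#' Runs the full raw-trace chain sensor by sensor without materialising the
#' array: render trace, saturation QC, zero-phase bandpass, per-sensor MAD
#' (or SD) noise estimate, negative-peak threshold detection, and active
#' classification.
#'
#' @param profile a \code{\link{genotype_profile}}.
#' @param config a \code{\link{sim_config}} (mode \code{"raw-trace"}).
#' @param fspec a \code{\link{filter_spec}}.
#' @param dspec a \code{\link{detector_spec}}.
#' @param rate_threshold active-sensor threshold (Hz).
#' @return list with \code{trains} (detected \code{\link{spike_train_set}}),
#'   \code{truth} (simulator ground truth) and \code{noise_scale}
#'   (per-sensor noise estimates, uV).
#' @export
detect_network_activity <- function(profile, config, fspec = filter_spec(),
                                    dspec = detector_spec(),
                                    rate_threshold = 0.05) {
  sim <- sample_spike_trains(profile, config)
  coefs <- butter_coefs(fspec, config$sampling_rate)
  n <- config$n_sensors
  times <- vector("list", n)
  amps <- vector("list", n)
  valid <- rep(TRUE, n)
  noise <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    x <- render_sensor_trace(sim, i)
    if (saturation_fraction(x, config$adc_range, config$adc_bits) > 0.01) {
      valid[i] <- FALSE
      times[[i]] <- numeric(0)
      amps[[i]] <- numeric(0)
      next
    }
    xf <- apply_filter(x, coefs, fspec$zero_phase)
    noise[i] <- estimate_noise_scale(xf, dspec$noise_method)
    det <- detect_spikes(xf, config$sampling_rate, dspec, noise_scale = noise[i])
    times[[i]] <- det$times
    amps[[i]] <- det$amplitudes
  }
  trains <- spike_train_set(times, config$duration, amplitudes = amps,
                            sensor_ids = sim$trains$sensor_ids,
                            subarray = sim$trains$subarray, valid = valid,
                            rate_threshold = rate_threshold)
  list(trains = trains, truth = sim$truth, noise_scale = noise)
}
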