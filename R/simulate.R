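#' Simulation configuration
#'
#' Describes the array geometry and recording parameters of a simulated MEA
#' recording. The seed fully determines the simulator output; each sensor
#' draws from its own deterministic substream so that results are identical
#' however the array is chunked.
#'
#' @param n_sensors number of sensors.
#' @param duration recording duration (s).
#' @param sampling_rate sampling rate (Hz), used in raw-trace mode.
#' @param n_subarrays number of subarrays; sensors are assigned to subarrays
#'   in contiguous blocks, and synchrony is computed within subarrays only.
#' @param seed master seed (integer).
#' @param mode \code{"spike-train"} (event times only) or \code{"raw-trace"}
#'   (continuous voltage traces).
#' @param saturated_fraction proportion of sensors rendered as rail-clipped
#'   (invalid) in raw-trace mode.
#' @param adc_bits ADC resolution (bits).
#' @param adc_range ADC input range in uV, \code{c(lo, hi)}.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_sensors, duration, sampling_rate = 20000,
                       n_subarrays = 1, seed = 1,
                       mode = c("spike-train", "raw-trace"),
                       saturated_fraction = 0,
                       adc_bits = 10, adc_range = c(-512, 512)) {
  mode <- match.arg(mode)
  stopifnot_scalar(n_sensors, "n_sensors", positive = TRUE)
  stopifnot_scalar(duration, "duration", positive = TRUE)
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  stopifnot_scalar(n_subarrays, "n_subarrays", positive = TRUE)
  stopifnot_scalar(seed, "seed")
  check_proportion(saturated_fraction, "saturated_fraction")
  if (length(adc_range) != 2L || adc_range[1] >= adc_range[2]) {
    stop("'adc_range' must be c(lo, hi) with lo < hi", call. = FALSE)
  }
  structure(
    list(n_sensors = as.integer(n_sensors), duration = duration,
         sampling_rate = sampling_rate, n_subarrays = as.integer(n_subarrays),
         seed = as.integer(seed), mode = mode,
         saturated_fraction = saturated_fraction,
         adc_bits = as.integer(adc_bits), adc_range = as.numeric(adc_range)),
    class = "sim_config")
}

subarray_assignment <- function(config) {
  rep(seq_len(config$n_subarrays),
      each = ceiling(config$n_sensors / config$n_subarrays))[seq_len(config$n_sensors)]
}

#' Construct a spike-train set
#'
#' The container used for per-sensor sorted spike times throughout the
#' package. Sensor identifiers are 0-based, matching the on-disk formats.
#'
#' @param times list of numeric vectors of sorted spike times (s), one per
#'   sensor.
#' @param duration recording duration (s).
#' @param amplitudes optional list of spike amplitudes (uV) parallel to
#'   \code{times}.
#' @param sensor_ids integer sensor identifiers (default \code{0:(n-1)}).
#' @param subarray integer subarray id per sensor.
#' @param valid logical validity flag per sensor (saturated sensors are
#'   invalid).
#' @param rate_threshold activity threshold (Hz) used to set the
#'   \code{active} flags; a sensor is active when its rate is strictly above
#'   the threshold and the sensor is valid.
#' @return an object of class \code{spike_train_set}.
#' @export
spike_train_set <- function(times, duration, amplitudes = NULL,
                            sensor_ids = NULL, subarray = NULL,
                            valid = NULL, rate_threshold = 0.05) {
  stopifnot_scalar(duration, "duration", positive = TRUE)
  n <- length(times)
  if (is.null(sensor_ids)) sensor_ids <- seq_len(n) - 1L
  if (is.null(subarray)) subarray <- rep(1L, n)
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (is.null(amplitudes)) amplitudes <- lapply(times, function(t) rep(NA_real_, length(t)))
  rates <- vapply(times, length, integer(1)) / duration
  structure(
    list(times = times, amplitudes = amplitudes, duration = duration,
         sensor_ids = as.integer(sensor_ids), subarray = as.integer(subarray),
         rates = rates, valid = as.logical(valid),
         active = rates > rate_threshold & valid,
         rate_threshold = rate_threshold),
    class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat("<spike_train_set>", length(x$times), "sensors,",
      sprintf("%.1f s", x$duration), "\n")
  cat(sprintf("  spikes: %d | valid: %d | active (> %.3g Hz): %d | mean rate (active): %.4g Hz\n",
              sum(lengths(x$times)), sum(x$valid), x$rate_threshold, sum(x$active),
              if (any(x$active)) mean(x$rates[x$active]) else NA_real_))
  invisible(x)
}

poisson_train <- function(rate, duration) {
  if (rate <= 0) return(numeric(0))
  n <- rpois(1L, rate * duration)
  sort(runif(n, 0, duration))
}

burst_train <- function(profile, duration) {
  n_bursts <- rpois(1L, duration / profile$ibi_mean)
  if (n_bursts == 0L) {
    return(list(times = numeric(0),
                bursts = data.frame(onset = numeric(0), n_spikes = integer(0))))
  }
  onsets <- sort(runif(n_bursts, 0, duration))
  times <- vector("list", n_bursts)
  n_kept <- integer(n_bursts)
  for (k in seq_len(n_bursts)) {
    n_spk <- 3L + rpois(1L, profile$spikes_per_burst_mean - 3)
    tt <- onsets[k] + cumsum(c(0, rexp(n_spk - 1L, 1 / profile$intra_burst_isi_mean)))
    tt <- tt[tt < duration]
    times[[k]] <- tt
    n_kept[k] <- length(tt)
  }
  list(times = unlist(times),
       bursts = data.frame(onset = onsets, n_spikes = n_kept))
}

#' Sample spike trains with known ground truth
#'
#' Generates one simulated recording at spike-train level: background
#' sensors fire homogeneous Poisson at the profile rate, bursting sensors
#' superpose an exponential-interval renewal burst process, and assembly
#' members copy events of a shared mother train (with jitter and thinning)
#' plus independent makeup spikes. Assemblies are confined to single
#' subarrays so that subarray-local synchrony can see them.
#'
#' @param profile a \code{\link{genotype_profile}}.
#' @param config a \code{\link{sim_config}} with \code{mode = "spike-train"}
#'   (raw-trace configs are accepted; rendering is a separate step).
#' @return a list of class \code{mea_simulation} with elements
#'   \code{trains} (a \code{\link{spike_train_set}}) and \code{truth}
#'   (ground truth: true spike times, assembly membership, true bursts,
#'   saturated sensors).
#' @examples
#' sim <- sample_spike_trains(mea_profile("deletion", 28),
#'                            sim_config(64, 60, seed = 1))
#' sim$trains
#' @export
sample_spike_trains <- function(profile, config) {
  stopifnot(inherits(profile, "genotype_profile"), inherits(config, "sim_config"))
  n <- config$n_sensors
  dur <- config$duration
  subarray <- subarray_assignment(config)

  exp_events <- profile$background_rate * dur
  if (profile$active_fraction > 0 && profile$background_rate > 0 && exp_events < 1) {
    warning(sprintf("expected events per active sensor is %.3g (< 1); consider a longer duration",
                    exp_events), call. = FALSE)
  }

  asm_size <- profile$assembly_size
  n_assemblies <- round(n * profile$assembly_fraction / asm_size)

  layout <- with_seed(config$seed, {
    bg <- sort(sample.int(n, round(n * profile$active_fraction)))
    member_of <- rep(NA_integer_, n)
    if (n_assemblies > 0) {
      sub_of_asm <- rep(seq_len(config$n_subarrays), length.out = n_assemblies)
      free <- seq_len(n)
      for (a in seq_len(n_assemblies)) {
        pool <- free[subarray[free] == sub_of_asm[a]]
        if (length(pool) < asm_size) pool <- free
        mem <- sample(pool, asm_size)
        member_of[mem] <- a
        free <- setdiff(free, mem)
      }
    }
    non_members <- which(is.na(member_of))
    bursters <- sort(sample(non_members, min(length(non_members),
                                             round(n * profile$burster_fraction))))
    saturated <- sort(sample.int(n, round(n * config$saturated_fraction)))
    list(bg = bg, member_of = member_of, bursters = bursters, saturated = saturated)
  })

  mother <- list()
  if (n_assemblies > 0) {
    asm_seeds <- substream_seeds(config$seed, n_assemblies, "assembly")
    mother <- lapply(seq_len(n_assemblies), function(a) {
      with_seed(asm_seeds[a], poisson_train(profile$background_rate, dur))
    })
  }

  spike_seeds <- substream_seeds(config$seed, n, "spikes")
  is_bg <- logical(n); is_bg[layout$bg] <- TRUE
  is_burster <- logical(n); is_burster[layout$bursters] <- TRUE

  times <- vector("list", n)
  burst_truth <- vector("list", n)
  for (i in seq_len(n)) {
    res <- with_seed(spike_seeds[i], {
      tt <- numeric(0)
      bursts_i <- NULL
      a <- layout$member_of[i]
      if (!is.na(a)) {
        mt <- mother[[a]]
        keep <- runif(length(mt)) < profile$copy_prob
        copied <- mt[keep] + rnorm(sum(keep), 0, profile$jitter_sd)
        makeup <- poisson_train((1 - profile$copy_prob) * profile$background_rate, dur)
        tt <- c(copied[copied >= 0 & copied < dur], makeup)
      } else if (is_bg[i]) {
        tt <- poisson_train(profile$background_rate, dur)
      }
      if (is_burster[i]) {
        bt <- burst_train(profile, dur)
        keep_b <- bt$bursts$n_spikes >= 3L
        if (any(keep_b)) {
          bursts_i <- data.frame(sensor = i - 1L,
                                 onset = bt$bursts$onset[keep_b],
                                 n_spikes = bt$bursts$n_spikes[keep_b])
        }
        tt <- c(tt, bt$times)
      }
      list(times = sort(tt), bursts = bursts_i)
    })
    times[[i]] <- res$times
    burst_truth[[i]] <- res$bursts
  }

  valid <- rep(TRUE, n)
  valid[layout$saturated] <- FALSE
  trains <- spike_train_set(times, dur, sensor_ids = seq_len(n) - 1L,
                            subarray = subarray, valid = valid)
  truth <- list(
    true_spike_times = times,
    assembly_membership = layout$member_of,
    true_bursts = if (length(bt <- Filter(Negate(is.null), burst_truth))) {
      do.call(rbind, bt)
    } else {
      data.frame(sensor = integer(0), onset = numeric(0), n_spikes = integer(0))
    },
    saturated_sensors = layout$saturated - 1L)
  structure(list(trains = trains, truth = truth, profile = profile,
                 config = config),
            class = "mea_simulation")
}

#' @export
print.mea_simulation <- function(x, ...) {
  cat("<mea_simulation>", x$profile$label, "|", x$config$mode, "\n")
  print(x$trains)
  invisible(x)
}

#' Biphasic extracellular spike template
#'
#' One period of a negative-leading sine, normalised to a negative peak of
#' -1, spanning \code{width} seconds. The exact shape is irrelevant to
#' threshold detection; what matters is the ~1 ms biphasic footprint whose
#' energy lies inside the 300-7000 Hz detection band.
#'
#' @param sampling_rate sampling rate (Hz).
#' @param width template width (s).
#' @return list with the waveform (\code{shape}) and the 1-based index of
#'   its negative peak (\code{peak}).
#' @keywords internal
biphasic_template <- function(sampling_rate, width = 1e-3) {
  n_t <- round(width * sampling_rate)
  if (n_t < 4) {
    stop(sprintf("sampling rate %g Hz is below Nyquist for a %.3g s biphasic template",
                 sampling_rate, width), call. = FALSE)
  }
  s <- (seq_len(n_t) - 0.5) / n_t
  w <- -sin(2 * pi * s)
  w <- w / abs(min(w))
  list(shape = w, peak = which.min(w))
}

#' Render the raw voltage trace of one sensor
#'
#' Streams the raw-trace rendering one sensor at a time so a full array
#' never needs to reside in memory: Gaussian noise plus a biphasic template
#' centred (negative peak) at each true spike time; overlapping templates
#' sum. Sensors listed as saturated in the ground truth are rendered as
#' rail-clipped segments. Deterministic per-sensor noise substreams make the
#' result independent of rendering order.
#'
#' @param sim a \code{mea_simulation} from \code{\link{sample_spike_trains}}.
#' @param sensor 1-based sensor index.
#' @return numeric vector of length \code{duration * sampling_rate} (uV).
#' @export
render_sensor_trace <- function(sim, sensor) {
  stopifnot(inherits(sim, "mea_simulation"))
  config <- sim$config
  profile <- sim$profile
  ns <- round(config$duration * config$sampling_rate)
  tpl <- biphasic_template(config$sampling_rate)
  noise_seed <- substream_seeds(config$seed, config$n_sensors, "noise")[sensor]
  trace <- with_seed(noise_seed, {
    x <- if (profile$noise_sd > 0) rnorm(ns, 0, profile$noise_sd) else numeric(ns)
    if ((sensor - 1L) %in% sim$truth$saturated_sensors) {
      # rail-clipped sensor: several long segments pinned at the positive rail
      n_seg <- 5L
      starts <- sort(sample.int(ns, n_seg))
      seg_len <- round(0.04 * ns)
      for (s0 in starts) {
        idx <- s0:min(ns, s0 + seg_len)
        x[idx] <- config$adc_range[2]
      }
      x
    } else {
      tt <- sim$truth$true_spike_times[[sensor]]
      if (length(tt)) {
        n_t <- length(tpl$shape)
        for (t1 in tt) {
          i0 <- round(t1 * config$sampling_rate) + 1L - (tpl$peak - 1L)
          lo <- max(1L, i0); hi <- min(ns, i0 + n_t - 1L)
          if (lo <= hi) {
            x[lo:hi] <- x[lo:hi] + profile$spike_amp * tpl$shape[(lo - i0 + 1L):(hi - i0 + 1L)]
          }
        }
      }
      x
    }
  })
  trace
}

#' Render a full raw recording
#'
#' Materialises (or streams to disk) the raw voltage traces of a simulated
#' recording. With \code{file} set, traces are written sensor-major as
#' little-endian 32-bit floats with a JSON sidecar
#' (\code{\link{write_raw_recording}} format) without ever holding the full
#' array in memory.
#'
#' @param sim a \code{mea_simulation} (see \code{\link{sample_spike_trains}}).
#' @param file optional path prefix; when given, writes
#'   \code{<file>.bin} + \code{<file>.json} and returns the prefix
#'   invisibly.
#' @return a \code{\link{raw_recording}} (in-memory), or the file prefix.
#' @export
render_raw_recording <- function(sim, file = NULL) {
  stopifnot(inherits(sim, "mea_simulation"))
  config <- sim$config
  ns <- round(config$duration * config$sampling_rate)
  if (is.null(file)) {
    if (as.double(config$n_sensors) * ns > 2e8) {
      stop("recording too large to hold in memory; pass 'file' to stream to disk",
           call. = FALSE)
    }
    samples <- matrix(0, nrow = config$n_sensors, ncol = ns)
    for (i in seq_len(config$n_sensors)) samples[i, ] <- render_sensor_trace(sim, i)
    raw_recording(samples, config$sampling_rate,
                  sensor_ids = sim$trains$sensor_ids,
                  subarray = sim$trains$subarray,
                  adc_bits = config$adc_bits, adc_range = config$adc_range,
                  seed = config$seed)
  } else {
    con <- file(paste0(file, ".bin"), "wb")
    on.exit(close(con))
    for (i in seq_len(config$n_sensors)) {
      writeBin(as.numeric(render_sensor_trace(sim, i)), con, size = 4,
               endian = "little")
    }
    write_recording_sidecar(paste0(file, ".json"),
                            n_sensors = config$n_sensors, n_samples = ns,
                            sampling_rate = config$sampling_rate,
                            sensor_ids = sim$trains$sensor_ids,
                            subarray = sim$trains$subarray,
                            adc_bits = config$adc_bits,
                            adc_range = config$adc_range,
                            duration = config$duration, seed = config$seed)
    invisible(file)
  }
}

#' Synthetic excitability cohort
#'
#' Generates \code{n_cells} current-clamp input-output curves from a common
#' piecewise-linear template whose 1-AP crossing sits at
#' \code{rheobase_target}, each cell shifted along the current axis by
#' zero-mean Gaussian jitter. The cohort-averaged curve therefore crosses
#' 1 AP at the target in expectation.
#'
#' @param rheobase_target target 1-AP crossing (pA).
#' @param n_cells number of cells.
#' @param jitter per-cell standard deviation of the current-axis shift (pA).
#' @param current_grid strictly increasing injected current steps (pA).
#' @param seed RNG seed.
#' @param slope AP-count slope above threshold (AP/pA); the template is
#'   \code{max(0, slope * (I - onset))} with \code{onset =
#'   rheobase_target - 1/slope}.
#' @return list of \code{\link{excitability_curve}} objects.
#' @export
make_excitability_cohort <- function(rheobase_target, n_cells, jitter = 1,
                                     current_grid = 0:20, seed = 1,
                                     slope = 1 / 3) {
  stopifnot_scalar(rheobase_target, "rheobase_target")
  stopifnot_scalar(n_cells, "n_cells", positive = TRUE)
  if (any(diff(current_grid) <= 0)) {
    stop("'current_grid' must be strictly increasing", call. = FALSE)
  }
  if (rheobase_target < min(current_grid) || rheobase_target > max(current_grid)) {
    stop("'rheobase_target' lies outside the current grid span", call. = FALSE)
  }
  onset <- rheobase_target - 1 / slope
  with_seed(seed, {
    shifts <- if (jitter > 0) rnorm(n_cells, 0, jitter) else numeric(n_cells)
    lapply(seq_len(n_cells), function(i) {
      counts <- pmax(0, slope * (current_grid - onset - shifts[i]))
      excitability_curve(current_grid, counts)
    })
  })
}
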