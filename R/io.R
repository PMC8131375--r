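# File formats: raw traces are flat little-endian 32-bit float, sensor-major,
# in uV, with a JSON sidecar; tables are TSV/CSV with headers, times in
# seconds at 6 decimals.

write_recording_sidecar <- function(path, n_sensors, n_samples, sampling_rate,
                                    sensor_ids, subarray, adc_bits, adc_range,
                                    duration, seed) {
  sidecar <- list(
    n_sensors = n_sensors, n_samples = n_samples,
    sampling_rate_hz = sampling_rate,
    sensor_ids = sensor_ids, subarray_of = subarray,
    adc_bits = adc_bits, adc_range_uv = adc_range,
    byte_order = "little", sample_type = "float32",
    duration_s = duration, seed = seed)
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a raw recording to disk
#'
#' Writes \code{<prefix>.bin} (flat little-endian float32, sensor-major, uV)
#' and \code{<prefix>.json} (sidecar with geometry and recording metadata).
#'
#' @param rec a \code{\link{raw_recording}}.
#' @param prefix path prefix (without extension).
#' @return the prefix, invisibly.
#' @export
write_raw_recording <- function(rec, prefix) {
  stopifnot(inherits(rec, "raw_recording"))
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(rec$samples))) {
    writeBin(as.numeric(rec$samples[i, ]), con, size = 4, endian = "little")
  }
  write_recording_sidecar(paste0(prefix, ".json"),
                          n_sensors = nrow(rec$samples),
                          n_samples = ncol(rec$samples),
                          sampling_rate = rec$sampling_rate,
                          sensor_ids = rec$sensor_ids,
                          subarray = rec$subarray,
                          adc_bits = rec$adc_bits, adc_range = rec$adc_range,
                          duration = ncol(rec$samples) / rec$sampling_rate,
                          seed = rec$seed)
  invisible(prefix)
}

#' Read a raw recording from disk
#'
#' Validates that the binary payload size matches the sidecar's declared
#' geometry (\code{n_sensors x n_samples x 4} bytes) and fails fast naming
#' the expected and found byte counts otherwise.
#'
#' @param prefix path prefix written by \code{\link{write_raw_recording}}.
#' @param sensors optional 1-based indices of the sensors to load.
#' @return a \code{\link{raw_recording}}.
#' @export
read_raw_recording <- function(prefix, sensors = NULL) {
  sidecar <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  bin_path <- paste0(prefix, ".bin")
  expected <- as.double(sidecar$n_sensors) * sidecar$n_samples * 4
  found <- file.info(bin_path)$size
  if (is.na(found) || found != expected) {
    stop(sprintf("payload size mismatch in '%s': expected %.0f bytes (%d sensors x %d samples x 4), found %.0f",
                 bin_path, expected, sidecar$n_sensors, sidecar$n_samples,
                 ifelse(is.na(found), 0, found)), call. = FALSE)
  }
  if (is.null(sensors)) sensors <- seq_len(sidecar$n_sensors)
  con <- file(bin_path, "rb")
  on.exit(close(con))
  samples <- matrix(0, nrow = length(sensors), ncol = sidecar$n_samples)
  for (k in seq_along(sensors)) {
    seek(con, (sensors[k] - 1) * sidecar$n_samples * 4)
    samples[k, ] <- readBin(con, "numeric", n = sidecar$n_samples, size = 4,
                            endian = "little")
  }
  raw_recording(samples, sidecar$sampling_rate_hz,
                sensor_ids = sidecar$sensor_ids[sensors],
                subarray = sidecar$subarray_of[sensors],
                adc_bits = sidecar$adc_bits, adc_range = sidecar$adc_range_uv,
                seed = sidecar$seed)
}

#' Write / read spike trains as TSV
#'
#' Column order is \code{sensor_id}, \code{time_s}, \code{amplitude_uV};
#' times and amplitudes carry 6 decimal places.
#'
#' @param trains a \code{\link{spike_train_set}}.
#' @param path output file.
#' @return the path (write) or a data frame (read), invisibly for write.
#' @export
write_spikes_tsv <- function(trains, path) {
  stopifnot(inherits(trains, "spike_train_set"))
  rows <- lapply(seq_along(trains$times), function(i) {
    tt <- trains$times[[i]]
    if (!length(tt)) return(NULL)
    data.frame(sensor_id = trains$sensor_ids[i], time_s = tt,
               amplitude_uV = trains$amplitudes[[i]])
  })
  df <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(df)) {
    df <- data.frame(sensor_id = integer(0), time_s = numeric(0),
                     amplitude_uV = numeric(0))
  }
  df$time_s <- sprintf("%.6f", df$time_s)
  df$amplitude_uV <- ifelse(is.na(df$amplitude_uV), "NA",
                            sprintf("%.6f", df$amplitude_uV))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes_tsv
#' @param duration recording duration (s), needed to rebuild the train set.
#' @param n_sensors total sensor count (ids run 0 to n_sensors - 1).
#' @export
read_spikes_tsv <- function(path, duration, n_sensors = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t")
  if (is.null(n_sensors)) n_sensors <- if (nrow(df)) max(df$sensor_id) + 1L else 0L
  times <- rep(list(numeric(0)), n_sensors)
  amps <- rep(list(numeric(0)), n_sensors)
  if (nrow(df)) {
    by_sensor <- split(df, df$sensor_id)
    for (b in by_sensor) {
      i <- b$sensor_id[1] + 1L
      ord <- order(b$time_s)
      times[[i]] <- b$time_s[ord]
      amps[[i]] <- b$amplitude_uV[ord]
    }
  }
  spike_train_set(times, duration, amplitudes = amps,
                  sensor_ids = seq_len(n_sensors) - 1L)
}

#' Write a burst table as TSV
#'
#' Columns: \code{sensor_id}, \code{first_spike_s}, \code{last_spike_s},
#' \code{n_spikes}, \code{duration_s}.
#'
#' @param bursts burst table from \code{\link{detect_bursts_all}}.
#' @param path output file.
#' @export
write_bursts_tsv <- function(bursts, path) {
  df <- data.frame(sensor_id = bursts$sensor,
                   first_spike_s = sprintf("%.6f", bursts$first_spike),
                   last_spike_s = sprintf("%.6f", bursts$last_spike),
                   n_spikes = bursts$n_spikes,
                   duration_s = sprintf("%.6f", bursts$duration))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synchrony result: pair table (TSV) and per-scan summary (CSV)
#'
#' @param sync a \code{\link{synchrony_summary}} result.
#' @param pair_path TSV path for the synchronized-pair table.
#' @param summary_path CSV path for the one-line scan summary.
#' @param scan_id identifier echoed into the summary row.
#' @export
write_synchrony <- function(sync, pair_path, summary_path, scan_id = "scan") {
  stopifnot(inherits(sync, "synchrony_result"))
  pr <- sync$pairs
  pr$r <- sprintf("%.6f", pr$r)
  write.table(pr, pair_path, sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- data.frame(scan_id = scan_id, n_valid = sync$n_valid,
                     n_active = sync$n_active,
                     n_synchronized = sync$n_synchronized,
                     fraction = sprintf("%.6f", sync$fraction))
  write.table(summ, summary_path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(c(pair_path, summary_path))
}
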