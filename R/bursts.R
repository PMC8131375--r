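#' Burst detector specification
#'
#' Parameters of the adaptive CMA (cumulative moving average) burst
#' detector. The ISI threshold is read off the CMA curve of the
#' inter-spike-interval histogram (see \code{\link{isi_threshold_cma}}); the
#' minimum number of spikes per burst is 3 by convention.
#'
#' \code{alpha_policy = "fixed"} (default) uses \code{alpha1} directly;
#' \code{"skewness_lookup"} selects alpha1 from the sample skewness of the
#' ISI distribution (\code{<1: 1.0, <4: 0.7, <9: 0.5, >=9: 0.3}), the
#' convention of the published CMA method. The fixed default
#' \code{alpha1 = 0.7} places the threshold near the geometric middle of the
#' intra/inter-burst ISI gap on bursty trains; see the package vignette for
#' the calibration analysis behind this choice.
#'
#' @param min_spikes minimum spikes per burst (>= 2).
#' @param isi_hist_bins number of ISI histogram bins.
#' @param isi_hist_scale \code{"log"} or \code{"linear"} bin spacing.
#' @param alpha_policy \code{"fixed"} or \code{"skewness_lookup"}.
#' @param alpha1 CMA decay fraction in (0, 1] used when
#'   \code{alpha_policy = "fixed"}.
#' @param max_isi_override optional hard cap (s) on the ISI threshold.
#' @return an object of class \code{burst_detector_spec}.
#' @export
burst_detector_spec <- function(min_spikes = 3, isi_hist_bins = 100,
                                isi_hist_scale = c("log", "linear"),
                                alpha_policy = c("fixed", "skewness_lookup"),
                                alpha1 = 0.7, max_isi_override = NULL) {
  isi_hist_scale <- match.arg(isi_hist_scale)
  alpha_policy <- match.arg(alpha_policy)
  stopifnot_scalar(min_spikes, "min_spikes")
  if (min_spikes < 2) stop("'min_spikes' must be >= 2", call. = FALSE)
  stopifnot_scalar(alpha1, "alpha1")
  if (alpha1 <= 0 || alpha1 > 1) stop("'alpha1' must be in (0, 1]", call. = FALSE)
  structure(list(min_spikes = as.integer(min_spikes),
                 isi_hist_bins = as.integer(isi_hist_bins),
                 isi_hist_scale = isi_hist_scale,
                 alpha_policy = alpha_policy, alpha1 = alpha1,
                 max_isi_override = max_isi_override),
            class = "burst_detector_spec")
}

alpha_from_skewness <- function(sk) {
  if (sk < 1) 1 else if (sk < 4) 0.7 else if (sk < 9) 0.5 else 0.3
}

#' Adaptive ISI threshold from the CMA of the ISI histogram
#'
#' Builds the inter-spike-interval histogram (log-spaced bins spanning 1 ms
#' to the recording duration by default), computes the cumulative moving
#' average of the bin counts, locates its maximum, and returns the ISI at
#' which the CMA has decayed to \code{alpha1} times that maximum.
#'
#' Two small-sample safeguards keep the threshold meaningful: ISIs below the
#' first histogram edge (1 ms) are excluded from the histogram (they are
#' unconditionally intra-burst and would otherwise fabricate an early CMA
#' maximum), and the maximum is taken only over bins that have accumulated
#' at least \code{max(2, 5\%)} of the ISI count.
#'
#' @param times sorted spike times (s).
#' @param spec a \code{\link{burst_detector_spec}}.
#' @param duration recording duration (s); defaults to the span of
#'   \code{times}.
#' @return ISI threshold (s), or \code{NA} when the train has fewer than
#'   \code{min_spikes} spikes or no threshold exists.
#' @references Kapucu et al. (2012) Front. Comput. Neurosci. 6:38 (original
#'   CMA burst detection method).
#' @export
isi_threshold_cma <- function(times, spec = burst_detector_spec(),
                              duration = NULL) {
  stopifnot(inherits(spec, "burst_detector_spec"))
  if (length(times) < spec$min_spikes) return(NA_real_)
  isis <- diff(times)
  if (length(isis) < 2L || any(isis < 0)) {
    if (any(isis < 0)) stop("spike times must be sorted", call. = FALSE)
    return(NA_real_)
  }
  if (is.null(duration)) duration <- max(times)
  nb <- spec$isi_hist_bins
  if (spec$isi_hist_scale == "log") {
    lo <- 1e-3
    hi <- max(duration, max(isis) * 1.001, lo * 10)
    edges <- 10^seq(log10(lo), log10(hi), length.out = nb + 1L)
    hv <- isis[isis >= lo]
  } else {
    edges <- seq(0, max(duration, max(isis) * 1.001), length.out = nb + 1L)
    hv <- isis
  }
  if (length(hv) < 2L) return(NA_real_)
  h <- tabulate(findInterval(pmin(hv, edges[nb + 1L]), edges,
                             rightmost.closed = TRUE), nb)
  cma <- cumsum(h) / seq_len(nb)
  eligible <- cumsum(h) >= max(2, 0.05 * length(hv))
  if (!any(eligible)) return(NA_real_)
  m <- which(eligible)[which.max(cma[eligible])]
  alpha1 <- if (spec$alpha_policy == "skewness_lookup") {
    alpha_from_skewness(sample_skewness(hv))
  } else spec$alpha1
  idx <- which(seq_len(nb) >= m & cma <= alpha1 * cma[m])
  if (!length(idx)) return(NA_real_)
  thr <- edges[idx[1] + 1L]
  if (!is.null(spec$max_isi_override)) thr <- min(thr, spec$max_isi_override)
  thr
}

#' Detect bursts on one spike train
#'
#' Groups maximal runs of consecutive spikes whose inter-spike intervals are
#' all at or below the adaptive CMA threshold; runs with at least
#' \code{min_spikes} spikes become bursts. Bursts are disjoint and ordered.
#'
#' @inheritParams isi_threshold_cma
#' @param threshold optional fixed ISI threshold (s) overriding the CMA
#'   computation (used by the brute-force oracle in tests).
#' @return data frame with one row per burst: \code{first_spike},
#'   \code{last_spike}, \code{n_spikes}, \code{duration} (all times in s).
#' @export
detect_bursts <- function(times, spec = burst_detector_spec(),
                          duration = NULL, threshold = NULL) {
  empty <- data.frame(first_spike = numeric(0), last_spike = numeric(0),
                      n_spikes = integer(0), duration = numeric(0))
  if (length(times) < spec$min_spikes) return(empty)
  if (is.null(threshold)) {
    threshold <- isi_threshold_cma(times, spec, duration)
  }
  if (is.na(threshold)) return(empty)
  grp <- cumsum(c(1L, as.integer(diff(times) > threshold)))
  runs <- rle(grp)$lengths
  ends <- cumsum(runs)
  starts <- ends - runs + 1L
  keep <- runs >= spec$min_spikes
  if (!any(keep)) return(empty)
  data.frame(first_spike = times[starts[keep]],
             last_spike = times[ends[keep]],
             n_spikes = as.integer(runs[keep]),
             duration = times[ends[keep]] - times[starts[keep]])
}

#' Detect bursts on every valid sensor of a train set
#'
#' @param trains a \code{\link{spike_train_set}}.
#' @param spec a \code{\link{burst_detector_spec}}.
#' @return data frame with columns \code{sensor} (0-based id),
#'   \code{first_spike}, \code{last_spike}, \code{n_spikes},
#'   \code{duration}.
#' @export
detect_bursts_all <- function(trains, spec = burst_detector_spec()) {
  stopifnot(inherits(trains, "spike_train_set"))
  out <- lapply(which(trains$valid), function(i) {
    b <- detect_bursts(trains$times[[i]], spec, duration = trains$duration)
    if (nrow(b)) cbind(sensor = trains$sensor_ids[i], b) else NULL
  })
  out <- Filter(Negate(is.null), out)
  if (!length(out)) {
    return(data.frame(sensor = integer(0), first_spike = numeric(0),
                      last_spike = numeric(0), n_spikes = integer(0),
                      duration = numeric(0)))
  }
  do.call(rbind, out)
}

#' Chip-level burst feature summary
#'
#' Burst features are computed from the pooled distribution of all bursts
#' detected across all sensors of a recording: mean spikes/burst, mean burst
#' duration, mean within-burst ISI (total within-burst time over total
#' within-burst intervals), and the mean inter-burst interval (between first
#' spikes of consecutive bursts on the same sensor, pooled over sensors).
#' The chip-level burst rate is the mean over all valid sensors (including
#' burst-free ones) of per-sensor bursts per minute. A recording is included
#' only when at least \code{inclusion_min} bursts were detected over all
#' sensors combined.
#'
#' @param bursts burst table from \code{\link{detect_bursts_all}}.
#' @param n_valid_sensors number of valid sensors in the recording.
#' @param duration recording duration (s).
#' @param inclusion_min minimum total bursts for inclusion.
#' @param rate_scope \code{"per_sensor"} (mean over all valid sensors,
#'   default) or \code{"chip"} (total bursts per minute per chip).
#' @return an object of class \code{burst_summary}.
#' @export
summarize_bursts <- function(bursts, n_valid_sensors, duration,
                             inclusion_min = 100,
                             rate_scope = c("per_sensor", "chip")) {
  rate_scope <- match.arg(rate_scope)
  stopifnot_scalar(duration, "duration", positive = TRUE)
  total <- nrow(bursts)
  minutes <- duration / 60
  if (total == 0L) {
    return(structure(list(total_bursts = 0L, included = FALSE,
                          bursts_per_min_all_sensors = 0,
                          mean_spikes_per_burst = NA_real_,
                          mean_duration = NA_real_,
                          mean_inter_burst_interval = NA_real_,
                          mean_within_burst_isi = NA_real_,
                          n_valid_sensors = n_valid_sensors,
                          duration = duration,
                          inclusion_min = inclusion_min),
                     class = "burst_summary"))
  }
  ibis <- unlist(lapply(split(bursts$first_spike, bursts$sensor), function(f) {
    if (length(f) > 1L) diff(sort(f)) else numeric(0)
  }), use.names = FALSE)
  rate <- if (rate_scope == "per_sensor") {
    total / minutes / n_valid_sensors
  } else {
    total / minutes
  }
  structure(
    list(total_bursts = total,
         included = total >= inclusion_min,
         bursts_per_min_all_sensors = rate,
         mean_spikes_per_burst = mean(bursts$n_spikes),
         mean_duration = mean(bursts$duration),
         mean_inter_burst_interval = if (length(ibis)) mean(ibis) else NA_real_,
         mean_within_burst_isi = sum(bursts$duration) / sum(bursts$n_spikes - 1L),
         n_valid_sensors = n_valid_sensors,
         duration = duration,
         inclusion_min = inclusion_min),
    class = "burst_summary")
}

#' @export
print.burst_summary <- function(x, ...) {
  cat("<burst_summary>", x$total_bursts, "bursts on", x$n_valid_sensors,
      sprintf("sensors over %.1f s%s\n", x$duration,
              if (x$included) "" else sprintf(" [excluded: < %d bursts]", x$inclusion_min)))
  if (x$total_bursts > 0) {
    cat(sprintf("  bursts/min per sensor: %.4g | spikes/burst: %.4g | duration: %.4g s\n",
                x$bursts_per_min_all_sensors, x$mean_spikes_per_burst, x$mean_duration))
    cat(sprintf("  inter-burst interval: %.4g s | within-burst ISI: %.4g s\n",
                x$mean_inter_burst_interval, x$mean_within_burst_isi))
  }
  invisible(x)
}

#' Rank bursting sensors and assemble a raster
#'
#' Ranks sensors in descending order of the per-sensor mean of the chosen
#' key (burst rate in bursts/min, or mean spikes per burst), breaking ties
#' by ascending sensor id, and returns the top \code{top_k} sensors with
#' their spike trains ordered for raster plotting (y index 0 is the
#' top-ranked sensor).
#'
#' @param bursts burst table from \code{\link{detect_bursts_all}}.
#' @param trains the \code{\link{spike_train_set}} the bursts came from.
#' @param key \code{"burst_rate"} or \code{"spikes_per_burst"}.
#' @param top_k number of sensors to keep.
#' @return an object of class \code{mea_raster}: ranking table plus the
#'   ordered spike trains; has \code{plot} and \code{\link{write_raster}}
#'   methods.
#' @export
rank_and_raster <- function(bursts, trains, key = c("burst_rate", "spikes_per_burst"),
                            top_k = 200) {
  key <- match.arg(key)
  if (top_k <= 0) stop("'top_k' must be > 0", call. = FALSE)
  stopifnot(inherits(trains, "spike_train_set"))
  if (nrow(bursts) == 0L) {
    ranking <- data.frame(sensor = integer(0), value = numeric(0))
  } else {
    per <- split(bursts, bursts$sensor)
    vals <- vapply(per, function(b) {
      if (key == "burst_rate") nrow(b) / (trains$duration / 60) else mean(b$n_spikes)
    }, numeric(1))
    ids <- as.integer(names(per))
    ord <- order(-vals, ids)
    ranking <- data.frame(sensor = ids[ord], value = unname(vals[ord]))
  }
  ranking <- head(ranking, top_k)
  pos <- match(ranking$sensor, trains$sensor_ids)
  structure(list(key = key, ranking = ranking,
                 spikes = trains$times[pos],
                 duration = trains$duration),
            class = "mea_raster")
}

#' @export
print.mea_raster <- function(x, ...) {
  cat("<mea_raster>", nrow(x$ranking), "sensors ranked by", x$key, "\n")
  if (nrow(x$ranking)) print(head(x$ranking, 5))
  invisible(x)
}

#' @export
plot.mea_raster <- function(x, ...) {
  n <- nrow(x$ranking)
  plot(NULL, xlim = c(0, x$duration), ylim = c(n, -1),
       xlab = "time (s)", ylab = "rank", main = paste("raster:", x$key), ...)
  for (k in seq_len(n)) {
    tt <- x$spikes[[k]]
    if (length(tt)) points(tt, rep(k - 1L, length(tt)), pch = "|", cex = 0.4)
  }
  invisible(x)
}

#' Export a raster to plain text and SVG
#'
#' Writes one spike-list text file (rank, sensor id, spike times) and an SVG
#' raster figure.
#'
#' @param x an \code{mea_raster}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_raster <- function(x, dir) {
  stopifnot(inherits(x, "mea_raster"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  txt <- file.path(dir, paste0("raster_", x$key, ".txt"))
  con <- file(txt, "w")
  writeLines("# rank\tsensor_id\tspike_times_s", con)
  for (k in seq_len(nrow(x$ranking))) {
    writeLines(sprintf("%d\t%d\t%s", k - 1L, x$ranking$sensor[k],
                       paste(sprintf("%.6f", x$spikes[[k]]), collapse = ",")), con)
  }
  close(con)
  svg_path <- file.path(dir, paste0("raster_", x$key, ".svg"))
  grDevices::svg(svg_path, width = 8, height = 6)
  plot(x)
  grDevices::dev.off()
  invisible(c(txt, svg_path))
}
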