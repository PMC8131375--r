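#' Interpolate per-unit metric series and aggregate by genotype
#'
#' Each recording unit (chip or well) contributes a series of (day, value)
#' observations. Every unit is linearly interpolated onto a common day grid
#' within its observed span (no extrapolation: grid days outside a unit's
#' span are missing for that unit), then units are averaged per genotype,
#' reporting mean, SEM (sample sd / sqrt(n)) and n at each grid day.
#'
#' @param series data frame with columns \code{unit_id}, \code{genotype},
#'   \code{day}, \code{value} (long format; one metric at a time).
#' @param day_grid numeric grid of days; defaults to the observed day range
#'   at 2-day spacing.
#' @return an object of class \code{group_summary}: data frame with columns
#'   \code{genotype}, \code{day}, \code{mean}, \code{sem}, \code{n}.
#' @export
interpolate_and_aggregate <- function(series, day_grid = NULL) {
  req <- c("unit_id", "genotype", "day", "value")
  if (!is.data.frame(series) || !all(req %in% names(series)) || nrow(series) == 0L) {
    stop("'series' must be a non-empty data frame with columns unit_id, genotype, day, value",
         call. = FALSE)
  }
  if (any(!is.finite(series$value))) stop("metric values must be finite", call. = FALSE)
  if (is.null(day_grid)) {
    day_grid <- seq(min(series$day), max(series$day), by = 2)
  }
  units <- split(series, series$unit_id)
  interp <- lapply(units, function(u) {
    u <- u[order(u$day), ]
    if (anyDuplicated(u$day)) {
      stop(sprintf("unit '%s' has duplicated days", u$unit_id[1]), call. = FALSE)
    }
    v <- if (nrow(u) == 1L) {
      ifelse(day_grid == u$day, u$value, NA_real_)
    } else {
      approx(u$day, u$value, xout = day_grid, method = "linear", rule = 1)$y
    }
    data.frame(genotype = u$genotype[1], day = day_grid, value = v)
  })
  long <- do.call(rbind, interp)
  long <- long[!is.na(long$value), ]
  if (nrow(long) == 0L) stop("no grid day falls inside any unit's observed span", call. = FALSE)
  agg <- do.call(rbind, lapply(split(long, list(long$genotype, long$day), drop = TRUE),
    function(g) {
      data.frame(genotype = g$genotype[1], day = g$day[1],
                 mean = mean(g$value),
                 sem = if (nrow(g) > 1L) sd(g$value) / sqrt(nrow(g)) else NA_real_,
                 n = nrow(g))
    }))
  agg <- agg[order(agg$genotype, agg$day), ]
  rownames(agg) <- NULL
  class(agg) <- c("group_summary", "data.frame")
  agg
}

#' Weighted mean firing rate of one multiwell-MEA well
#'
#' WMFR = total spikes on active electrodes / (duration x number of active
#' electrodes). An electrode is active when it fires at least
#' \code{active_rate_min} spikes per minute over the recording; the well is
#' excluded unless it has strictly more than \code{min_active} active
#' electrodes.
#'
#' @param spike_counts integer vector of spike counts, one per electrode of
#'   the well.
#' @param duration recording duration (s).
#' @param active_rate_min electrode activity rule (spikes per minute).
#' @param min_active wells need strictly more than this many active
#'   electrodes.
#' @return list with \code{wmfr} (Hz, \code{NA} when excluded),
#'   \code{n_active}, and \code{excluded}.
#' @export
weighted_mean_firing_rate <- function(spike_counts, duration,
                                      active_rate_min = 5, min_active = 3) {
  stopifnot_scalar(duration, "duration", positive = TRUE)
  active <- spike_counts / (duration / 60) >= active_rate_min
  n_active <- sum(active)
  if (n_active <= min_active) {
    return(list(wmfr = NA_real_, n_active = n_active, excluded = TRUE))
  }
  list(wmfr = sum(spike_counts[active]) / (duration * n_active),
       n_active = n_active, excluded = FALSE)
}

#' Simulate a plate of low-density MEA wells
#'
#' Each well has \code{n_electrodes} electrodes; a fixed fraction
#' (\code{active_fraction} of the profile) fires homogeneous Poisson at the
#' profile's background rate and the rest are silent.
#'
#' @param profile a \code{\link{genotype_profile}} (use the day-24 well
#'   profiles from \code{\link{mea_profile}}).
#' @param n_wells number of wells.
#' @param n_electrodes electrodes per well.
#' @param duration recording duration (s).
#' @param seed RNG seed.
#' @return list of wells, each an integer vector of per-electrode spike
#'   counts.
#' @export
simulate_ld_wells <- function(profile, n_wells = 16, n_electrodes = 16,
                              duration = 300, seed = 1) {
  stopifnot(inherits(profile, "genotype_profile"))
  n_firing <- round(n_electrodes * profile$active_fraction)
  with_seed(seed, {
    lapply(seq_len(n_wells), function(w) {
      counts <- integer(n_electrodes)
      if (n_firing > 0) {
        counts[seq_len(n_firing)] <- rpois(n_firing, profile$background_rate * duration)
      }
      counts
    })
  })
}

#' Plate-level WMFR summary
#'
#' Applies the electrode-activity rule and the well filter to every well and
#' averages the WMFR over retained wells.
#'
#' @param wells list of per-electrode spike-count vectors
#'   (\code{\link{simulate_ld_wells}}).
#' @inheritParams weighted_mean_firing_rate
#' @return list with \code{mean_wmfr}, \code{n_retained}, \code{n_wells}.
#' @export
ld_wmfr_summary <- function(wells, duration, active_rate_min = 5, min_active = 3) {
  res <- lapply(wells, weighted_mean_firing_rate, duration = duration,
                active_rate_min = active_rate_min, min_active = min_active)
  vals <- vapply(res, `[[`, numeric(1), "wmfr")
  keep <- !vapply(res, `[[`, logical(1), "excluded")
  list(mean_wmfr = if (any(keep)) mean(vals[keep]) else NA_real_,
       n_retained = sum(keep), n_wells = length(wells))
}
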