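#' Bin spike times into counts
#'
#' @param times sorted spike times (s) in \code{[0, duration)}.
#' @param bin_width bin width (s).
#' @param duration recording duration (s).
#' @return integer vector of length \code{ceiling(duration / bin_width)};
#'   entry k counts spikes in \code{[(k-1) * bin, k * bin)}.
#' @export
bin_counts <- function(times, bin_width, duration) {
  stopifnot_scalar(bin_width, "bin_width", positive = TRUE)
  stopifnot_scalar(duration, "duration", positive = TRUE)
  nb <- ceiling(duration / bin_width)
  if (!length(times)) return(integer(nb))
  idx <- floor(times / bin_width) + 1L
  idx <- idx[idx >= 1L & idx <= nb]
  tabulate(idx, nbins = nb)
}

#' Zero-lag correlation of two binned count vectors
#'
#' Pearson correlation at lag zero. If either vector has zero variance the
#' correlation is defined as 0 (an empty train cannot be synchronized).
#'
#' @param v1,v2 equal-length count vectors.
#' @return correlation coefficient in \code{[-1, 1]}.
#' @export
zero_lag_correlation <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("count vectors differ in length", call. = FALSE)
  if (!length(v1)) return(0)
  if (sd(v1) == 0 || sd(v2) == 0) return(0)
  cor(v1, v2)
}

# Sparse representation of one binned train: unique bin indices + counts.
sparse_bins <- function(times, bin_width, nb) {
  idx <- floor(times / bin_width) + 1L
  idx <- idx[idx >= 1L & idx <= nb]
  if (!length(idx)) return(list(idx = integer(0), cnt = integer(0), s1 = 0, s2 = 0))
  r <- rle(sort(idx))
  list(idx = r$values, cnt = r$lengths,
       s1 = sum(r$lengths), s2 = sum(as.double(r$lengths)^2))
}

# Pearson r of two sparse binned trains over nb bins (zero-variance -> 0).
sparse_pearson <- function(a, b, nb, binarize = FALSE) {
  ca <- a$cnt; cb <- b$cnt; s1a <- a$s1; s2a <- a$s2; s1b <- b$s1; s2b <- b$s2
  if (binarize) {
    ca <- pmin(ca, 1L); cb <- pmin(cb, 1L)
    s1a <- sum(ca); s2a <- s1a; s1b <- sum(cb); s2b <- s1b
  }
  m <- match(a$idx, b$idx)
  hit <- !is.na(m)
  sxy <- sum(as.double(ca[hit]) * cb[m[hit]])
  va <- nb * s2a - s1a^2
  vb <- nb * s2b - s1b^2
  if (va <= 0 || vb <= 0) return(0)
  (nb * sxy - s1a * s1b) / sqrt(va * vb)
}

#' Subarray-local zero-lag synchrony summary
#'
#' Bins every active sensor's train (default 1 ms), computes the zero-lag
#' Pearson correlation for all pairs of active sensors within each subarray,
#' and classifies pairs with correlation strictly above \code{threshold} as
#' synchronized. A sensor is synchronized when it belongs to at least one
#' synchronized pair. The synchronized fraction divides by all valid sensors
#' in scope (set \code{denominator = "active"} for the active-only variant).
#' The pairwise computation is sparse: cost scales with spike counts, not
#' with pairs times bins.
#'
#' @param trains a \code{\link{spike_train_set}} with active flags set.
#' @param bin_width bin width (s).
#' @param threshold synchrony threshold on the correlation coefficient.
#' @param denominator \code{"valid"} or \code{"active"}.
#' @param binarize clip bin counts at 1 before correlating?
#' @return an object of class \code{synchrony_result}: pair table,
#'   synchronized sensor set, fraction, and counts.
#' @export
synchrony_summary <- function(trains, bin_width = 1e-3, threshold = 0.25,
                              denominator = c("valid", "active"),
                              binarize = FALSE) {
  stopifnot(inherits(trains, "spike_train_set"))
  denominator <- match.arg(denominator)
  nb <- ceiling(trains$duration / bin_width)
  active_idx <- which(trains$active)
  pairs <- list()
  sync_sensors <- integer(0)
  for (sa in unique(trains$subarray)) {
    members <- active_idx[trains$subarray[active_idx] == sa]
    k <- length(members)
    if (k < 2L) next
    sp <- lapply(members, function(i) sparse_bins(trains$times[[i]], bin_width, nb))
    for (p in seq_len(k - 1L)) {
      for (q in seq.int(p + 1L, k)) {
        r <- sparse_pearson(sp[[p]], sp[[q]], nb, binarize)
        if (r > threshold) {
          pairs[[length(pairs) + 1L]] <- c(members[p], members[q], sa, r)
          sync_sensors <- c(sync_sensors, members[p], members[q])
        }
      }
    }
  }
  pair_df <- if (length(pairs)) {
    m <- do.call(rbind, pairs)
    data.frame(sensor_i = trains$sensor_ids[m[, 1]],
               sensor_j = trains$sensor_ids[m[, 2]],
               subarray = as.integer(m[, 3]), r = m[, 4])
  } else {
    data.frame(sensor_i = integer(0), sensor_j = integer(0),
               subarray = integer(0), r = numeric(0))
  }
  sync_sensors <- sort(unique(sync_sensors))
  denom <- if (denominator == "valid") sum(trains$valid) else length(active_idx)
  structure(
    list(bin_width = bin_width, threshold = threshold,
         denominator = denominator,
         pairs = pair_df,
         synchronized_sensors = trains$sensor_ids[sync_sensors],
         n_valid = sum(trains$valid), n_active = length(active_idx),
         n_synchronized = length(sync_sensors),
         fraction = if (denom > 0) length(sync_sensors) / denom else 0),
    class = "synchrony_result")
}

#' @export
print.synchrony_result <- function(x, ...) {
  cat("<synchrony_result>",
      sprintf("bin %.3g ms, threshold %.3g (%s denominator)\n",
              1000 * x$bin_width, x$threshold, x$denominator))
  cat(sprintf("  %d synchronized pairs | %d/%d sensors synchronized | fraction %.4g\n",
              nrow(x$pairs), x$n_synchronized,
              if (x$denominator == "valid") x$n_valid else x$n_active,
              x$fraction))
  invisible(x)
}
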