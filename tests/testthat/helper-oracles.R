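# Brute-force oracles and small fixture builders used across test files.

# Dense Pearson synchrony over all pairs of active sensors within subarrays.
dense_synchrony_oracle <- function(trains, bin_width, threshold) {
  nb <- ceiling(trains$duration / bin_width)
  active <- which(trains$active)
  sync <- integer(0)
  pair_r <- list()
  for (sa in unique(trains$subarray)) {
    mem <- active[trains$subarray[active] == sa]
    if (length(mem) < 2) next
    vecs <- lapply(mem, function(i) bin_counts(trains$times[[i]], bin_width, trains$duration))
    for (p in seq_len(length(mem) - 1)) {
      for (q in seq.int(p + 1, length(mem))) {
        r <- if (sd(vecs[[p]]) == 0 || sd(vecs[[q]]) == 0) 0 else cor(vecs[[p]], vecs[[q]])
        pair_r[[length(pair_r) + 1]] <- c(mem[p], mem[q], r)
        if (r > threshold) sync <- c(sync, mem[p], mem[q])
      }
    }
  }
  list(pairs = if (length(pair_r)) do.call(rbind, pair_r) else matrix(numeric(0), ncol = 3),
       synchronized = sort(unique(sync)))
}

# Fixed-threshold burst grouper (the brute-force oracle for the CMA path).
fixed_threshold_bursts <- function(times, threshold, min_spikes = 3) {
  if (length(times) < min_spikes) {
    return(data.frame(first_spike = numeric(0), n_spikes = integer(0)))
  }
  grp <- cumsum(c(1, as.integer(diff(times) > threshold)))
  runs <- rle(grp)$lengths
  ends <- cumsum(runs)
  starts <- ends - runs + 1
  keep <- runs >= min_spikes
  data.frame(first_spike = times[starts[keep]], n_spikes = as.integer(runs[keep]))
}

# Bursty train with a guaranteed empty ISI gap: intra-burst ISIs are capped
# well below `gap_lo`, inter-burst gaps start above `gap_hi`.
gapped_bursty_train <- function(n_bursts, spikes_per_burst = 5,
                                intra_max = 0.02, gap_lo = 0.02, gap_hi = 1,
                                seed = 1) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    t0 <- 0
    tt <- c()
    for (b in seq_len(n_bursts)) {
      isis <- runif(spikes_per_burst - 1, 0.002, intra_max)
      tt <- c(tt, t0 + cumsum(c(0, isis)))
      t0 <- max(tt) + gap_hi + rexp(1, 1)
    }
    tt
  })
}

# Spike trains whose 1 ms binned vectors hit exactly the requested bins.
trains_from_bins <- function(bin_lists, duration, bin_width = 1e-3, ...) {
  times <- lapply(bin_lists, function(bins) (bins - 0.5) * bin_width)
  spike_train_set(times, duration, ...)
}
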