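test_that("the CMA threshold handles degenerate trains", {
  spec <- burst_detector_spec()
  expect_true(is.na(isi_threshold_cma(c(1, 2), spec)))
  expect_true(is.na(isi_threshold_cma(numeric(0), spec)))
  expect_error(isi_threshold_cma(c(2, 1, 3), spec), "sorted")
})

test_that("the CMA threshold lands inside a clear bimodal ISI gap", {
  tt <- gapped_bursty_train(60, spikes_per_burst = 5, intra_max = 0.015,
                            gap_hi = 2, seed = 4)
  thr <- isi_threshold_cma(tt, burst_detector_spec(), duration = max(tt))
  expect_gt(thr, 0.015)
  expect_lt(thr, 2)
})

test_that("CMA grouping equals the fixed-threshold oracle when a gap exists", {
  for (s in 1:5) {
    tt <- gapped_bursty_train(40, spikes_per_burst = 4 + s, intra_max = 0.02,
                              gap_hi = 1.5, seed = s)
    b_cma <- detect_bursts(tt, duration = max(tt))
    b_fix <- fixed_threshold_bursts(tt, 0.5)
    expect_equal(b_cma$first_spike, b_fix$first_spike)
    expect_equal(b_cma$n_spikes, b_fix$n_spikes)
  }
})

test_that("homogeneous Poisson trains produce almost no bursts", {
  set.seed(21)
  n_bursts <- 0
  n_spikes <- 0
  for (k in 1:50) {
    tt <- sort(runif(rpois(1, 0.2 * 600), 0, 600))
    n_spikes <- n_spikes + length(tt)
    n_bursts <- n_bursts + nrow(detect_bursts(tt, duration = 600))
  }
  expect_lte(n_bursts, 0.05 * n_spikes)
})

test_that("burst grouping matches the worked example", {
  tt <- c(0, 0.01, 0.02, 5, 5.01, 5.02, 5.03)
  b <- detect_bursts(tt, threshold = 0.1)
  expect_equal(b$n_spikes, c(3L, 4L))
  expect_equal(b$duration, c(0.02, 0.03))
  expect_equal(diff(b$first_spike), 5.0)       # first-spike-to-first-spike
  # runs of two spikes never form a burst
  b2 <- detect_bursts(c(0, 0.01, 10, 10.01, 10.02, 10.03), threshold = 0.1)
  expect_equal(nrow(b2), 1L)
  expect_equal(b2$n_spikes, 4L)
  expect_equal(nrow(detect_bursts(numeric(0), threshold = 0.1)), 0L)
})

test_that("burst properties: disjoint, sub-threshold ISIs, IBI exceeds duration", {
  for (s in 1:4) {
    tt <- gapped_bursty_train(30, spikes_per_burst = 6, seed = s)
    thr <- isi_threshold_cma(tt, duration = max(tt))
    b <- detect_bursts(tt, threshold = thr, duration = max(tt))
    expect_true(all(b$first_spike[-1] > b$last_spike[-nrow(b)]))
    for (k in seq_len(nrow(b))) {
      inside <- tt[tt >= b$first_spike[k] & tt <= b$last_spike[k]]
      expect_true(all(diff(inside) <= thr))
    }
    if (nrow(b) > 1) {
      expect_true(all(diff(b$first_spike) > b$duration[-nrow(b)]))
    }
  }
})

test_that("raising min_spikes never increases the burst count", {
  tt <- gapped_bursty_train(30, spikes_per_burst = 4, seed = 9)
  counts <- vapply(2:6, function(m) {
    nrow(detect_bursts(tt, burst_detector_spec(min_spikes = m), threshold = 0.5))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("burst summary implements the inclusion rule and pooled features", {
  mk_bursts <- function(n, sensor = 0) {
    data.frame(sensor = sensor, first_spike = seq_len(n) * 2,
               last_spike = seq_len(n) * 2 + 0.05,
               n_spikes = rep(4L, n), duration = rep(0.05, n))
  }
  s99 <- summarize_bursts(mk_bursts(99), n_valid_sensors = 100, duration = 300)
  expect_false(s99$included)
  s100 <- summarize_bursts(mk_bursts(100), n_valid_sensors = 100, duration = 300)
  expect_true(s100$included)
  # 4 valid sensors, 60 s, one sensor with 2 bursts -> 0.5 bursts/min/sensor
  b <- mk_bursts(2)
  s <- summarize_bursts(b, n_valid_sensors = 4, duration = 60)
  expect_equal(s$bursts_per_min_all_sensors, 0.5)
  expect_equal(s$mean_spikes_per_burst, 4)
  expect_equal(s$mean_inter_burst_interval, 2)
  expect_equal(s$mean_within_burst_isi, 0.05 / 3)
  # chip-level rate variant
  s_chip <- summarize_bursts(b, 4, 60, rate_scope = "chip")
  expect_equal(s_chip$bursts_per_min_all_sensors, 2)
  # no bursts anywhere
  s0 <- summarize_bursts(b[0, ], 4, 60)
  expect_false(s0$included)
  expect_true(is.na(s0$mean_spikes_per_burst))
})

test_that("sensor ranking breaks ties by ascending id and caps at top_k", {
  bursts <- do.call(rbind, Map(function(sensor, n) {
    data.frame(sensor = sensor, first_spike = seq_len(n),
               last_spike = seq_len(n) + 0.01, n_spikes = 3L, duration = 0.01)
  }, c(7, 2, 9, 4), c(5, 3, 3, 1)))
  trains <- spike_train_set(rep(list(c(1, 2)), 10), duration = 60)
  rr <- rank_and_raster(bursts, trains, "burst_rate", top_k = 200)
  expect_equal(rr$ranking$sensor, c(7, 2, 9, 4))
  expect_equal(rr$ranking$value, c(5, 3, 3, 1))
  expect_equal(nrow(rank_and_raster(bursts, trains, "burst_rate", top_k = 2)$ranking), 2)
  expect_error(rank_and_raster(bursts, trains, top_k = 0), "top_k")
  # spikes-per-burst key
  rr2 <- rank_and_raster(bursts, trains, "spikes_per_burst")
  expect_equal(rr2$ranking$value, rep(3, 4))
  expect_equal(rr2$ranking$sensor, c(2, 4, 7, 9))
})

test_that("raster export writes a spike list and an SVG", {
  bursts <- data.frame(sensor = 0L, first_spike = 1, last_spike = 1.02,
                       n_spikes = 3L, duration = 0.02)
  trains <- spike_train_set(list(c(1, 1.01, 1.02)), duration = 10)
  rr <- rank_and_raster(bursts, trains)
  dir <- tempfile()
  paths <- write_raster(rr, dir)
  expect_true(all(file.exists(paths)))
  lines <- readLines(paths[1])
  expect_match(lines[2], "^0\t0\t1\\.000000")
})

test_that("pooled spikes/burst of a simulation recovers the generator mean", {
  p <- mea_profile("deletion", 20)
  sim <- sample_spike_trains(p, sim_config(800, 120, seed = 31))
  bursts <- detect_bursts_all(sim$trains)
  expect_gt(nrow(bursts), 200)
  expect_equal(mean(bursts$n_spikes), 6.24, tolerance = 0.1)
})

test_that("deletion-profile top burst rates exceed control top rates", {
  wins <- 0
  for (s in 1:5) {
    top_rate <- function(genotype) {
      sim <- sample_spike_trains(mea_profile(genotype, 20),
                                 sim_config(400, 120, seed = s))
      b <- detect_bursts_all(sim$trains)
      if (nrow(b) == 0) return(0)
      rank_and_raster(b, sim$trains, "burst_rate", 1)$ranking$value[1]
    }
    wins <- wins + (top_rate("deletion") > top_rate("control"))
  }
  expect_gte(wins, 4)
})
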