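make_rec <- function(x, fs = 20000) raw_recording(matrix(x, nrow = 1), fs)

test_that("bandpass filter: degenerate inputs and band gains", {
  fs <- 20000
  n <- fs
  # all-zero stays zero
  z <- bandpass_filter(make_rec(numeric(n)))
  expect_identical(as.numeric(z$samples[1, ]), numeric(n))
  # DC is outside the passband
  dc <- bandpass_filter(make_rec(rep(5, n)))
  mid <- dc$samples[1, 2000:(n - 2000)]
  expect_lt(max(abs(mid)), 5e-6 * 5)
  # 1 kHz passes with gain in [0.9, 1]; 50 Hz attenuated > 20 dB
  tt <- (0:(n - 1)) / fs
  g1k <- bandpass_filter(make_rec(sin(2 * pi * 1000 * tt)))
  gain1k <- sd(g1k$samples[1, 2000:(n - 2000)]) / sd(sin(2 * pi * 1000 * tt[2000:(n - 2000)]))
  expect_gt(gain1k, 0.9)
  expect_lte(gain1k, 1.0)
  g50 <- bandpass_filter(make_rec(sin(2 * pi * 50 * tt)))
  gain50 <- sd(g50$samples[1, 2000:(n - 2000)]) / sd(sin(2 * pi * 50 * tt[2000:(n - 2000)]))
  expect_lt(20 * log10(gain50), -20)
})

test_that("zero-phase filtering introduces no lag on in-band signals", {
  fs <- 20000
  tt <- (0:(fs - 1)) / fs
  s <- sin(2 * pi * 1000 * tt)
  f <- bandpass_filter(make_rec(s))$samples[1, ]
  lags <- -5:5
  cc <- vapply(lags, function(L) {
    i <- 3000:(fs - 3000)
    cor(s[i], f[i + L])
  }, numeric(1))
  expect_equal(lags[which.max(cc)], 0)
  # in-band signals are near-idempotent under the filter
  f2 <- bandpass_filter(make_rec(f))$samples[1, ]
  expect_equal(f2[3000:(fs - 3000)], f[3000:(fs - 3000)], tolerance = 0.02)
})

test_that("filter specification is validated against Nyquist", {
  expect_error(bandpass_filter(make_rec(rnorm(100), fs = 10000)), "Nyquist")
  expect_error(filter_spec(300, 200), "below")
  expect_error(filter_spec(0, 100), "low_cut")
})

test_that("noise-scale estimation: MAD and SD conventions", {
  expect_error(estimate_noise_scale(numeric(0)), "empty")
  expect_equal(estimate_noise_scale(rep(3, 100), "mad"), 0)
  set.seed(4)
  x <- rnorm(2e5, sd = 2)
  expect_equal(estimate_noise_scale(x, "mad"), 0.6745 * 2, tolerance = 0.02)
  # the 5.5 x SD low-density threshold on sigma = 2 noise is 11 uV
  expect_equal(5.5 * estimate_noise_scale(x, "sd"), 11, tolerance = 0.02 * 11)
})

test_that("spike detection respects the strict -8 MAD threshold", {
  n <- 2000
  trough <- function(depth) {
    x <- numeric(n)
    x[990:1010] <- -depth * sin(pi * (0:20) / 20)
    x
  }
  spec <- detector_spec("mad", multiplier = 8)
  expect_length(detect_spikes(trough(7.9), 20000, spec, noise_scale = 1)$times, 0)
  expect_length(detect_spikes(trough(8.0), 20000, spec, noise_scale = 1)$times, 0)
  expect_length(detect_spikes(trough(8.1), 20000, spec, noise_scale = 1)$times, 1)
})

test_that("Gaussian noise alone yields no spikes at -8 MAD", {
  set.seed(9)
  x <- rnorm(2e5)
  det <- detect_spikes(x, 20000, detector_spec(), noise_scale = estimate_noise_scale(x))
  expect_length(det$times, 0)
})

test_that("injected biphasic events are recovered at the right times", {
  fs <- 20000
  p <- genotype_profile("inj", background_rate = 0, noise_sd = 2, spike_amp = 20)
  sim <- suppressWarnings(sample_spike_trains(p, sim_config(1, 2, seed = 6, mode = "raw-trace")))
  truth <- seq(0.2, 1.8, length.out = 5)
  sim$truth$true_spike_times[[1]] <- truth
  tr <- render_sensor_trace(sim, 1)
  xf <- bandpass_filter(make_rec(tr))$samples[1, ]
  det <- detect_spikes(xf, fs, detector_spec(), noise_scale = estimate_noise_scale(xf))
  expect_length(det$times, 5)
  expect_true(all(abs(det$times - truth) <= 2.5e-4))
})

test_that("dead time keeps only the deepest peak, and both monotonicities hold", {
  fs <- 20000
  x <- numeric(4000)
  x[1000 + 0:4] <- c(-9, -10, -9, -10.5, -9)   # two sub-ms troughs
  det <- detect_spikes(x, fs, detector_spec("mad", 8, dead_time = 1e-3), noise_scale = 1)
  expect_length(det$times, 1)
  expect_equal(det$amplitudes, -10.5)
  set.seed(2)
  y <- rnorm(2e4)
  y[sample(100:19900, 50)] <- -runif(50, 5, 12)
  counts_mult <- vapply(c(4, 6, 8, 10), function(m) {
    length(detect_spikes(y, fs, detector_spec("mad", m), noise_scale = 1)$times)
  }, numeric(1))
  expect_true(all(diff(counts_mult) <= 0))
  counts_dead <- vapply(c(0, 5e-4, 1e-3, 5e-3), function(d) {
    length(detect_spikes(y, fs, detector_spec("mad", 8, dead_time = d), noise_scale = 1)$times)
  }, numeric(1))
  expect_true(all(diff(counts_dead) <= 0))
})

test_that("low-density adaptive mode recomputes the SD threshold per bin", {
  fs <- 1000
  set.seed(3)
  # noise sd doubles in the second half; a -8 uV event is a spike only in
  # the quiet half
  x <- c(rnorm(5 * fs, sd = 1), rnorm(5 * fs, sd = 2))
  x[2.5 * fs] <- -8
  x[8.5 * fs] <- -8
  det <- detect_spikes(x, fs, ld_detector_spec())
  expect_true(any(abs(det$times - 2.5) < 0.01))
  expect_false(any(abs(det$times - 8.5) < 0.01))
})

test_that("saturated sensors are flagged invalid and recovered from simulations", {
  set.seed(8)
  clean <- rnorm(1e4, sd = 2)
  clipped <- clean
  clipped[1:500] <- 512                      # 5% at the positive rail
  rec <- raw_recording(rbind(clean, clipped), 20000)
  expect_identical(qc_sensors(rec), c(TRUE, FALSE))
  p <- mea_profile("deletion", 28)
  cfg <- sim_config(20, 5, seed = 4, mode = "raw-trace", saturated_fraction = 0.2)
  sim <- sample_spike_trains(p, cfg)
  expect_length(sim$truth$saturated_sensors, 4)
  flags <- vapply(1:20, function(i) {
    meanet:::saturation_fraction(render_sensor_trace(sim, i), cfg$adc_range,
                                 cfg$adc_bits) > 0.01
  }, logical(1))
  expect_identical(which(flags) - 1L, as.integer(sim$truth$saturated_sensors))
})

test_that("active classification uses a strict rate threshold and implies validity", {
  trains <- spike_train_set(
    list(seq_len(6) * 10 - 5,     # 6 spikes / 120 s = 0.05 Hz exactly
         seq_len(7) * 10 - 5,     # 0.0583 Hz
         numeric(0),
         seq_len(50)),            # active but invalid sensor
    duration = 120, valid = c(TRUE, TRUE, TRUE, FALSE))
  trains <- classify_active(trains, 0.05)
  expect_identical(trains$active, c(FALSE, TRUE, FALSE, FALSE))
  expect_true(all(which(trains$active) %in% which(trains$valid)))
  expect_error(classify_active(spike_train_set(list(1), 1e-9)), NA)
})

test_that("end-to-end detector meets sensitivity and false-positive bounds at 10 sigma", {
  p <- mea_profile("deletion", 28)   # 24 uV spikes on 2.4 uV noise
  det <- detect_network_activity(p, sim_config(12, 60, seed = 10, mode = "raw-trace"))
  truth <- det$truth$true_spike_times
  n_true <- sum(lengths(truth))
  n_matched <- 0
  n_false <- 0
  for (i in seq_along(truth)) {
    d <- det$trains$times[[i]]
    matched <- vapply(truth[[i]], function(t1) any(abs(d - t1) <= 2.5e-4), logical(1))
    n_matched <- n_matched + sum(matched)
    hit <- vapply(d, function(t1) any(abs(truth[[i]] - t1) <= 2.5e-4), logical(1))
    n_false <- n_false + sum(!hit)
  }
  expect_gte(n_matched / n_true, 0.95)
  expect_lt(n_false / (12 * 60), 0.05)
})
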