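test_that("zero-rate profiles generate empty trains", {
  p <- genotype_profile("null", background_rate = 0, active_fraction = 1)
  sim <- suppressWarnings(sample_spike_trains(p, sim_config(20, 10, seed = 1)))
  expect_true(all(lengths(sim$trains$times) == 0))
  expect_true(all(!sim$trains$active))
})

test_that("profile validation rejects bad parameters", {
  expect_error(genotype_profile("x", background_rate = -1), "background_rate")
  expect_error(genotype_profile("x", 1, active_fraction = 1.2), "active_fraction")
  expect_error(genotype_profile("x", 1, spikes_per_burst_mean = 2), ">= 3")
  expect_error(genotype_profile("x", 1, burster_fraction = 0.1,
                                ibi_mean = 0.02, spikes_per_burst_mean = 3,
                                intra_burst_isi_mean = 0.01), "ibi_mean")
  expect_warning(genotype_profile("x", 1, noise_sd = 10, spike_amp = 10),
                 "threshold")
  expect_warning(
    sample_spike_trains(genotype_profile("x", 0.01), sim_config(5, 10, seed = 1)),
    "expected events")
})

test_that("the simulator is deterministic in (profile, config, seed)", {
  p <- mea_profile("deletion", 28)
  a <- sample_spike_trains(p, sim_config(50, 30, seed = 7, n_subarrays = 5))
  b <- sample_spike_trains(p, sim_config(50, 30, seed = 7, n_subarrays = 5))
  d <- sample_spike_trains(p, sim_config(50, 30, seed = 8, n_subarrays = 5))
  expect_identical(a$trains$times, b$trains$times)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$trains$times, d$trains$times))
})

test_that("Poisson sensors recover the profile rate within the analytic CI", {
  p <- genotype_profile("poisson1", background_rate = 1)
  sim <- sample_spike_trains(p, sim_config(200, 600, seed = 11))
  expect_equal(mean(sim$trains$rates), 1.00, tolerance = 0.02)
  # per-sensor rate law: error < 3/sqrt(rate * duration) for most sensors
  err <- abs(sim$trains$rates - 1)
  expect_lt(mean(err > 3 / sqrt(600)), 0.01)
})

test_that("within-assembly zero-lag correlations match the analytic calibration", {
  p <- genotype_profile("asm", background_rate = 2, assembly_fraction = 1,
                        assembly_size = 8, copy_prob = 0.6, jitter_sd = 2e-4)
  sim <- sample_spike_trains(p, sim_config(8, 120, seed = 3))
  expect_equal(sum(!is.na(sim$truth$assembly_membership)), 8)
  vecs <- lapply(sim$trains$times, bin_counts, bin_width = 1e-3, duration = 120)
  rs <- c()
  for (i in 1:7) for (j in (i + 1):8) rs <- c(rs, cor(vecs[[i]], vecs[[j]]))
  expect_equal(mean(rs), assembly_zero_lag_r(0.6, 2e-4, 1e-3), tolerance = 0.05)
})

test_that("copy-probability calibration inverts the analytic correlation", {
  p <- calibrate_copy_prob(0.5, 2e-4, 1e-3)
  expect_equal(assembly_zero_lag_r(p, 2e-4, 1e-3), 0.5, tolerance = 1e-10)
  expect_equal(assembly_coincidence_prob(0, 1e-3), 1)
  expect_error(calibrate_copy_prob(0.99, 2e-3, 1e-3), "unreachable")
})

test_that("raw rendering: silent noiseless sensors give an identically zero trace", {
  p <- genotype_profile("silent", background_rate = 0, noise_sd = 0,
                        spike_amp = 24)
  sim <- suppressWarnings(sample_spike_trains(p, sim_config(2, 1, seed = 1, mode = "raw-trace")))
  expect_identical(render_sensor_trace(sim, 1), rep(0, 20000))
})

test_that("raw rendering conserves the ground-truth spike count", {
  p <- genotype_profile("clean", background_rate = 2, noise_sd = 0, spike_amp = 10)
  sim <- sample_spike_trains(p, sim_config(3, 20, seed = 5, mode = "raw-trace"))
  for (i in 1:3) {
    tr <- render_sensor_trace(sim, i)
    det <- detect_spikes(tr, 20000, detector_spec(), noise_scale = 10 / 9)
    expect_equal(length(det$times), length(sim$truth$true_spike_times[[i]]))
  }
})

test_that("rendered Gaussian noise has MAD 0.6745 sigma", {
  p <- genotype_profile("noise", background_rate = 0, noise_sd = 2)
  sim <- suppressWarnings(sample_spike_trains(p, sim_config(1, 60, seed = 2, mode = "raw-trace")))
  tr <- render_sensor_trace(sim, 1)
  expect_equal(estimate_noise_scale(tr, "mad"), 0.6745 * 2, tolerance = 0.02)
})

test_that("rendering rejects sampling rates below the template's bandwidth", {
  p <- genotype_profile("x", background_rate = 1)
  sim <- sample_spike_trains(p, sim_config(1, 5, seed = 1, sampling_rate = 2000,
                                           mode = "raw-trace"))
  expect_error(render_sensor_trace(sim, 1), "Nyquist")
})

test_that("overlapping spikes sum rather than drop", {
  # two spikes 0.3 ms apart on a noiseless trace: the summed trough is deeper
  p <- genotype_profile("overlap", background_rate = 0, noise_sd = 0, spike_amp = 10)
  sim <- suppressWarnings(sample_spike_trains(p, sim_config(1, 1, seed = 1, mode = "raw-trace")))
  sim$truth$true_spike_times[[1]] <- c(0.5, 0.5003)
  tr <- render_sensor_trace(sim, 1)
  expect_lt(min(tr), -10)
})

test_that("excitability cohort: degenerate cases and the averaged crossing", {
  # zero jitter: every curve identical, averaged crossing exactly at target
  cohort <- make_excitability_cohort(5, n_cells = 5, jitter = 0,
                                     current_grid = 0:20, seed = 1)
  expect_true(all(vapply(cohort, function(cv) {
    identical(cv$ap_counts, cohort[[1]]$ap_counts)
  }, logical(1))))
  expect_equal(rheobase_from_cohort(cohort)$rheobase, 5)
  # n = 1: averaged curve equals the single curve
  one <- make_excitability_cohort(5, n_cells = 1, jitter = 0, seed = 1)
  expect_equal(cohort_curve(one)$mean_counts, one[[1]]$ap_counts)
  # target outside the grid span errors
  expect_error(make_excitability_cohort(30, 5, current_grid = 0:20), "span")
})

test_that("excitability cohort recovers the target rheobase under jitter", {
  est <- vapply(1:10, function(s) {
    rheobase_from_cohort(make_excitability_cohort(5, 23, jitter = 1, seed = s))$rheobase
  }, numeric(1))
  # each cohort estimate within 2 x (sample SEM of per-cell crossings)
  expect_true(all(abs(est - 5) < 2 * 1 / sqrt(23) + 0.1))
  expect_lt(abs(mean(est) - 5), 0.15)
})
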