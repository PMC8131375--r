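#' Genotype activity profile for the spike-train simulator
#'
#' A \code{genotype_profile} bundles the generative parameters of one culture
#' condition: per-sensor background firing, a minority of bursting sensors,
#' correlated assemblies that produce zero-lag synchrony, and the waveform /
#' noise parameters used when rendering raw voltage traces.
#'
#' The burst process on a bursting sensor is a renewal process with
#' exponential first-spike-to-first-spike intervals (mean \code{ibi_mean});
#' each burst carries \code{3 + Poisson(spikes_per_burst_mean - 3)} spikes
#' with exponential intra-burst inter-spike intervals. Assembly members copy
#' events of a shared mother train with probability \code{copy_prob} and
#' Gaussian timing jitter \code{jitter_sd}, plus independent Poisson makeup
#' spikes so the expected rate stays at \code{background_rate}.
#'
#' @param label character tag for the condition.
#' @param background_rate events/s of the homogeneous Poisson background per
#'   active sensor.
#' @param active_fraction proportion of sensors with nonzero background.
#' @param burster_fraction proportion of sensors carrying the burst process.
#' @param ibi_mean mean inter-burst interval (s), measured first spike to
#'   first spike of consecutive bursts.
#' @param spikes_per_burst_mean mean spikes per burst (>= 3).
#' @param intra_burst_isi_mean mean intra-burst inter-spike interval (s).
#' @param assembly_fraction proportion of sensors assigned to synchronized
#'   assemblies.
#' @param assembly_size sensors per assembly.
#' @param copy_prob probability that a mother event is copied onto a member
#'   sensor; the default is calibrated so the expected within-assembly
#'   zero-lag correlation on 1 ms bins is 0.5 (see
#'   \code{\link{calibrate_copy_prob}}).
#' @param jitter_sd Gaussian jitter (s) applied to copied events.
#' @param noise_sd Gaussian sensor noise (uV) used in raw-trace mode.
#' @param spike_amp negative peak magnitude (uV) of the biphasic spike
#'   template in raw-trace mode.
#' @return an object of class \code{genotype_profile}.
#' @seealso \code{\link{mea_profile}} for the packaged condition profiles.
#' @export
genotype_profile <- function(label,
                             background_rate,
                             active_fraction = 1,
                             burster_fraction = 0,
                             ibi_mean = 10,
                             spikes_per_burst_mean = 3,
                             intra_burst_isi_mean = 0.01,
                             assembly_fraction = 0,
                             assembly_size = 8,
                             copy_prob = calibrate_copy_prob(),
                             jitter_sd = 2e-4,
                             noise_sd = 2.4,
                             spike_amp = 24) {
  stopifnot_scalar(background_rate, "background_rate")
  if (background_rate < 0) stop("'background_rate' must be >= 0", call. = FALSE)
  check_proportion(active_fraction, "active_fraction")
  check_proportion(burster_fraction, "burster_fraction")
  check_proportion(assembly_fraction, "assembly_fraction")
  check_proportion(copy_prob, "copy_prob")
  stopifnot_scalar(ibi_mean, "ibi_mean", positive = TRUE)
  stopifnot_scalar(spikes_per_burst_mean, "spikes_per_burst_mean")
  if (spikes_per_burst_mean < 3) {
    stop("'spikes_per_burst_mean' must be >= 3", call. = FALSE)
  }
  stopifnot_scalar(intra_burst_isi_mean, "intra_burst_isi_mean", positive = TRUE)
  if (ibi_mean <= intra_burst_isi_mean * spikes_per_burst_mean) {
    stop("'ibi_mean' must exceed intra_burst_isi_mean * spikes_per_burst_mean",
         call. = FALSE)
  }
  stopifnot_scalar(assembly_size, "assembly_size", positive = TRUE)
  stopifnot_scalar(jitter_sd, "jitter_sd")
  if (jitter_sd < 0) stop("'jitter_sd' must be >= 0", call. = FALSE)
  stopifnot_scalar(noise_sd, "noise_sd")
  stopifnot_scalar(spike_amp, "spike_amp")
  if (noise_sd > 0 && spike_amp / (0.6745 * noise_sd) <= 8) {
    warning("spike_amp / (0.6745 * noise_sd) <= 8: spikes will sit at or ",
            "below the -8 MAD detection threshold", call. = FALSE)
  }
  structure(
    list(label = as.character(label),
         background_rate = background_rate,
         active_fraction = active_fraction,
         burster_fraction = burster_fraction,
         ibi_mean = ibi_mean,
         spikes_per_burst_mean = spikes_per_burst_mean,
         intra_burst_isi_mean = intra_burst_isi_mean,
         assembly_fraction = assembly_fraction,
         assembly_size = as.integer(assembly_size),
         copy_prob = copy_prob,
         jitter_sd = jitter_sd,
         noise_sd = noise_sd,
         spike_amp = spike_amp),
    class = "genotype_profile")
}

#' @export
print.genotype_profile <- function(x, ...) {
  cat("<genotype_profile>", x$label, "\n")
  cat(sprintf("  background: %.3g Hz on %.0f%% of sensors\n",
              x$background_rate, 100 * x$active_fraction))
  if (x$burster_fraction > 0) {
    cat(sprintf("  bursting:   %.3g%% of sensors, IBI %.3g s, %.3g spikes/burst, intra-ISI %.3g s\n",
                100 * x$burster_fraction, x$ibi_mean,
                x$spikes_per_burst_mean, x$intra_burst_isi_mean))
  }
  if (x$assembly_fraction > 0) {
    cat(sprintf("  assemblies: %.3g%% of sensors in groups of %d, copy_prob %.3f, jitter %.3g s\n",
                100 * x$assembly_fraction, x$assembly_size, x$copy_prob, x$jitter_sd))
  }
  cat(sprintf("  waveform:   %.3g uV peak on %.3g uV noise\n", x$spike_amp, x$noise_sd))
  invisible(x)
}

#' Solve the bursting-sensor fraction from chip-level burst targets
#'
#' A bursting sensor emits \code{60 / ibi_mean} bursts per minute in
#' expectation, so for the chip-level mean over all sensors to equal
#' \code{bursts_per_min} the fraction of bursting sensors must be
#' \code{bursts_per_min / (60 / ibi_mean)}.
#'
#' @param bursts_per_min target mean bursts per minute per sensor, averaged
#'   over all sensors of the array.
#' @param ibi_mean mean inter-burst interval (s) on a bursting sensor.
#' @return the required bursting-sensor proportion.
#' @export
solve_burster_fraction <- function(bursts_per_min, ibi_mean) {
  stopifnot_scalar(bursts_per_min, "bursts_per_min")
  stopifnot_scalar(ibi_mean, "ibi_mean", positive = TRUE)
  f <- bursts_per_min / (60 / ibi_mean)
  if (f > 1) stop("targets imply a bursting fraction > 1", call. = FALSE)
  f
}

#' Analytic same-bin coincidence probability for jittered event copies
#'
#' Two copies of a common mother event, each displaced by independent
#' Gaussian jitter with standard deviation \code{jitter_sd}, are counted as a
#' zero-lag coincidence when they fall into the same time bin of width
#' \code{bin_width}. With the mother event uniformly positioned within a bin,
#' the probability of a same-bin coincidence is
#' \deqn{c = \frac{1}{b}\int_0^b \sum_k \left[\Phi\!\left(\frac{(k+1)b-u}{s}\right)
#'       - \Phi\!\left(\frac{kb-u}{s}\right)\right]^2 du,}
#' evaluated here by numerical quadrature.
#'
#' @param jitter_sd Gaussian jitter (s) of each copy.
#' @param bin_width bin width (s) used for the synchrony analysis.
#' @return coincidence probability in (0, 1].
#' @export
assembly_coincidence_prob <- function(jitter_sd = 2e-4, bin_width = 1e-3) {
  stopifnot_scalar(bin_width, "bin_width", positive = TRUE)
  if (jitter_sd <= 0) return(1)
  ks <- -4:4
  f <- function(u) {
    vapply(u, function(ui) {
      p <- stats::pnorm(((ks + 1) * bin_width - ui) / jitter_sd) -
           stats::pnorm((ks * bin_width - ui) / jitter_sd)
      sum(p^2)
    }, numeric(1))
  }
  stats::integrate(f, 0, bin_width)$value / bin_width
}

#' Expected within-assembly zero-lag correlation
#'
#' For sparse binned spike counts, the Pearson correlation between two
#' assembly members whose trains are \code{copy_prob}-thinned jittered copies
#' of a common mother train (topped up with independent Poisson spikes to the
#' common rate) is approximately
#' \code{copy_prob^2 * assembly_coincidence_prob(jitter_sd, bin_width)},
#' independent of the firing rate.
#'
#' @inheritParams assembly_coincidence_prob
#' @param copy_prob probability that a mother event is copied onto a member.
#' @return expected zero-lag Pearson correlation.
#' @export
assembly_zero_lag_r <- function(copy_prob, jitter_sd = 2e-4, bin_width = 1e-3) {
  check_proportion(copy_prob, "copy_prob")
  copy_prob^2 * assembly_coincidence_prob(jitter_sd, bin_width)
}

#' Calibrate the copy probability for a target assembly correlation
#'
#' Inverts \code{\link{assembly_zero_lag_r}}: returns the copy probability
#' for which the expected within-assembly zero-lag correlation equals
#' \code{target_r}.
#'
#' @param target_r desired within-assembly zero-lag Pearson correlation.
#' @inheritParams assembly_coincidence_prob
#' @return copy probability in (0, 1].
#' @export
calibrate_copy_prob <- function(target_r = 0.5, jitter_sd = 2e-4, bin_width = 1e-3) {
  check_proportion(target_r, "target_r")
  cc <- assembly_coincidence_prob(jitter_sd, bin_width)
  p <- sqrt(target_r / cc)
  if (p > 1) {
    stop(sprintf("target correlation %.3g unreachable with jitter %.3g s (max %.3g)",
                 target_r, jitter_sd, cc), call. = FALSE)
  }
  p
}

#' Packaged genotype activity profiles
#'
#' Ready-made \code{\link{genotype_profile}}s for the three culture
#' conditions (isogenic control, 16p11.2 deletion, 16p11.2 duplication) at
#' the three assay time points used throughout the package. The profile
#' parameters are calibrated so that the analysis pipeline's expected outputs
#' equal the reported group means for each condition:
#'
#' \describe{
#'   \item{day 28 (high-density network assay)}{background firing 0.26 /
#'     0.93 / 0.24 Hz (control / deletion / duplication) on all sensors;
#'     assemblies of 8 covering 4\% / 27\% / 1\% of sensors with copy
#'     probability calibrated for a within-assembly zero-lag correlation of
#'     0.5 on 1 ms bins.}
#'   \item{day 20 (high-density burst assay)}{a bursting minority solved from
#'     the chip-level burst-rate and inter-burst-interval targets
#'     (\code{\link{solve_burster_fraction}}): 0.017 / 0.386 / 0.023
#'     bursts/min per sensor, inter-burst intervals 7.0 / 4.2 / 6.2 s and
#'     4.29 / 6.24 / 5.34 spikes per burst; background firing is set to zero
#'     so the burst statistics are identified by the bursting minority.}
#'   \item{day 24 (low-density multiwell assay)}{per-electrode Poisson firing
#'     at the weighted-mean-firing-rate targets 0.56 / 1.14 / 0.49 Hz on 75\%
#'     of electrodes per well.}
#' }
#'
#' Raw-trace parameters are shared: 2.4 uV Gaussian sensor noise and a 24 uV
#' (10 sigma) biphasic spike template.
#'
#' @param genotype one of \code{"control"}, \code{"deletion"},
#'   \code{"duplication"}.
#' @param day assay day: 20, 24 or 28.
#' @return a \code{\link{genotype_profile}}.
#' @export
mea_profile <- function(genotype = c("control", "deletion", "duplication"),
                        day = c(28, 20, 24)) {
  genotype <- match.arg(genotype)
  day <- match.arg(as.character(day[1]), c("28", "20", "24"))
  tag <- paste0(genotype, "-d", day)
  if (day == "28") {
    rate <- switch(genotype, control = 0.26, deletion = 0.93, duplication = 0.24)
    sync <- switch(genotype, control = 0.04, deletion = 0.27, duplication = 0.01)
    genotype_profile(tag, background_rate = rate, active_fraction = 1,
                     assembly_fraction = sync, assembly_size = 8)
  } else if (day == "20") {
    bpm <- switch(genotype, control = 0.017, deletion = 0.386, duplication = 0.023)
    ibi <- switch(genotype, control = 7.0, deletion = 4.2, duplication = 6.2)
    spb <- switch(genotype, control = 4.29, deletion = 6.24, duplication = 5.34)
    genotype_profile(tag, background_rate = 0, active_fraction = 0,
                     burster_fraction = solve_burster_fraction(bpm, ibi),
                     ibi_mean = ibi, spikes_per_burst_mean = spb,
                     intra_burst_isi_mean = 0.01)
  } else {
    rate <- switch(genotype, control = 0.56, deletion = 1.14, duplication = 0.49)
    genotype_profile(tag, background_rate = rate, active_fraction = 0.75)
  }
}
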