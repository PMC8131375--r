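---
title: "Methods: network activity analysis for MEA recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network activity analysis for MEA recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meanet)
```

## Scope and model

`meanet` implements the analysis chain used to phenotype cultured neuronal
networks on microelectrode arrays (MEAs), together with a synthetic-data
generator that makes every stage testable against known ground truth. The
motivating system is iPSC-derived dopaminergic neuron cultures carrying
16p11.2 copy-number variants (deletion, duplication, isogenic control),
recorded longitudinally on a 26,400-sensor high-density array (1,024
channels read out per configuration, 20 kHz, 10-bit) and on 48-well
low-density plates with 16 electrodes per well. The pipeline stages are:

1. **Spike detection.** Traces are bandpass filtered with a third-order
   Butterworth (300–7000 Hz for the high-density system; 200–2500 Hz for
   the low-density system) applied forward–backward, so the filter is
   zero-phase and spike times are not shifted. The per-sensor noise scale
   is the *unscaled* median absolute deviation,
   `median(|x - median(x)|)`; no Gaussian consistency factor is applied, so
   for Gaussian noise the MAD converges to 0.6745&sigma; and the detection
   rule — every negative local minimum strictly below −8&times;MAD — sits at
   about −5.4&sigma;. Within a 1 ms dead time only the deepest peak is
   kept. A sensor is *active* when its detected rate is strictly above
   0.05 Hz; sensors with more than 1% of samples within 1 LSB of an ADC
   rail are discarded as saturated. The low-density preset instead uses an
   adaptive threshold of 5.5&times;SD recomputed in 1 s bins.
2. **Synchrony.** Spike trains of active sensors are binned at 1 ms and the
   Pearson correlation of the count vectors is computed at zero lag for all
   pairs *within a subarray* (the 1,024-sensor block recorded in one
   configuration); correlation never crosses subarray boundaries. Pairs
   strictly above 0.25 are synchronized; a sensor is synchronized if it
   belongs to at least one synchronized pair; the synchronized fraction
   divides by all valid sensors in scope (an active-only denominator is
   available as an option). Zero-variance vectors get correlation 0: an
   empty train cannot be synchronized. The pair computation is sparse — it
   touches only occupied bins — so cost scales with spike counts rather
   than pairs&times;bins.
3. **Bursts.** Per sensor, an inter-spike-interval (ISI) threshold is read
   off the cumulative moving average (CMA) of the ISI histogram (the
   published CMA method; see *Numerical choices*), and maximal runs of at
   least 3 spikes whose ISIs all lie at or below the threshold become
   bursts. Chip-level features (spikes/burst, burst duration, within-burst
   ISI, inter-burst interval between first spikes of consecutive bursts)
   are computed over the pooled burst distribution of all sensors; the
   burst rate is the mean over all valid sensors of per-sensor bursts per
   minute; recordings with fewer than 100 bursts in total are excluded.
   Sensors can be ranked by burst rate or spikes/burst (ties broken by
   ascending sensor id) and the top 200 exported as a raster.
4. **Longitudinal aggregation.** Per-chip metric series are linearly
   interpolated onto a common day grid within each chip's observed span
   (no extrapolation), then averaged per genotype with mean ± SEM.
5. **Multiwell metrics.** The weighted mean firing rate of a well is the
   total spike count on active electrodes divided by duration times the
   number of active electrodes; wells need strictly more than 3 active
   electrodes. The electrode activity rule (≥ 5 spikes/min) is a vendor-style
   convention, configurable.
6. **Excitability.** Per-cell current-clamp input–output curves (500 ms
   steps, −60 mV holding) are resampled to the union current grid, averaged
   pointwise, and the rheobase is the current at which the averaged curve
   first crosses 1 AP, linearly interpolated between bracketing steps. A
   curve that never reaches 1 AP yields a no-rheobase result, distinct
   from 0 pA.

## The synthetic-data generator

No raw electrophysiology is distributed with the package, so the generator
*is* the study condition: its packaged profiles (`mea_profile()`) are
calibrated so that the pipeline's expected outputs equal the reported group
means of the three genotypes.

* **Background firing** is homogeneous Poisson per sensor. Day-28 profiles
  use 0.26 / 0.93 / 0.24 Hz (control / deletion / duplication) on all
  sensors; day-24 well profiles use 0.56 / 1.14 / 0.49 Hz on 12 of 16
  electrodes (the remainder silent).
* **Bursting sensors** superpose a renewal process: burst onsets with
  exponential first-spike-to-first-spike intervals (mean `ibi_mean`),
  `3 + Poisson(mean − 3)` spikes per burst, exponential intra-burst ISIs
  (10 ms mean). The bursting fraction is solved so that the chip-mean burst
  rate matches the reported value: a burster emits `60/ibi_mean` bursts per
  minute, so `burster_fraction = bursts_per_min / (60/ibi_mean)`
  (`solve_burster_fraction()`). Day-20 profiles encode 0.017 / 0.386 /
  0.023 bursts/min with inter-burst intervals 7.0 / 4.2 / 6.2 s and
  4.29 / 6.24 / 5.34 spikes/burst.
* **Assemblies** produce zero-lag synchrony: members of an assembly (8
  sensors, confined to one subarray) copy events of a shared mother train
  with probability `copy_prob`, jittered by 0.2 ms Gaussian noise, plus
  independent Poisson makeup spikes so the expected rate is unchanged. For
  sparse binned counts the expected within-assembly correlation is
  `copy_prob² × c`, where `c` is the analytic same-bin coincidence
  probability under jitter (`assembly_coincidence_prob()`); the packaged
  profiles invert this for a target correlation of 0.5, comfortably above
  the 0.25 synchrony threshold yet realistic for co-active clusters. The
  assembly fraction equals the reported synchronized fractions (0.04 /
  0.27 / 0.01 at day 28). The 0.2 ms jitter default is deliberately much
  smaller than the 1 ms bin so zero-lag correlation survives binning.
* **Raw traces** are Gaussian noise (2.4 µV, the quoted r.m.s. noise of the
  high-density system) plus a biphasic, negative-leading template of 1 ms
  total width and 24 µV negative peak (10&sigma;) centred at each true
  spike time; overlapping templates sum. The exact template shape is
  irrelevant to threshold detection — what matters is that its energy lies
  inside the detection band. Saturated sensors are rendered as rail-clipped
  segments. Rendering streams one sensor at a time, with deterministic
  per-sensor RNG substreams, so a full 256-sensor, 120 s, 20 kHz array
  never needs to reside in memory and results do not depend on chunking.
* **Excitability cohorts** share a piecewise-linear AP-count template,
  `max(0, slope × (I − onset))` with the 1-AP crossing at the target
  rheobase, shifted per cell by zero-mean Gaussian current jitter. The
  onset sits `1/slope = 3` pA below the crossing so that, with 1 pA jitter,
  the averaging region around the crossing stays linear and the
  cohort-averaged crossing is unbiased.

**What the generator does not emulate.** Waveform diversity and spike
sorting, electrode drift, non-Poisson background (refractoriness,
oscillations), distance-dependent correlation structure, network-wide
bursts spanning sensors, astrocyte co-culture effects, and any biophysics.
Passing recovery tests therefore demonstrates that the *pipeline* is
correct and calibrated under the stated generative assumptions, not that
the assumptions exhaust real recordings. Distribution families (Poisson
backgrounds, exponential intervals, Gaussian jitter) are generator
conventions chosen for tractability, not claims about the biology.

## Numerical choices

* **"Butterfly" filter.** Read as Butterworth, order 3, zero-phase
  (forward–backward); the low-density "2500 kHz" low-pass is read as
  2.5 kHz, since the 15 kHz sampling rate forbids a MHz edge. The filter
  kernel is compiled (direct-form II transposed, specialised for the
  7-tap bandpass) with edge-reflection padding; its band gains and
  zero-lag behaviour are unit-tested against analytic expectations.
* **CMA internals.** The cited burst-detection method leaves several
  internals to the implementation; ours uses a log-spaced ISI histogram of
  100 bins spanning 1 ms to the recording duration. Two small-sample
  guards keep the adaptive threshold meaningful on sparse trains:
  sub-millisecond ISIs are excluded from the histogram (they are
  unconditionally intra-burst, and clamping them into the first bin
  fabricates an early CMA maximum), and the CMA maximum is taken only over
  bins holding at least `max(2, 5%)` of the ISI count (a single stray ISI
  in an early narrow bin otherwise dominates the running mean and shreds
  bursts). The skewness→alpha lookup of the original method
  (`{<1, <4, <9, ≥9} → {1.0, 0.7, 0.5, 0.3}`) is implemented, but the
  package default is a *fixed* `alpha1 = 0.7`: with exponential inter-burst
  intervals the lookup selects 0.5 on strongly bursty trains, pushing the
  threshold into the inter-burst mode (~1 s) and merging a material share
  of consecutive bursts, which violates the package's own recovery
  requirement that pooled spikes/burst converge to the generator mean
  within 10%. At `alpha1 = 0.7` the threshold lands near the geometric
  middle of the intra/inter ISI gap (~0.15 s on the packaged regimes) and
  all three genotype regimes are recovered within 10%. On homogeneous
  Poisson trains the CMA yields either a sub-ISI threshold or none, so the
  null burst rate is essentially zero, as required.
* **Strict inequalities.** All headline thresholds are strict exactly where
  specified: spikes are *below* −8×MAD, active sensors are *above*
  0.05 Hz, synchronized pairs are *above* 0.25, wells need *more than* 3
  active electrodes; the 100-burst inclusion and the 3-spike burst minimum
  are inclusive. Each edge is pinned by a dedicated test.
* **Degenerate inputs.** Empty trains, zero-variance count vectors,
  no-threshold CMA outcomes, cohorts that never reach 1 AP, and burst-free
  chips all return defined results (empty tables, correlation 0,
  no-rheobase, excluded summaries) rather than errors; genuinely invalid
  configurations (Nyquist violations, negative rates, truncated payloads)
  fail fast with messages naming the offending quantity.
* **Ties and ordering.** Sensor ranking breaks ties by ascending sensor id;
  flat troughs take the first sample; sensor ids are 0-based in all
  on-disk formats, times are seconds from recording start at 6 decimals.

## Problem sizes and reproducibility

The recovery checks run the deletion and control day-28 raw-trace
simulations at 256 sensors × 120 s × 20 kHz (three seeds each), the
synchrony simulations at 1,000 sensors across 25 subarrays, the day-20
burst simulations at 5,000 sensors (6,000 for control, whose sparser
bursting needs the larger array to clear the 100-burst inclusion rule),
rheobase cohorts of 23 cells over ten seeds, and plates of 16 wells —
sizes at which the group means are identified while a full run of
`scripts/acceptance.R` stays in the minutes range on a single core. One
master seed drives everything; per-sensor and per-assembly substreams make
simulator output bit-identical under any chunking or evaluation order.

## Known limitations

* With exponential inter-burst intervals, gaps shorter than the adaptive
  ISI threshold genuinely merge consecutive bursts (~5% of bursts on the
  packaged regimes); detected burst rates are correspondingly a few
  percent below, and spikes/burst above, the generative values. This is a
  property of threshold-based burst detection on renewal input, not a bug.
* The synchrony measure is zero-lag only; lagged correlation, spike-train
  distances, and synchrony-graph community structure are out of scope.
* Network-burst detection (cross-sensor merging) is not implemented.
* The whole-chip scan geometry is configurable but defaults to 25
  subarrays; the pipeline does not model the vendor's activity-based
  channel routing.
* Inferential statistics are out of scope by design: summaries are
  descriptive (mean ± SEM) and export cleanly to any statistics package.
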