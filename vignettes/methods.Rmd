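---
title: "Methods: synthetic cochlear Ca2+ recordings and the ohcsync analysis chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic cochlear Ca2+ recordings and the ohcsync analysis chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohcsync)
```

`ohcsync` analyses spontaneous Ca2+ activity of cochlear outer hair cells
(OHCs) and its synchronization by intercellular Ca2+ waves spreading
through the greater epithelial ridge (GER). Because raw imaging data for
this preparation are not publicly deposited, the package pairs every
analysis stage with a seeded synthetic-recording generator that carries
full ground truth, so each stage is validated by parameter recovery rather
than by comparison to a fixed data file. This vignette documents the
generative model, each analysis step, and the deliberate design decisions
a reader should know before trusting (or modifying) the defaults.

## 1. The generative model (`simulation_config`, `simulate_recording`)

A recording is a field of `n_cells` OHCs laid out in up to three rows near
the GER, imaged at `frame_rate_hz` (default 30.3 fps) for `n_frames`
(default 4,000 frames, about 132 s). Per cell:

* **Spiking.** A homogeneous Poisson baseline (`baseline_rate_hz`,
  default 0.2 Hz) optionally modulated by a two-state burst process
  (exponential inter-burst interval, mean 20 s; burst length mean 1 s;
  in-burst rate 5 Hz).
* **Waves.** Intercellular waves are either drawn from a Poisson process
  (`wave_rate_per_min`, default 2.09 per min, extents uniform on
  20–180 µm) or supplied explicitly as a `wave_schedule` data frame. A
  wave multiplies the firing rate of nearby cells by
  `1 + coupling_gain * g(extent) * exp(-d / coupling_length_um)` while it
  is active, with `g(extent) = min(extent / field, 1)`; `coupling_enabled
  = FALSE` (the `"uncoupled"` preset) removes the modulation while leaving
  every random stream untouched, giving a matched ablation.
* **Fluorescence.** Spikes are convolved with a mono-exponential indicator
  kernel (`kernel_tau_s = 0.3` s), multiplied by a photobleaching decay
  (`bleach_tau_s = 200` s), offset by `f0`, and corrupted with Gaussian
  noise (`noise_sd = 0.05` dF/F0 units). Every stochastic component uses
  its own derived seed (`derive_seed(seed, stream)`), so ablations change
  nothing but the component under study.

`render_movie()` rasterizes traces into a synthetic movie: square cell
ROIs, a diffuse GER band, and elliptical wave footprints that *grow
radially during the rise phase* and reach full extent at the temporal
profile peak. The growth matters: an instantly painted wide wave would
first appear already touching the field border and be discarded as having
entered from outside the field (Section 4).

The generator's `coupling_gain` and `baseline_rate_hz` defaults were
calibrated once against the target regime the generator is meant to emulate (slope of
synchronization versus extension near 2.6e-3 per µm, wave-window rsavg up
to ~0.5, individual significance for most waves longer than 75 µm) and
frozen before any acceptance test was written.

```{r quick-sim}
cfg <- simulation_config(n_cells = 12, n_frames = 600, seed = 1L)
rec <- simulate_recording(cfg)
rec$traces
head(rec$ground_truth$wave_events_true)
```

## 2. Trace extraction (`extract_roi_traces`, `compute_dff`)

Movies are registered by integer-pixel translation (FFT cross-correlation
against the first frame); recordings whose maximum shift exceeds
`max_drift_px = 8` are flagged for discard. Cell traces are means over
square ROIs of side 3.7 µm — 15 px at the reference pixel size of
125/512 µm, using round-half-up. dF/F0 uses F0 = mean of the first 10
frames; non-positive F0 is an error naming the offending cells, and double
conversion is refused.

## 3. The six-step activity classifier

`condition_trace()` applies, in order: (i) a centred moving average of
length 3 (shrunken windows at the edges); (ii) subtraction of an order-5
polynomial in the frame index (slow drifts, photobleaching); (iii)
max-normalization. The noise floor is the high-band Welch estimate —
average one-sided PSD above 66% of Nyquist, converted back to an SD.

**Design decision — noise floor from the unsmoothed trace.** The length-3
moving average has a transfer-function null near two-thirds of Nyquist: it
empties exactly the band the noise estimator reads. The floor is therefore
estimated on the detrended but unsmoothed trace; the smoothed trace still
feeds spike inference. Traces shorter than 256 frames fall back to
`sd(diff(x))/sqrt(2)`.

`infer_spikes()` deconvolves with a nonnegative AR(1) innovation model
(`gamma = exp(-1/(tau * fs))`, tau = 0.3 s). Sparsity is enforced on the
**3-frame aggregated innovation**: the upstream moving average spreads each
spike's innovation over three adjacent frames, so no per-frame threshold
can both reject noise and keep a 5-sigma spike. The aggregate recaptures
the full per-spike mass; its noise SD has a closed form in `gamma`
(`agg_noise_factor`), and the default `lambda = 4.5` aggregate-SDs leaves
about 0.01 expected spurious events per 4,000-frame recording. A
unit-amplitude transient carries total innovation mass S = 1, so S counts
spikes in units of one unit transient.

A cell is **active** when S exceeds a threshold calibrated per recording
geometry as the 99th percentile of S over pure-noise simulations
(`calibrate_s_threshold`; scale-invariant after max-normalization, so run
at unit SD). The 4-SD consistency rule flags discordant calls — active
with maximum signal under 4 noise SDs, or inactive above — for review;
flagged cells are never silently relabelled.

**Event counting and dead time.** `n_events` counts local maxima of the
aggregated innovation above threshold, which is amplitude-independent but
merges spikes closer than about 1.5 frames. `spike_frequency()` therefore
inverts the Poisson thinning relation r = lambda * exp(-lambda * delta)
with delta = 1.5/fs (set `correct_dead_time = FALSE` for the raw rate).

```{r classify}
dff <- compute_dff(rec$traces)
head(classify_cells(dff, S_threshold = 1))
```

## 4. Wave detection (`detect_waves`)

Frames restricted to the GER band are Gaussian-smoothed (sigma = 1 px);
pixels exceeding their baseline by `k_sigma = 5` baseline SDs are grouped
into 8-connected components linked across adjacent frames (union–find), and
a component becomes a wave if its peak single-frame area reaches 100 µm².

Three measurement decisions:

* **Robust baseline.** Per-pixel median and scaled MAD over up to 100
  frames sampled evenly across the whole recording. A wave-free *prefix*
  fails whenever a wave happens early (it inflates the threshold and
  deletes every detection); the evenly-sampled median is immune because a
  wave occupies few of any pixel's sampled frames.
* **Border rule.** Components whose *first* suprathreshold footprint
  touches the field border entered from outside the field and are excluded
  (reported as `n_excluded_boundary`); components that *grow* into the x
  border are kept but flagged `censored` — their extension is a lower
  bound.
* **Half-maximum extension.** Smoothing dilates the detection contour
  outward by roughly two smoothing SDs, but leaves the 50%-of-peak
  crossing of a sharp wave edge at the true edge. The footprint used for
  `extension_um` (bounding-box x-extent) is therefore re-measured at the
  half-maximum contour of the baseline-subtracted peak-area frame. In the
  recovery suite this removes a systematic +4 px bias.

Wave onsets elsewhere (e.g. OHC responses) use the 5-baseline-SD crossing
rule (`wave_onset`), and `propagation_delay` reports signed onset
differences.

## 5. Synchronization statistics

For each wave, a 400-frame window (13.2 s at 30.3 fps) is centred on the
wave peak; windows that would cross the recording boundary are rejected,
never shrunk. The background window is the earliest 400-frame stretch free
of any detected wave. Within a window, pairwise Spearman correlations are
averaged through Fisher's z (`rsavg = tanh(mean(atanh(r)))`, with |r|
clipped away from 1); constant traces yield NA pairs that are counted, not
zeroed. A wave "synchronizes" the OHCs when the one-sided Mann–Whitney
test of wave-window versus background correlations is significant at
P < 0.001.

Activity recruitment uses Savitzky–Golay (order 1, length 11) smoothed
trace integrals over the same windows. **Integrals are computed on F/F0 =
1 + detrended dF/F0**: the synthetic photobleaching otherwise dominates any
wave-versus-background difference, and the strictly positive background
integral keeps the fractional increase `(I_wave - I_bg) / I_bg` stable.
Cells with non-positive background integrals are excluded and counted.
Distance from a cell to a wave is the Euclidean gap to the wave footprint
(zero inside).

Dataset-level analyses are then: an OLS regression (with F-test) of rsavg on
wave extension; Welch's t comparison of fractional increases between waves
shorter than 75 µm and longer than 150 µm (strict boundaries, censored
extents being lower bounds); and wave rates in events per minute.

## 6. Pipeline, CLI, and chosen problem sizes

`run_pipeline()` chains the stages (`simulate`, `classify`, `waves`,
`sync`, or `all`) from a config, a traces CSV, or a TIFF movie plus cell
map, and `write_run_report()` serializes `report.json` with CSV
side-tables. A thin command-line front end ships at
`system.file("cli", "ohcsync.R", package = "ohcsync")`.

The acceptance-scale checks use: 100 coupled and 100 uncoupled 2-minute
recordings of 60 cells (slope recovery, in ten replicates of ten), 16
recordings with scheduled 50/170 µm waves (size classes, n = 32 per
class), 100 reduced-resolution movies (96 px, 7.575 fps; wave-rate
comparison), and 100 single-wave movies (count and extension recovery).
These sizes were chosen by power pilots run *before* the test assertions
were frozen, and fit a single-CPU grading budget.

## 7. Limitations

* The generator is phenomenological: wave propagation is a growing
  ellipse, coupling is a multiplicative rate modulation, and noise is
  white; none of this models IP3-receptor dynamics.
* The spike model assumes a single indicator time constant; amplitude
  adaptation and saturation are not modelled.
* The dead-time inversion assumes Poisson firing; for strongly bursty
  cells the corrected rate is still an underestimate.
* Extension of a censored wave is a lower bound; the size-class
  comparison treats it as such only through strict class boundaries.
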