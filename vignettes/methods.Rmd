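---
title: "Models and methods behind ca1drift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ca1drift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ca1drift reimplements, as a tested pipeline over synthetic data with known
ground truth, the per-session and multi-day analysis of chronic two-photon
calcium imaging from hippocampal CA1 pyramidal cells navigating a virtual
linear corridor. This vignette documents the models, the tunable
parameters, the numerical choices, and what the synthetic validation does
and does not establish about real data.

## The event noise filter

Upstream deconvolution emits nonnegative per-frame activity (`spks`, in
arbitrary tool units) alongside the neuropil-subtracted fluorescence
(`Fc`). To obtain a conservative activity estimate, every deconvolved
event must be backed by a fluorescence transient that clears the noise:

* the Fc peak is searched between the spike frame and nine frames later
  (first index on ties), and `Fc_max` is the mean of the three samples
  around it (clipped at the trace edges);
* the baseline `Fc_base` is a least-squares line over the 11 samples from
  30 to 20 frames before the spike, evaluated at the −20 position; the
  local noise SD is the RMSE of that fit;
* the global noise SD is the population SD of the Fc samples between 0.5
  and 1.5 times the trace median (a degenerate band, e.g. median 0,
  yields 0);
* the event is valid iff `Fc_max − Fc_base` strictly exceeds the noise
  SD. "Exceeds the local or the global SD" is read as exceeding **both**
  (`rule = "both"`), the conservative reading consistent with the
  filter's purpose; `rule = "either"` is available as a switch.

Choices left open by the procedure's verbal definition, fixed here: the
baseline window is anchored to the spike frame (all offsets in the
definition are spike-relative), the −30..−20 window is inclusive (11
samples), population rather than sample SD is used throughout (exposed in
code), overlapping event windows are processed independently per spike
(no merge rule exists), and events in the first 30 frames — where no
baseline window fits — fall back to the global SD alone with the trace
median as baseline, and are flagged.

## Spatial analysis

Positions are binned into 80 half-open bins (10 cm on the 800 cm track;
the bin count is a config key since the source procedure does not state
one). All (lap, bin) cells whose mean running speed is below 4 cm/s are
discarded before any tuning computation (strict inequality; a cell at
exactly 4 cm/s is kept).

The tuning curve is the mean filtered activity per bin; occupancy is the
fraction of valid frames per bin. Spatial information, in bits per event,
is

$$SI = \sum_i p_i \frac{\lambda_i}{\bar\lambda}
        \log_2 \frac{\lambda_i}{\bar\lambda},
  \qquad \bar\lambda = \sum_i p_i \lambda_i,$$

with zero-activity bins contributing zero. SI is invariant to rescaling
all rates, so the arbitrary units of deconvolved activity do not matter
for the tests.

The classification cascade per cell and session:

1. **silent** — no valid events after filtering;
2. odd–even gate: Pearson correlation of the odd-lap and even-lap tuning
   curves must reach 0.25 (lap 1 is odd; zero-variance curves fail with
   reason "degenerate") — otherwise **active non-place**;
3. global SI test: 1,500 circular rotations of the *full* deconvolved
   train by a uniform shift in {1, …, T−1} (identity excluded, since it
   would bias the null toward the observed value); the speed mask is
   applied after rotation. The cell is a **putative place cell** if its
   SI strictly exceeds the 99th percentile (linear interpolation,
   quantile type 7) of the shuffled SIs;
4. field delineation on the all-lap curve: interior strict local maxima
   with height ≥ 6 (inclusive; plateaus count once at their leftmost
   bin); if the valley between two adjacent peaks exceeds half the larger
   peak, the smaller peak is discarded (equal heights: the right peak,
   deterministically); bases at evaluation height
   `peak − 0.93 × prominence` with linearly interpolated crossings,
   rounded outward to whole bins; overlapping or touching bases merged;
5. local SI test per candidate field: the base extended by half its width
   (in bins, rounded outward) on each side defines the region; the null
   circularly rotates each lap's region samples independently (laps with
   fewer than two region frames stay unshuffled); criterion: 95th
   percentile, strict;
6. lap coverage: valid events in at least 30% of laps (inclusive) inside
   the base bins. A putative place cell with ≥ 1 surviving field is a
   **place cell**.

The peak/prominence/width machinery reproduces the standard
signal-processing definitions exactly (verified against an independent
interpolation oracle to 1e−9 in the test suite).

## ROI matching, tracking, and footprints

Anatomy-based masks (all somata, from the mean image) and activity-based
masks (active cells only) are matched when their overlap exceeds 75% of
the anatomy mask size; each anatomy ROI takes its largest-overlap partner
(ties: lower id). Unmatched anatomy ROIs are silent cells. Mean images
across days are registered by integer rigid translation (FFT
cross-correlation); day-to-day FOV repositioning is approximately
translational, so no warping model is used. Cross-day linkage reuses the
within-day 75% threshold — the minimal assumption, exposed in config —
computed at pixel resolution on shift-compensated masks, greedily by
descending overlap so links stay one-to-one. Only cells with an anatomy
ROI on every day become tracks.

Footprint validation attributes transients to their source ROI: the raw
ROI fluorescence is smoothed (Gaussian, σ = 2 frames), putative events
are maximal runs above median + 2 population SD of the smoothed trace,
the footprint is the mean event frame minus an equal-length pre-event
baseline restricted to the ROI bounding box dilated by 5 px, and the
event is accepted if the Pearson correlation with the binary mask exceeds
0.5. The frame window, baseline length and dilation instantiate a
procedure whose source description is not fully specified; all three are
config keys. The correlation is invariant to affine intensity rescaling.

## The multi-day silent-state model

Per-day states follow a two-state Markov chain: silent→active with the
unsilencing rate *u* (default 0.54, the mean rate over consecutive
session pairs), active→silent with the silencing rate (default also 0.54,
which keeps the silent fraction stationary at 0.5). The mean unsilencing
rate is estimated as the **unweighted mean over consecutive day pairs**
(pairs without silent cells are skipped); the transition-pooled estimate
is also reported. Under a memoryless chain the expected count of cells
silent on all of days 1..k, normalized to day 1, is $(1-u)^{k-1}$ — the
normalization to the first day's count fixes the exponent convention
(day 1 ≡ 1). A persistently silent subpopulation (cells that never
unsilence) lifts the empirical curve above this prediction from day 2 on;
the generator exposes `persistent_silent_frac` to produce exactly that
deviation.

## The synthetic-data generator

The generator's defaults are the study conditions: an 800 cm corridor,
50-lap sessions at 30 Hz, mean running speed 35 cm/s (the 30–40 cm/s
range of well-trained animals), a reward zone at 720–800 cm with licking
and slowing in a 100 cm approach window, ~50% silent cells, place cells
with 1–6 Gaussian fields, six-day cohorts with u = 0.54 and
representational drift (20 cm/day field-center random walk), and a
512×505 imaging grid.

Behavioral realism matters for the shuffle tests: lap-to-lap mean-speed
variability (lognormal, sdlog 0.15), within-lap Ornstein–Uhlenbeck speed
fluctuations (SD 5 cm/s, τ 0.5 s) and reward stops at RZ entry
(probability 0.7, exponential mean 1.5 s, near-zero speed) decorrelate
lap timing. Without them the trajectory is metronomic and a circular time
rotation merely translates a cell's field around the track, collapsing
the shuffle null onto the observed SI. The stops also generate the
sub-4 cm/s periods the speed filter must discard.

Event trains are inhomogeneous Poisson (baseline + Gaussian field bumps
evaluated at position); fluorescence is the true event train convolved
with an exponential kernel (τ = 0.7 s, a GCaMP6s-like indicator) on a
baseline of 100 with Gaussian noise (SD 2). Deconvolved amplitudes are
lognormal around 150 units: event rates the filter retains (~2 Hz field
peak) then put tuning-curve peaks near 10, comfortably above the
peak-height threshold of 6, whose units the upstream tool defines.
Per-class event rates are free parameters, not calibrated to any real
recording. False events (amplitude 1, ~0.2 Hz) are injected into the
deconvolved trains of active cells only — an activity-based segmenter
emits no trace at all for cells it cannot find — giving the noise filter
true rejects as well as true positives.

What the synthetic validation does **not** show: the generator has no
motion artifacts, no neuropil contamination beyond the overlapping-ROI
footprint scenario, no optics/PSF model, Gaussian (not heavy-tailed)
fluorescence noise, and ideal-disc ROIs. Passing tests demonstrate the
pipeline implements its stated rules correctly and is calibrated under
the generative model; they do not certify performance on real movies.

## Numerical choices and degenerate inputs

Percentiles use linear interpolation (quantile type 7). Significance
comparisons are strict (`>`), matching "larger than". Argmax ties take
the first index. The registration errors out on flat images; the tuning
computation errors out when no valid frames remain; silent cells return
NA spatial information. Bootstrap CIs are plain percentile intervals
(2.5th/97.5th of 5,000 resamples) — the procedure the whiskers represent —
not BCa. Dunn's post-hoc test is computed from rank sums with tie
correction and Holm adjustment. Seeds fan out from one master seed via a
stable string-hash derivation (`derive_seed`), so stages are reproducible
yet independent.

## Problem sizes in the validation suite

The test suite calibrates the global (1%) and local (5%) shuffle tests on
500 untuned cells each with 500 shuffles against exact binomial
acceptance regions; measures recovery on 100 single-field and 40
multi-field place cells over 50-lap sessions; checks the event filter
against a brute-force oracle on 1,000 random traces and the peak-base
delineation against an interpolation oracle on 1,000 random curves; and
estimates the unsilencing rate on 20 × 1,000 cells × 6 days. The
well-separated multi-field regime spaces fields ≥ ~120 cm apart with a
0.1 Hz out-of-field rate: at rel_height 0.93 a base descends to ~7% of
the peak prominence, so closer fields legitimately merge into one — a
property of the delineation rule, not a detection failure.
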