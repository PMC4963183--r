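---
title: "Methods: speed and direction decoding from trigeminal brainstem recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: speed and direction decoding from trigeminal brainstem recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vibdecode)
```

This vignette is the package's account of the analysis it implements: the
models and their assumptions, the parameters that matter, what the synthetic
generator does and does not emulate, and the numerical and design choices made
where the procedure left room.

## The experimental setting

A vertical post mounted on a 27 cm servo arm sweeps through the rat whisker
array at three angular speeds (90, 180, 360 °/s; `post_linear_speed()` gives
the corresponding 42/85/170 cm/s at the post) in two directions across the
array, rostral→caudal (RC) and caudal→rostral (CR). Six conditions, indexed
j = 1..6 in fixed order (speed ascending, RC before CR), each repeated 29
times. Extracellular recordings capture a broadband voltage: a slow evoked
LFP deflection (population activity), background noise, and the spikes of
nearby units.

## Trial alignment

Stimulus onset is not recorded, so trials are aligned on the physiological
response: per condition, the threshold is 60% of the mean over trials of the
peak **rectified** LFP, and the crossing is the first sample exceeding it. A
750 ms window centred on the crossing is extracted. Choices made where the
procedure is underspecified:

* **Rectified threshold.** Evoked deflections may be negative-going, so the
  absolute voltage is thresholded; first crossing of the rectified trace marks
  response onset.
* **Padding.** The decoders later compare templates at shifts up to ±100 ms,
  so alignment also stores an extended window with 100 ms of real samples on
  each side (`lfp_ext`); no zero-padding or truncated comparisons ever occur.
  A trial whose padded window does not fit inside the trace, or that never
  crosses threshold, is rejected (flagged, not an error).
* **Trial length.** The synthetic generator therefore defaults to 1.2 s trials
  with evoked onset at 0.5 s: the crossing lands near the trace middle with
  enough margin for the padded window at ±4 SD of onset jitter across all six
  conditions. (A bare minimum of 0.75 + 2×0.1 s would require the crossing to
  sit exactly at the midpoint, which jitter makes impossible.)

## The synthetic generator

`synth_params()` / `simulate_dataset()` build six-condition datasets with
complete ground truth (spike times, contact window, jitter). Each trial is:

    voltage = shifted evoked profile + N(0, lfp_noise_sd) + spike waveforms

* **Evoked LFP profile**: smooth, compact-support deflection — a
  difference-of-Gaussians main lobe (negative-going, with a smaller rebound)
  under a Hann taper. Support width equals the speed's evoked duration
  (default 0.15/0.075/0.0375 s — inversely proportional to speed, as the post
  spends less time in the array); peak amplitude is per condition (default
  2.0–3.0, higher for CR); the lobe peaks earlier in the window for RC than
  for CR. All six profiles are mutually distinct.
* **Spiking**: piecewise-constant rate (spontaneous 2 spikes/s outside the
  contact window, condition rate 60–100 spikes/s inside), sampled by
  per-sample Bernoulli thinning with p = rate/fs (requires rate ≤ 0.1·fs).
* **Shared jitter**: one Gaussian onset jitter per trial (SD 10 ms) shifts the
  LFP profile *and* the rate profile — the ground-truth contact window tracks
  it, so alignment and decoding can be validated against it.
* **Spike waveform**: a biphasic ~1.5 ms template, peak amplitude 1, added at
  every ground-truth spike time.

Default calibration: with noise SD 0.1, the evoked deflection sits 20–30
noise SDs above the floor (evoked LFPs dwarf single spikes in vivo) and the
spike waveform near 10 in the broadband trace — above the customary
signal-to-noise bound of 3 for an isolatable unit. The contact rates and
durations are set so the evoked rate exceeds **3× the whole-window mean rate
with at least ~2 SD of 15 ms-bin margin** in every condition; this is the
regime the PSTH-threshold window estimator assumes (a visibly strong response
over a low baseline), and outside it the 3×/2× rule is not meaningfully
applicable. Sampling rate defaults to 4 kHz to keep desk-scale analyses in
seconds; everything downstream is fs-agnostic and 40 kHz works unchanged.

What the generator does **not** emulate: spike-rate adaptation within the
contact window, overlapping-spike waveform superposition beyond simple
addition, electrode drift, 1/f or line noise, multi-unit background, and any
whisker biomechanics. Tests passing on this world therefore validate the
*pipeline's* statistics and bookkeeping, not its robustness to those
real-data complications.

## Filtering and envelopes

Band-pass filtering is a 4th-order Butterworth applied forward–backward
(`signal::filtfilt`), i.e. zero-phase, so spike/LFP latency relations are
preserved. Envelopes are the magnitude of the analytic signal (FFT-based
Hilbert construction). The filterbank for tuning analysis defaults to
{1–100, 100–300, 100–3000, 300–1000, 300–3000, 1000–3000, 1000–5000,
1500–4200} Hz; bands at or above Nyquist are skipped.

## Spike sorting

Detection thresholds the rectified 300–3000 Hz trace at `k_mad = 4` robust
SDs (MAD/0.6745), takes the local extremum of each supra-threshold excursion,
and enforces a 1 ms lockout. Snippets are 2 ms. Features are peak height,
peak width, trough depth, trough width (widths are full width at half
extremum with **sub-sample interpolation** of the crossings — without it the
widths are quantised to the sample grid and mixture models over-split), plus
the first three principal components of the centred snippets. Clustering is a
Gaussian mixture over k = 1..5 selected by BIC (`mclust`).

Two manual steps of the original procedure are replaced by deterministic
rules:

* **Cluster selection**: the isolation score is template peak-to-peak over the
  median within-cluster residual RMS; the best cluster must score ≥ 3 or a
  no-unit signal is returned.
* **Acceptance threshold**: 3× the median least-squares error of *all*
  detected events against the template, over a central 1 ms matching window,
  with the error minimised over ±1 sample of detection jitter. Basing the
  median on all events (not only the chosen cluster's members) matters at low
  sampling rates: with ~6 samples per spike the mixture model often splits
  one unit into sub-clusters by sub-sample alignment phase, and a
  cluster-local threshold would then reject the unit's other phase variants.

At 4 kHz the nominal 300–3000 Hz spike band violates Nyquist; the sorting
front-end caps the band at 0.9× Nyquist (300–1600 Hz at 4 kHz). `bandpass()`
itself refuses invalid bands.

Known limitation: near-coincident spikes (< 1 ms apart, common at 100
spikes/s) merge under the lockout, which bounds recall; overlapping-spike
resolution is out of scope.

## Contact windows and response metrics

The PSTH uses half-open 15 ms bins, 0-based, normalised to spikes/s. The
contact window starts at the left edge of the first bin exceeding 3× the mean
rate and ends at the left edge of the first *subsequent* bin below 2× the
mean rate (window end if none). "Mean rate" is the mean PSTH over the full
750 ms window; a pre-stimulus baseline would also be defensible, and the
quantity is an explicit argument. A single bin below the end threshold
terminates the window. Per-trial statistics are the in-window rate, the
window duration, and the out-of-window background rate.

## Tuning ANOVA

Each trial contributes three observations (pre-contact, contact,
post-contact), with the response being the phase's spike rate or the RMS of a
band envelope. The model is a fixed-effects three-way ANOVA with main effects
only (phase + speed + direction), Type-II sums of squares (`car::Anova`), at
α = 0.05 per band with no multiple-testing correction (a Benjamini–Hochberg
option would be trivial to add, but per-band testing is the convention
followed here). A constant response yields p = 1 rather than an undefined F.
Phase is included as a factor (rather than subsetting to contact) so
responsiveness itself is testable.

## The decoders

**LFP templates.** Per condition, μ_j is the pointwise mean of training-trial
windows and σ_j the time-average of the across-trial SD — an isotropic
diagonal covariance (independence across samples, constant variance over
time; both clearly idealisations). The log-likelihood drops the
condition-independent −N/2·log 2π term. σ is floored at 1e−9 so degenerate
noiseless fixtures remain classifiable.

**Bernoulli spike trains.** p_i is the fraction of training trials with ≥ 1
spike in bin i (3 ms bins over 750 ms). This makes "1 if a spike occurred in
that bin in every trial" a theorem rather than a rule. p_i is floored at
spontaneous_rate × bin_width and capped at 1 − 1e−6 (an empty bin must never
contribute log 0). Bin occupancy is binary; multiple spikes in a bin count
once. The spontaneous rate defaults to a pooled estimate from the first
150 ms of the aligned window (pre-contact baseline), recomputed per fold.

**Shift search.** Both classifiers maximise over τ ∈ −100..+100 ms in 2.5 ms
steps before the argmax over conditions. Shifted spikes falling outside
[0, 750 ms) are dropped (not wrapped). Ties break deterministically: lowest
condition index, then smallest |τ|, then negative τ first.

**LOOCV.** For each held-out trial all models are refit per fold — no caching
shortcut that changes numerics. Confusion matrices are row-stochastic over
true conditions; accuracy is the trial-count-weighted diagonal.

By default the folds are **balanced**: besides the test trial, one
matched-index trial of every other condition is dropped, so every condition
trains on n−1 trials. Naive leave-one-out (own condition n−1, others n) is
measurably biased on uninformative data: the Gaussian template likelihood
handicaps the true condition by roughly 0.5·N·(1/(n−1) − 1/n) — at N = 750,
n = 29 this depresses pure-noise accuracy visibly below 1/6, and severely so
for small n — while the sparse Bernoulli spike model is nudged the other way
(a model fit on fewer trials has fewer bins lifted off the spontaneous floor
and scores mostly-empty test trains slightly higher). Balancing restores
exchangeability across conditions, so chance-level data decode at exactly
1/6 in expectation; on informative data the effect of dropping one foreign
training trial is negligible. `balance_training = FALSE` gives the naive
variant.

## Problem sizes used in validation

The test suite and the acceptance script run the study-scale configuration
(29 trials × 6 conditions) at 4 kHz for the end-to-end recovery checks, and
at 1 kHz for the repeated-dataset studies: 10 shuffled-label noise datasets
for the chance level, 10 seeds per amplitude level for the SNR sweep
(windows centred on the known per-trial stimulus time, isolating the decoder
from threshold alignment, which cannot operate at zero SNR), 8 simulated
recording sites for the LFP-vs-spike rank-sum comparison, and 1000 simulated
null tables for the ANOVA type-I error. Monte-Carlo convergence checks
(PSTH ↔ rate profile, thinning expectations) use 1000–4000 simulated trials.
These sizes were chosen so the whole suite runs in a couple of minutes; all
of them scale with the corresponding parameters.

## Degenerate inputs, by design

* All-zero or never-crossing traces: trial rejected at alignment, not an error.
* Flat PSTH: no-response signal (`NULL` window).
* Identical training trials: σ floored; classification still deterministic.
* Constant ANOVA response: p = 1.
* Identical accuracy lists: rank-sum p = 1.
* Zero-amplitude conditions: all-zero profiles, pure-noise voltage.

## Outputs

`run_pipeline()` writes `rates_durations.csv` (per-trial rate/duration/
background), `anova.csv` (per-band p-values and tuned flags),
`confusion_{lfp,spikes}.json` (accuracy, confusion matrix, per-trial
predictions with best shifts), `config.yaml` (every constant of the analysis
as a named key) and a stage-timing log. Trial stores round-trip through a
plain-text directory layout (`meta.csv`, `voltage.csv`, `spikes.csv` in the
published per-trial spike-time spreadsheet layout).
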