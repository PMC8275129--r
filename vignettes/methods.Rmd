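---
title: "Methods: sleep scoring and synaptic-stability analytics in sleepephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep scoring and synaptic-stability analytics in sleepephys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sleepephys)
```

`sleepephys` implements an analysis chain for experiments that track a
rodent's natural sleep/wake history and ask whether excitatory synapses
change across extended periods of sleep or wake: real-time sleep scoring
from EEG/EMG/video, hypnogram analytics (dense-epoch detection, delta-power
homeostasis), miniature-EPSC detection and group statistics, evoked field
potential (fEPSP) measurement with current-source-density layer
localization, and bootstrap-gated evoked-spike analysis. Because the method
itself — not any one animal's data — is the package's subject, every stage
is paired with a seeded synthetic generator that produces ground-truthed
input with the statistical structure the analysis assumes.

## The behavioral-state model

States tick at 1 s (so that 1-s review granularity is representable) and
evolve as a Markov chain whose per-tick transition matrix is assembled from
two ingredients of `sim_params()`: mean dwell times per state (giving
geometric sojourns, e.g. NREM 160 s in the light phase, in the range of
reported juvenile-rat NREM bout lengths) and an embedded jump matrix
(wake enters sleep through NREM; REM is entered from NREM and usually exits
to wake). Both are conditioned on photoperiod — light/dark is handled as two
parameter sets rather than a continuous circadian model, which is enough to
reproduce the coarse statistics the defaults are calibrated to: roughly 60%
of light-phase time asleep versus ~35-40% in the dark. These defaults are
calibrated targets, not claims about rat physiology; the analytic k-step
persistence of the chain (`expected_persistence()`) is what the empirical
tallies in the tests are checked against.

## The signal model

The synthetic EEG is a sum of band-limited Gaussian noise components
(delta 0.5–4, theta 5–8, beta 20–35, gamma 35–80 Hz; the gamma upper edge
is our choice since only the lower three bands have conventional
definitions here) produced by Fourier masking of white noise and scaled
per 1-s tick by the state's band-power profile with a ~1-s linear
crossfade. Per-epoch spectral features depend only on band variances, so
this deliberately simple model is sufficient for everything downstream.
NREM carries ~20x the delta power of wake/REM; REM carries ~10-20x the
theta of NREM/wake; wake is desynchronized with relatively high beta and
gamma. The EMG is baseline noise plus Hann-enveloped noise bursts
(Poisson-arriving, rate 1/s in wake, zero in NREM/REM — atonia), and
movement is a per-second Poisson count (~40 px/frame in wake, near zero in
sleep).

What the generator does *not* emulate: artifacts (chewing, scratching,
electrical noise), state-dependent spectral gradients within a state,
microarousals shorter than one tick, volume-conduction structure, or any
circadian drift in signal amplitude (except the optional imposed delta
decay). Passing tests therefore demonstrate correctness of the *machinery*
under the stated statistical assumptions, not robustness to real-world
recording pathology.

An oscillatory EMG burst can dip below the 1-SD excursion-termination
level mid-burst and be counted as more than one deflection; the deflection
score is therefore a monotone proxy for muscle activity rather than an
unbiased burst counter (the counting rule itself is verified against
unimodal pulses, where one pulse is exactly one excursion).

## Real-time classification

Features per 10-s epoch: Welch band powers (2-s Hann segments, 50%
overlap — a variance-reduced refinement of a plain 10-s FFT that leaves
band totals essentially unchanged), the delta/beta and theta/delta power
ratios (absolute powers; log10 only for display and forest features), an
EMG deflection count (|z| crossings of 3.5 SD, merged until re-crossing
1 SD), and summed movement. The decision tree runs in the order
movement/EMG → delta → theta → wake-fallback: wake is the safe default,
and a tie (both ratios above threshold) goes to NREM because REM rarely
shows high delta. EMG normalization uses the whole recording post hoc but
an expanding window in real time, since a causal system cannot see the
future.

**Threshold initialization.** The experimentalist sets thresholds by eye;
an automated benchmark needs a deterministic equivalent. Percentile-based
initialization is unstable for a bimodal log-ratio distribution: whenever
more than a quarter of the calibration window is NREM, a 75th-percentile
delta threshold lands *inside* the NREM cluster, and the wake-exit
multiplier then locks NREM out entirely. `calibrate_thresholds()` instead
splits each log-ratio by exhaustive 1-D two-means clustering (deterministic,
no RNG) and places the decision threshold at the ratio that a 50/50 mixture
of the two cluster-mean band-power profiles would produce. Because band
powers mix linearly across a transition epoch, this boundary labels a mixed
epoch by whichever state occupies most of it — matching the majority-vote
semantics of the reference scoring. Movement and EMG thresholds are linear
two-means midpoints for the same reason. A branch whose feature shows no
bimodal separation in the calibration window (cluster gap < 0.5 log10
units) is parked above all observed values so it stays inactive — this is
what makes an all-wake recording come out ≥99% wake. The calibration window
is 1 h so that a REM example is nearly always present.

**Adaptation.** Thresholds are multiplicatively biased by the previous
epoch's label (×0.8 toward persistence, ×1.2 after wake, clamped to
[0.5, 2]), reflecting the strongly non-uniform transition probabilities
between states. Thresholds live on the linear ratio scale: multiplying a
signed log-ratio would invert its meaning whenever the threshold log is
negative.

The classifier processes 4-min chunks of 10-s epochs. Epochs inside the
calibration window are labelled when it completes (a documented bootstrap
phase); from there on, the label of epoch *k* depends only on data up to
the chunk containing *k*.

The post hoc scorer is a 256-tree random forest on the same features plus
band proportions, min/max EEG and lags up to 3 epochs back (we lag all
features; the reference procedure lags "many" without naming them). Wake
is split into active/quiet wake by movement above threshold or a
desynchronization criterion (gamma proportion > 0.3 and delta proportion
< 0.2, matching the generator's active-wake spectral profile).

## Hypnogram analytics

Dense epochs use two criteria: ≥4 h with >65% time-in-state and the final
hour >70% (endpoint experiments), and ≥30 min with >75% (sandwich
analyses). All inequalities are exclusive. "Sleep" pools NREM+REM. A
window end qualifies when both fractions pass; overlapping qualifying
windows merge, the reported `end_s` is the *first* crossing (the moment an
endpoint experiment would proceed) and `span_end_s` the last. Labelled
time counts as-is — whether sub-10-s microarousals should count against
density is unresolved in the field, so we do not special-case them. Both
detectors are verified epoch-for-epoch against an exhaustive brute-force
window scan on 1,000 random hypnograms.

NREM delta power (per 10-s epoch, Welch) is normalized to the ZT 7–11
baseline where it is typically lowest; the time-of-day NREM-amount
correction is applied in spirit — epochs are weighted equally within NREM
only — rather than reproducing any particular weighting scheme. The
overnight drop compares ZT 23.5–1.5 with the final hour of sleep.

## mEPSC detection

Detection is a sliding optimal-scaling template fit (the classic
scaled-template criterion): at each offset the best scale and baseline are
closed-form, and the criterion is
`scale / (sqrt(SSE/N) * (1 + size_bias * scale))` — the size-bias term
(default 0.05/pA) discounts large events for their larger absolute
residuals. Defaults: 0.5 ms rise / 3 ms decay double-exponential template,
20 ms long, threshold 3.5. The trace and template are low-pass filtered at
1 kHz before fitting; because filtering is linear, fitting the *filtered*
template to the *filtered* trace leaves the amplitude estimate unbiased
while roughly halving the effective noise. These defaults were fixed once
against annotated synthetic training traces (the same tuning-then-freeze
procedure used with manually annotated recordings) and stay constant in
every analysis.

Amplitude is reported as the re-fit template scale rather than the raw
trace minimum: the minimum of ~200 noisy samples is biased upward by
extreme-value statistics (~1-2 pA at realistic noise), which would violate
the <5% amplitude-bias requirement; the least-squares scale is unbiased.
The 2 ms pre-onset baseline is still measured and reported, and is used
for the 20–80% rise time (the inclusion criterion "rise < 3 ms" does not
name percentage points; 20–80% is our concretization) and for the
single-exponential decay fit (analytic amplitude, 1-D tau search).
Inclusion filters: amplitude > 5 pA, rise < 3 ms, no digitizer-rail
saturation (two consecutive samples at a declared rail), decay fit must
converge. Cells need Rs ≤ 25 MΩ, Vm ≤ −50 mV and ≥10 included events.
Manual review is modeled as a table-injection API (`flag =
"manually_added"`), not reproduced automatically.

Group statistics: Kruskal–Wallis on cell means; cumulative distributions
from an equal-count seeded subsample per neuron with pairwise KS tests and
Bonferroni correction.

## fEPSP measurement

LFP is band-passed 5–450 Hz (order 2). Zero-phase filtering is required so
trough latencies are comparable across channels; we apply the squared
Butterworth magnitude in the frequency domain, which is exactly what a
forward-backward time-domain pass applies without its edge transients.
Sweeps are −100/+80 ms around each stimulus, baseline-subtracted; QC
rejects baseline SD > 200 µV (final 5 ms) and absent troughs (> 30 µV,
exclusive) within a 1.5–30 ms post-stimulus search window (the artifact
blank and search limit are our choices; the reference values are the two
QC cutoffs). The trough is the first local minimum passing the criterion;
the slope is the least-squares line over falling-phase samples between 20%
and 80% of trough amplitude ("maximum amplitude" read as trough magnitude,
"rise of the waveform" as the rising magnitude of the downward
deflection); the analysis channel is chosen by joint rank of largest
amplitude and shortest latency. CSD is the negated second spatial
difference over uniformly spaced channels; edges are undefined; the sink
is the most negative CSD at the trough time.

Time courses normalize 10-min bins to the first hour of each epoch (the
first-hour convention; for epochs shorter than an hour the window
truncates to the epoch), with light-dark transitions re-anchored by
matching the first post-transition bin to the last pre-transition bin.
The sandwich statistic compares matched-state flanking hours: NREM
measurements flank wake-dense epochs and quiet-wake measurements flank
sleep-dense epochs (both pairings selectable via `flank_state`), change =
post/pre − 1, Wilcoxon signed-rank against zero, OLS of change on epoch
duration.

## Evoked spiking

Per stimulus: `response = count(t, t+0.02] − baseline_rate × 0.02`, with
the baseline rate from the preceding 60 s (truncated at recording start;
empty-baseline stimuli skipped). The post-stimulus window defaults to
20 ms per the printed formula; 15 ms is selectable since both appear in
the source descriptions. Hourly isolation requires ISI-contamination
(< 2 ms fraction) ≤ 4%; hours with < 2 spikes are unassessable and
excluded. The responsiveness gate builds a null from pseudo-stimulus sets
matched in count to the real stimuli, sampled uniformly outside ±100 ms
of any real stimulus (our concretization of "times where no stimulations
occurred"), with the overall count matched rather than the per-state
composition (state-matched sampling would be a straightforward extension).
A unit is responsive iff its observed mean reaches the null's 95th
percentile — by construction a 5% false-positive gate, which the
calibration tests verify empirically. State comparisons use two-sample
t-tests on log-transformed unit means; nonpositive means are excluded
with a warning rather than shifted, since an additive constant would make
the log-scale inference arbitrary.

## Problem sizes and numerical choices

The benchmark suite uses a 24-h recording at 200 Hz (17.3 M samples;
Nyquist comfortably above the 80 Hz gamma edge), 10-s epochs, 4-min
cycles; statistical calibrations use 1,000 replicates for type-I error
(±2% band on a 5% target) and 40–150 seeded replicates for power and gate
calibration, sizes at which a 3-SE band is decisive for the effects being
checked. mEPSC benchmarks use 100 s at 10 kHz (2 Hz events, 1.8 pA RMS
noise); fEPSP runs use 1–1.5 h at 1 kHz with 8 laminar channels. All
generators take explicit integer seeds and restore the caller's RNG
state; two-means clustering is exhaustive over sorted splits, so
calibration has no RNG at all. Ratios with zero denominators propagate as
flagged `NA` and the decision tree treats missing spectral features as
wake, never as an error.

## Interface notes

This is a library-style package: the exported functions, `pipeline_run()`
(config in, CSV + log + config snapshot out) and this vignette are the
operating surface; there is no shell entry point. Recordings interchange
as CSV or native EDF (16-bit; round-trip error bounded by the documented
quantization step); hypnograms, events, measurements and dense epochs as
CSV; configs as YAML/JSON. HDF5 is not supported.

## Known limitations

Real recordings will need per-animal threshold review (the automated
initialization assumes the calibration hour samples at least two states);
the EMG deflection score over-counts oscillatory bursts; the synthetic
polysomnography cannot probe robustness to artifacts or electrode drift;
dense-epoch semantics at the very start of a recording are undefined until
one full window has elapsed; and spike sorting, waveform clustering and
unit-type classification are upstream of this package — sorted spike times
are an input.
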