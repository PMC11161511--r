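---
title: "Models and methods behind optopeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind optopeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optopeth)
```

`optopeth` implements the analysis chain used to study how a genetically
defined neural population responds during head-fixed probabilistic
Pavlovian conditioning: optogenetic tagging statistics, spike-train
response analysis, isosbestic-corrected fiber photometry, and lick-based
behavioral readouts. Because the statistics involved (rank tests on
small trial counts, permutation and surrogate procedures, clustering)
are easy to get subtly wrong, every stage is exercised against a
synthetic-session generator with known ground truth. This vignette
explains the models, the defaults and why they were chosen, and what the
synthetic benchmarks do and do not demonstrate about real recordings.

## The task simulator

A session is a sequence of trials. Each trial draws a foreperiod from an
exponential distribution truncated to 1–4 s, then presents a 1 s
auditory cue (Cue 1 or Cue 2 with probability `p_cue1`), and delivers
the outcome 200–400 ms (uniform) after cue offset. Outcomes follow
per-cue contingency triplets; the defaults are the task's:

* Cue 1 (likely reward): 80% reward, 10% punishment, 10% omission;
* Cue 2 (likely punishment): 25% reward, 65% punishment, 10% omission.

The next trial requires 1.5 s of lick-free time. Two parameters are not
dictated by the task description and are package choices, exposed in
`session_config()`: the untruncated foreperiod mean (2 s, concentrating
mass early in the 1–4 s range, as a truncated exponential intends) and
the cue mix `p_cue1` (0.5; sessions that present only one cue are
obtained with `p_cue1` of 0 or 1). Truncation is by rejection, which is
exact and cheap at these parameters (roughly half of raw draws are
accepted).

Licking is an inhomogeneous Poisson process: between cue onset and the
outcome the rate ramps linearly from `lick_base` (0.5 Hz) to
`lick_base + lick_learning * value(cue)`, where `value(cue)` is the
cue's reward probability, so a trained animal (`lick_learning > 0`)
licks more, and earlier, after the reward-predicting cue; reward
triggers a consummatory bout (6 Hz for 1.5 s). Setting
`lick_learning = 0` produces a naive animal. Foreperiods are lick-free
by construction rather than by simulating trial restarts: restart
dynamics change no downstream statistic computed here, only the
wall-clock length of a session.

Every trial draws its randomness from a sub-stream seeded by the
session seed and the trial index, so extending a session preserves its
prefix bit-for-bit — a property the test suite relies on.

## Synthetic spike trains and tagging epochs

`generate_spike_train()` produces inhomogeneous Poisson spiking by
thinning. The rate is the baseline except inside
`[latency, latency + response_duration]` after each event whose gain
differs from 1, where it is `baseline * gain * adaptation^(k-1)` for
the k-th presentation — the adaptation term reproduces the decay of
responses over repeated aversive stimuli. A `burstiness` fraction of
spikes seeds short bursts (2–4 spikes, 3–8 ms intervals), giving the
short-lag autocorrelogram shoulder of a burst-firing unit. Spike times
are de-duplicated at 0.1 ms, the resolution of typical acquisition.

`generate_tagging_epoch()` follows the photostimulation protocol: 1 ms
pulses at 20 Hz for 2 s, a 3 s pause, repeated 25 times by default
(protocol range 20–30), preceded by a 120 s pulse-free baseline epoch
that the latency test needs for its surrogate windows. A tagged unit
fires after each pulse with probability `reliability` at
`latency ± jitter` (defaults 3 ms ± 0.5 ms) on top of baseline
spiking.

These generators emulate event-locked rate changes, bursting and
light-evoked spiking, but not waveform drift, electrode instability,
spike-sorting contamination, or rate co-fluctuations across units.
Passing the benchmarks therefore demonstrates correctness of the
statistics under their stated assumptions, not robustness to sorting
artifacts — which is what the quality gates (`unit_quality()`,
`duplicate_units()`) are for on real data.

## PETHs and z-scoring

`event_peth()` bins event-aligned point processes into trial-averaged
rates (Hz) over half-open windows, optionally smoothed with a
truncated-Gaussian kernel renormalized at the edges (a constant rate is
preserved exactly). Smoothing defaults differ by signal: 20 ms SD for
spikes — narrow enough to resolve a fast phasic punishment response —
and 100 ms for licks and photometry, where the underlying signals are
slower. The spike value is a package choice; only the 100 ms kernel is
dictated by the source methods.

`zscore_peth()` normalizes by the mean and SD of the bins in a baseline
window (default the 1 s before the alignment event), so baseline bins
have mean 0 and SD 1 by construction, and the transform is invariant to
affine rescaling of the rate. A baseline with zero variance is flagged
`degenerate` and only centred — never silently divided — so such PETHs
can be excluded from population averages.

An important convention used throughout: when the analysis aligns to
reinforcement, the baseline stays anchored to the *cue* of the same
trial (the 1 s before cue onset), passed via `baseline_events`. This
keeps the baseline free of cue-evoked activity.

## Response classification and adaptation

`classify_response()` compares per-trial baseline and test-window
firing rates with one-sided Mann–Whitney U tests in both directions at
`alpha = 0.001`; a unit is activated/inhibited when the corresponding
test is significant, otherwise unresponsive. Rates rather than raw
counts enter the test so that unequal window lengths are handled; with
equal windows the two are equivalent. The test window is 0–0.5 s after
the event for all event types — the fixed-window reading of the
methods — and both p-values are always reported. The suite verifies the
empirical type-I error on 1,000 homogeneous Poisson units (bounded by
2×alpha plus Monte-Carlo tolerance; the normal approximation with ties
is close to nominal here) and ≥ 95% power for a 4× gain over 0.5 s with
50 trials.

`session_half_comparison()` splits each unit's events at the median
event index (first half takes the extra event on odd counts — an index
split, not a clock split, so both halves have equal trial counts),
computes the smoothed-PETH peak and baseline rate per half, and runs
two-sided Wilcoxon signed-rank tests across units. A single unit yields
descriptive output only.

## Autocorrelograms, burst index, burst segmentation

`acg()` counts positive spike-pair lags in 0.5 ms bins (zero-lag
self-pairs excluded). For display normalization it z-scores per lag
against ISI-shuffled surrogates (default 100): the surrogate
construction in the source literature is not recoverable in detail, so
ISI shuffling — which preserves the ISI distribution while destroying
serial order — is this package's definition, recorded in the output.

The burst index is

$$\mathrm{BI} = \frac{\max_{0-10\,\mathrm{ms}} - \ \overline{180-200\,\mathrm{ms}}}{\max(\max_{0-10\,\mathrm{ms}},\ \overline{180-200\,\mathrm{ms}})} \in [-1, 1],$$

defined as 0 when both terms vanish. A unit is called bursting when
BI > 0.3 and its refractory period is < 2 ms; the refractory period is
estimated as the 0.5th ISI percentile (`is_bursting()`), a robust
stand-in for the minimum ISI that a stray coincidence would corrupt.

`segment_bursts()` applies the ISI rule left-to-right: a burst opens on
an ISI < 10 ms and extends while ISIs stay < 15 ms. The implementation
is checked for exact agreement with an independently written rule
oracle on 1,000 random trains spanning Poisson to strongly bursty
regimes.

## Optogenetic tagging: SALT

The stimulus-associated spike-latency test asks whether first-spike
latencies after light pulses could have arisen from spontaneous
activity. The package builds one latency histogram from 10 ms windows
at pulse onsets (1 ms bins plus a dedicated "no spike" bin, so empty
windows contribute mass instead of being dropped; windows are half-open
and the 1 ms pulse duration is not subtracted) and 100 histograms from
windows of the same length tiled over the pulse-free baseline epochs.

The source methods defer the test's internals to earlier work, so the
concrete scheme here is this package's definition, designed so that
statistical calibration — not bit-level agreement with any legacy
code — is the correctness contract:

* every histogram is built from the same number of windows (pulses or
  baseline windows are subsampled as needed), which makes all
  `N + 1` histograms exchangeable under the null;
* each histogram is scored by its median Jensen–Shannon divergence
  (base-2; the information radius) to all others;
* the p-value is the rank of the test histogram's score among all
  `N + 1` scores, so the smallest attainable p is `1/(N+1)` — with the
  default `N = 100`, p < 0.01 occurs with probability 1/101 ≈ 0.0099
  under the null, which the suite confirms empirically over 1,000
  Poisson replicates, along with ≥ 95% detection of a unit responding
  at 3 ms ± 0.5 ms with 0.9 reliability.

The final decision (`tag_decision()`) additionally requires the Pearson
correlation between light-evoked and spontaneous mean waveforms to
reach 0.84 — the empirical floor over accepted units — guarding against
light-artifact "units". Duplicate tagged units recorded on the same
tetrode within 200 µm are merged by `duplicate_units()` using waveform
correlation ≥ 0.95 and autocorrelogram cosine similarity ≥ 0.9;
the thresholds are not printed in the source and were chosen
conservatively relative to the reported within-unit correlation range
(0.84–1.00).

## Fiber photometry

The processing chain (`process_photometry()`) is: zero-phase 4th-order
Butterworth low-pass at 20 Hz on both raw channels → ordinary
least-squares fit of the calcium channel on the isosbestic channel →

$$\mathrm{dff} = \frac{f_{465} - f_{405,\mathrm{fitted}}}{f_{405,\mathrm{fitted}}} \times 100$$

→ zero-phase 0.2 Hz high-pass on the dff to remove the bleaching
trend. The filter order is not stated in the source; order 4 applied
forward–backward is the common physiological-signal choice and is
configurable. Whether the high-pass acted before or after the ratio is
also not explicit; it is applied to the dff here (the "slow decrease of
the baseline" reading) and both cutoffs can be disabled. The fit is
computed over the full recording; a per-trial fit would absorb slow
signal changes into the reference. Filtering subtracts the mean and
odd-reflection pads the series before the forward–backward pass, so
recursion startup transients stay out of the output; recordings shorter
than `3/cutoff` skip the high-pass with a warning rather than returning
edge artifacts.

`align_average()` extracts per-event dff snippets, smooths them
(100 ms), averages across events and z-scores the average by the mean
and SD of the baseline trace (1 s before the cue, via
`baseline_events`). The per-trial matrix is returned for single-trial
displays, and events too close to the recording edges are dropped with
a count.

The generator (`generate_photometry()`) builds
`f465 = B(t)(1 + g\,a(t)) + m(t) + \varepsilon` and
`f405 = c\,B(t) + s\,m(t) + \varepsilon'`, with `B(t)` an exponentially
bleaching baseline (tau 600 s), `a(t)` a sum of
difference-of-exponential calcium kernels (rise 0.1 s, decay 1 s —
typical slow-indicator kinetics) at the session's events, and `m(t)`
band-limited (2 Hz) motion noise shared between channels. The suite
verifies the three properties that matter: dff is identically zero when
one channel is an affine function of the other; with zero neural signal
and fully shared motion the event-aligned |z| stays below the 95th
percentile of an event-shuffled null; and the recovered peak z grows
monotonically with the simulated response amplitude over {0.5, 1, 2}.
This emulation omits wavelength-dependent motion coupling and
hemodynamic contamination; the isosbestic fit corrects only what is
linearly shared.

## Behavioral readouts

`anticipatory_rate()` counts licks in a window after cue onset (default
0.6–1.1 s, the half second preceding the earliest reinforcement) over
the window length. `reaction_time()` returns the first-lick latency
with censoring beyond `max_wait`; censored trials are excluded from
averages.

`auroc()` is the Mann–Whitney statistic scaled to [0, 1]: the
probability that a random value from one group exceeds one from the
other, ties counted half — verified against exhaustive pair counting.
`auroc_timecourse()` applies it per 10 ms bin between two groups of
sessions and attaches a permutation p per bin from 200 label
resamplings (two-sided on |auROC − 0.5|, with the +1 convention, so the
p floor is 1/201 and is reported). The per-session quantity entering
the comparison is, by default, that session's smoothed Cue 1 − Cue 2
lick-rate difference (`session_lick_series()`): the group contrast asks
whether cue *discrimination* differs, which matches plotting
per-session cue differences; a raw single-cue mode is available since
the source is not fully explicit on this point. No correction is
applied across time bins (none is applied in the source); contiguous
significant spans are flagged instead.

## Numerical conventions and degenerate inputs

* All event windows are half-open `[a, b)`; a point exactly at a window
  end is excluded.
* Latency binning is guarded by a small epsilon so results are exact
  under uniform time translation of a whole recording.
* Empty inputs: an empty session is an empty table, an empty lick
  train a zero PETH; an autocorrelogram needs ≥ 2 spikes; response
  classification needs ≥ 5 trials; group comparisons need ≥ 2 sessions
  per group. Each violation is an explicit error, not a silent NA.
* K-means uses 50 restarts on the first 3 principal components;
  clusters are relabeled by descending tagged fraction (ties by size)
  so "cluster 1" is always the tagged-enriched one. Fewer distinct
  profiles than `k` yields a single flagged cluster instead of
  duplicated centres.
* The isolation distance requires at least as many noise spikes as
  cluster spikes; a singular cluster covariance is an error with
  guidance, not a pseudo-inverse.

## Problem sizes in the checks

The statistical suites run at sizes chosen to give the Monte-Carlo
estimates enough precision while remaining comfortable to run locally:
10,000 trials per cue for contingency convergence, 1,000 replicates for
the SALT and classifier null calibrations (Monte-Carlo SE ~0.003 at the
1% level), 200 replicates for the power checks, 1,000 random trains for
the burst-rule equivalence, and 40 event shuffles for the photometry
artifact null. Larger sizes sharpen the same comparisons without
changing their outcome.

## Known limitations

* The SALT scheme is calibrated by construction and simulation but is
  not a bit-level reimplementation of the historically used code; with
  `N = 100` its p resolution (1/101) sits just under the 0.01
  threshold, so borderline units get p = 0.0099, never smaller.
* The lick model has no satiety, no session-level drift, and no
  foreperiod restarts; it supports testing discrimination statistics,
  not modeling licking microstructure.
* The photometry generator's motion artifact is spectrally stationary;
  real artifacts are impulsive and wavelength-dependent.
* `unit_quality()` assumes multivariate-normal cluster features, the
  standard assumption behind both metrics.
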