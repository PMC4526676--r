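---
title: "Models and methods behind ultracoll"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ultracoll}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ultracoll)
```

## The scientific question

Mice vocalize at high ultrasonic frequencies (their communication calls
carry a single frequency component confined to roughly 60–90 kHz), yet
their hearing is most sensitive between 15 and 25 kHz. ultracoll
implements the complete analysis chain used to ask where along the
ascending auditory pathway these calls become well represented: from raw
extracellular voltage and auditory brainstem response (ABR) sweeps,
through spike sorting and per-unit response metrics, to the
population-level statistic of interest — the fraction of units at each
station (auditory nerve, AN; dorsal cochlear nucleus, DCN; central
nucleus of the inferior colliculus, ICC) that respond significantly to a
battery of nine vocalizations, with bootstrap confidence intervals.

Because the original recordings are not deposited, the package pairs
every analysis stage with a synthetic-data generator that produces
stimuli, spike trains, extracellular traces and ABR sweep sets with
known ground truth. Every stage is therefore testable end to end: the
pipeline must recover, from simulated raw data, the parameters the
generator put in.

## Pipeline stages and their models

### Preprocessing

Spike-band filtering is a 4th-order Butterworth band-pass (500–5000 Hz)
applied forward and backward (`signal::filtfilt`), so no phase delay
contaminates latency measurements. Candidate spikes are threshold
crossings of |signal| at `threshold_sd` (default 4) times a robust noise
SD, `median(|x|)/0.6745`, with a 0.7 ms dead time that keeps the earlier
of two close crossings. Snippets span 0.4 ms before to 0.8 ms after the
trigger.

Two refinements matter in practice. First, snippets are re-centered on
the waveform extremum within the dead time of the crossing: the
zero-phase filter's symmetric pre-ripple fires the threshold a fraction
of a millisecond early on some spikes, and without re-centering one
unit's snippets split into several apparent waveform families. Second,
the extremum is localized to sub-sample precision by parabolic
interpolation and the snippet is resampled on the shifted grid;
otherwise a peak falling between two samples flips the discrete argmax
and again splits the cluster. Both are standard practice in sorting
pipelines and can be disabled (`align = FALSE`) for the bare
threshold-crossing behavior.

The analog multi-unit activity (aMUA) envelope used for the
multi-electrode stations is the parameter-free chain: band-pass
300–6000 Hz, full-wave rectify, low-pass below 300 Hz (undershoot
clipped at zero). It is linear in input gain and invariant to sign
flips; a sinusoid of amplitude A inside the band settles at 2A/π.

### Spike sorting

Snippets are projected onto the first three principal components of the
snippet covariance (SVD route, component signs fixed so the
largest-magnitude loading is positive). Clustering is Gaussian-mixture
EM with BIC model selection over 1..`max_clusters` components
(delegated to `mclust`, whose hierarchical initialization makes the fit
deterministic); snippets with maximum posterior responsibility below
0.5 stay unassigned and count as non-members downstream.

Cluster quality is the isolation distance: with $n$ the cluster size,
the squared Mahalanobis distance — under the cluster's own mean and
covariance — of the $n$-th closest non-member. Only clusters with
isolation distance strictly greater than 20 are accepted as single
units; undefined values (fewer non-members than members) are rejected.
The implementation is checked against a brute-force
compute-all-distances-and-sort oracle to 1e-10.

### Per-unit metrics and the fiber gate

For repeated presentations of a unit's CF tone the package computes:

* the PSTH (per-bin rate = count / (trials × bin width); the
  conservation identity `sum(rate) * bin_width * n_trials = total
  spikes` holds exactly);
* the ISI CV — SD/mean of interspike intervals pooled *within* trials
  (an interval spanning a trial boundary is not an ISI), sample SD with
  the n−1 denominator;
* the first-spike-latency (FSL) mode — 0.5 ms histogram bins over
  (0, 30] ms, earliest bin on ties;
* a deterministic surrogate for visual PSTH typing into primary,
  chopper, pri-N and onset shapes.

A unit passes the auditory-nerve-fiber gate iff CV ≥ 0.5 (inclusive),
FSL mode ≤ 5 ms (inclusive) and the PSTH is primary-like.

Two classification rules deserve comment. Chopping is detected from the
autocorrelation of the early (first 25 ms) response, but only when the
autocorrelation *dips and rebounds* to a local peak: a smooth adapting
decay also has high low-lag autocorrelation yet never rebounds, and a
naive "dominant non-zero lag" rule mislabels primaries as choppers. The
pri-N notch is judged against the mean rate 2–4 ms *after* the dip:
recovery after the dip distinguishes a notch from the monotone decay of
the onset transient, which would pass through any absolute dip
threshold.

### Frequency response areas, CF and F_max

FRAs are built from 50 ms tone pips spanning 2–90 kHz in 0.2 (or 0.15)
octave steps and 15–100 dB SPL in 5 dB steps. A cell's value is the
mean over repetitions of (evoked − baseline) rate, with the evoked
window (0, duration + 10] ms and the baseline the 50 ms before each
onset. Per-frequency threshold is the lowest level whose cell is
significantly above baseline — a one-sided t test at α when a cell has
five or more repetitions, a 2-SD criterion (Poisson-based null
variance) below that — and which stays significant at the next two
levels (a contiguity requirement that suppresses isolated
false-positive cells). CF is the frequency of minimal threshold; ties
resolve to the grid frequency nearest the geometric mean of the tied
frequencies.

F_max — the highest frequency whose tone responses significantly exceed
spontaneous activity — pools driven counts across all levels at each
frequency and compares them to pooled equal-duration pre-onset counts
with a one-sided Wilcoxon rank-sum test. Because F_max is the *highest*
of a few dozen per-frequency tests, the p-values are Holm-corrected
across the grid before thresholding at α = 0.05: without familywise
control, a 28-frequency grid hands a spurious F_max to roughly
three-quarters of purely spontaneous units, which contradicts the
statistic's meaning. Strong responses (p ≪ α/28) are unaffected.

### Vocalization responsiveness and the SNR

For each of the nine calls, per-trial driven counts (window = call
duration, shifted 5 ms for neural latency) are compared to equal-length
spontaneous counts immediately before onset with a two-sided Wilcoxon
rank-sum test. The test is exact (null permutation distribution) when
both samples have ≤ 10 observations and no ties, and uses the normal
approximation with tie and continuity corrections otherwise — count
data are heavily tied, so the corrected approximation is the practical
path, and its type-I error is verified by simulation to sit near the
nominal 5%. A unit is *responsive* when at least 3 of the 9 calls are
significant at p < 0.05 (strict).

Response strength is the SNR: the variance across time bins of the
PSTH divided by the mean over trials of the variance of each trial's
deviation from the PSTH (population variances, 2 ms bins over the
driven window). It is invariant to adding a constant and to positive
rescaling; a perfectly repeatable response is flagged infinite and
excluded from the per-unit mean across calls.

### ABR quantification

Sweep sets (500 repeats, 25 kHz sampling) are artifact-rejected (peak
|amplitude| above 5× the median per-sweep SD), averaged, and band-passed
100–3000 Hz zero-phase; by linearity the filtered average equals the
average of filtered sweeps, at a 500th of the cost. Odd/even split-half
averages are kept for repeatability checks.

Wave V is the local maximum nearest 5.7 ms within 4.5–7.0 ms; its
amplitude is the peak minus the nearest antecedent trough. Wave I is
the earliest peak in 0.8–2.8 ms (minimal neural latency plus the
cochlear travelling-wave delay range) that (a) exceeds 6× the record's
noise floor — estimated from the split-half difference,
`sd(half1 − half2)/2`, which is blind to evoked signal — and (b) has a
matching local maximum within 0.5 ms in both split halves. The
multiplier was calibrated by null simulation: with latency agreement
alone, band-limited noise produces dense local maxima and a "wave" is
falsely detected in about a quarter of noise-only records; at 6× the
false-detection rate is below 2%.

The objective threshold replaces visual judgement: a record is
supra-threshold when its wave-V amplitude exceeds 2× the noise floor
(SD of the 8–10 ms tail), and the threshold is the lowest level
supra-threshold with all higher levels also supra-threshold.

### Population summaries

The responsive fraction carries a percentile bootstrap CI (2.5th/97.5th
percentiles, linear interpolation between order statistics, 10,000
resamples by default). Unit-level resampling draws units with
replacement; animal-level resampling draws animals with replacement and
takes all their units, which widens the interval when responsiveness is
clustered by animal. Both modes are implemented; note that an
animal-level interval is only meaningful when the real per-animal
breakdown is available — applied to marginal counts with a fabricated
balanced assignment it collapses, so summaries built from counts alone
should use unit-level resampling. CF distributions are summarized in
1/3-octave histograms, and across-group comparisons (CFs across
animals on a log2 scale, wave amplitudes across frequencies) use
one-way fixed-effects ANOVA via `stats::aov`.

## The synthetic-data generator

The generator is first-class, tested code; its defaults encode the
recording protocol (50 ms tone pips with 2 ms raised-cosine ramps every
150 ms; the 2–90 kHz × 15–100 dB grid; nine 30–60 ms calls at 80 or
90 dB SPL presented 256 times each; 500 ABR sweeps at 25 kHz; stimulus
audio at 192 kHz with 94 dB SPL ≡ full scale).

**Response area.** A neuron responds to a tone at level $L$ when its
octave distance $d$ from CF satisfies
$d < w(L) = \min(q \cdot (L - \theta)/10,\ w_{\max})$, with threshold
$\theta$, sharpness $q$ (octaves of half-width per 10 dB; default 0.12,
i.e. steep flanks typical of sharp peripheral tuning) and a hard cap
$w_{\max}$ (default 0.5 octaves). The driven excess scales as
$(1 - d/w(L)) \cdot \min(1, (L-\theta)/30)$ — rising over the first
30 dB above threshold, then saturating. The cap keeps the response area
bounded at high levels; it is also what makes call responsiveness a
clean function of CF (a unit below ~42 kHz can never reach the 60–90
kHz call band), so the generator's `fraction_high_f` parameter controls
the ground-truth responsive fraction exactly. Real FRAs have low-side
tails this shape omits — passing tests show the pipeline recovers this
model's tuning, not that mouse FRAs are symmetric V's.

**Spiking.** Spike trains are time-rescaled gamma-renewal processes:
ISIs are gamma with shape $k$ and unit mean in integrated-rate time, so
a long stationary train has ISI CV $1/\sqrt{k}$ ($k=1$ is Poisson). An
absolute refractory period is enforced as a hard dead time. PSTH
classes shape the peristimulus time course: primary-like responses are
an exponential adaptation to a 35% plateau plus a 2.5× onset transient
(τ = 1.5 ms) — the transient is physiological (onset rates of several
hundred Hz) and necessary for the first spike to arrive promptly enough
that the measured FSL mode tracks the generator's nominal latency;
pri-N multiplies in a Gaussian notch at 4 ms; choppers modulate a
plateau at a 4 ms period (with high $k$, hence regular firing); onset
responses decay with τ = 1.5 ms. Class FSL distributions are drawn
apart from the 5 ms gate boundary (primaries 2.5–4.2 ms, CN-like
classes 4.5–8 ms), mirroring the bimodal separation the classification
criterion presumes; borderline-latency units would be genuinely
ambiguous for any criterion.

**Populations.** CFs come from a two-part mixture: a fraction
`fraction_high_f` uniform in log-frequency inside the call band
(62–88 kHz), the rest log-normal truncated to 2–42 kHz with the
station's mode (geometric mean 25 kHz for AN/DCN; 30 kHz with a wider
spread for ICC, whose overall mode then sits above 40 kHz because of
the large high-frequency fraction). Station profiles default to the
recorded sample sizes (94 fibers / 23 animals; 1248 sites / 8 animals;
696 sites / 5 animals) with high-frequency fractions 7/94, 118/1248 and
409/696. Ground-truth `responds_to_calls` is re-derived from the
response-area predicate (≥ 3 of the 9 calls' trajectories enter the
response area at the call level), never stored independently, so labels
are consistent with the generating model by construction.

**Traces and ABRs.** Extracellular traces are spike trains convolved
with ~1.2 ms biphasic templates plus white Gaussian noise. ABR sweeps
are sums of five biphasic bumps (difference of two Gaussians, trough
0.5 ms before peak, normalized so peak-minus-antecedent-trough is
exactly the nominal amplitude) at latencies 1.2/2.1/3.0/4.2/5.7 ms,
plus 2 µV white noise per sweep. The wave-I map falls with frequency
(1.2 → 0.3 µV from 8 to 80 kHz) and the wave-V map rises (0.3 →
1.2 µV); the paper-style pattern is the *ordering*, the absolute values
are design choices kept above the averaged-record detection criterion,
as the real waves were measurable at every tested frequency.

**What the generator does not emulate:** pinna spectral notches,
low-frequency FRA tails and inhibitory sidebands, multi-modal FRAs of
IC subnuclei, electrode drift, overlapping-spike waveform addition
beyond linear superposition, cochlear distortions, and any
call-spectrum structure beyond a single log-linear FM component.
Passing tests therefore validate the analysis chain, not these aspects
of real data.

## Numerical choices and degenerate inputs

* Time is milliseconds on one session clock; frequencies kHz; levels
  dB SPL; analysis windows are relative to event onsets.
* Wilcoxon: exact only for untied samples with both n ≤ 10; elsewhere
  normal approximation with tie and continuity corrections; identical
  samples give p = 1 (the tie-corrected variance is 0).
* Isolation distance regularizes a singular cluster covariance by
  adding 1e-9 × trace/3 to the diagonal, with a warning.
* `estimate_cf` reports undefined tuning (NA) when no cell passes the
  contiguity-checked significance criterion; `estimate_fmax` reports NA
  when no frequency survives Holm; responsiveness with fewer than nine
  calls scales the criterion to ⌈n/3⌉ with a warning; infinite SNRs are
  excluded from means with a logged count.
* Bootstrap CIs use `quantile(..., type = 7)` (linear interpolation
  between order statistics); degenerate all-true/all-false inputs give
  zero-width intervals.
* Reported percentages round to the nearest integer.

## Problem sizes used by the tests and acceptance script

Simulations are sized for desk-scale runs while keeping every statistic
in its asymptotic regime: renewal-CV checks use ~10,000-spike trains;
CF recovery uses 100 units on the 0.2-octave grid with 2 repetitions
per cell; the fiber-gate validation uses 40 mixed-class units with 200
CF-tone repetitions; end-to-end responsiveness uses an AN-like
population of 94 units and an ICC-like population of 200 units with the
protocol's 256 presentations per call; bootstrap coverage uses 500
Bernoulli replicates at n = 94 and 696; ABR checks use 500-sweep
records and five simulated animals. The full recorded ICC population
(696 sites) runs the same code path; only the unit count differs.

## Known limitations

* The clusterer can oversplit large, slightly non-Gaussian snippet
  clouds (BIC favors extra components); the isolation-distance gate
  rejects most fragments but accepted duplicates of one unit are
  possible, as with any mixture-based sorter.
* The rank-sum responsiveness test detects rate changes only; a unit
  reorganizing spike timing at constant count would be missed (the SNR
  would still rise).
* The visual PSTH typing of the original workflow is replaced by
  deterministic rules with config-exposed thresholds; classes outside
  the four canonical shapes come back "unclassified".
* Animal-level bootstrap intervals require the real per-animal
  composition; from marginal counts alone only unit-level intervals are
  meaningful.
* The ABR threshold criterion (2× noise floor) is an objective
  surrogate for visual scoring; absolute thresholds shift with the
  multiplier, which is exposed in the interface.
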