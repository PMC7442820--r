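---
title: "Models, metrics and design choices in songnerve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, metrics and design choices in songnerve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the choices made
where the design was genuinely open. It states no empirical result that
the test suite and the analysis scripts do not themselves compute.

## The problem

Chronic interfaces on small peripheral nerves — here the songbird
tracheosyringeal nerve (nXIIts), the motor nerve of the vocal organ — are
evaluated along four axes: (1) does the implant leave the behavior
(song) intact; (2) are the recorded signals nerve activity rather than
movement or EMG artifact, and are they stable over weeks; (3) can graded
stimulation evoke compound responses; (4) can spatially patterned
("current-steered") stimulation produce reproducibly distinct motor
outputs. Each axis has a quantitative pipeline in this package.

## Acoustic features

Each vocal element is reduced to five feature tracks computed in 10 ms
windows advancing in 1 ms steps, one estimate per millisecond (segment
edges are reflect-padded so the track length equals the segment length in
milliseconds). The features follow the conventions of the established
song-analysis tooling this literature builds on:

* **sound envelope** — total log power in 0.3–8 kHz, dB. Shifts by exactly
  20·log10(g) under waveform gain g.
* **Wiener entropy** — log(geometric mean / arithmetic mean) of the band
  power spectrum; ≤ 0 always, ~0 for white noise, strongly negative for
  tones; gain-invariant.
* **pitch** — autocorrelation fundamental estimator over 0.3–8 kHz with
  parabolic peak interpolation; frames whose periodicity confidence
  (normalized autocorrelation peak) falls below 0.2 are flagged unvoiced
  and excluded from pitch statistics.
* **AM** — relative time-derivative of band power (1/s); gain-invariant.
* **FM** — arctangent of the spectral-centroid velocity normalized by
  50 kHz/s (rad); gain-invariant.

The gain invariances matter because the similarity scale below must not
depend on recording gain: four of the five features are exactly invariant
and the envelope's additive dB shift is absorbed by the z-scoring center.

## The similarity score and its null

Two feature tracks are compared frame-by-frame in the five-dimensional
feature space after z-scoring each feature by the pooled mean/SD of the
null songs. The median frame distance is converted to a P value against
the empirical distribution of median distances among 20 unrelated songs
(190 pairwise values): `similarity = 1 − ECDF(median distance)`. A score
of 1 means acoustically identical; 0 means as different as two unrelated
songs; under the null the score is uniform on [0, 1] up to the null's own
sampling error.

Two design points were genuinely open:

* **Which frame pairs enter the median.** "Millisecond-by-millisecond
  comparisons" can mean time-indexed pairs (frame i with frame i) or the
  full Cartesian product. The package defaults to time-indexed pairing
  because it is the only reading under which an identical pair has median
  distance 0 — i.e., under which "a score of 1 means identical" holds
  exactly. The Cartesian reading is available via `pairing = "cartesian"`
  in `build_null()`.
* **What one null distance is.** The null stores one median distance per
  unrelated song *pair* (190 values for 20 songs), not a pool of raw
  frame distances. Only the per-pair-median construction makes the score
  an exact P value of the statistic actually computed, which is what
  produces the uniform-under-null behavior the test suite checks
  (Kolmogorov–Smirnov distance of 500 fresh unrelated-pair scores to
  Uniform(0,1) below 0.1).

Unvoiced frames drop the pitch dimension for that pair; the remaining
4-feature distance is rescaled by √(5/4) to stay on the same scale.
The null's unit of comparison should match the unit being scored: a null
built from whole-song tracks calibrates whole-song comparisons, one built
from syllable tracks calibrates syllable comparisons (the nerve-function
assay in `analysis/02` does the latter).

With a 20-song null the score lattice has 191 levels and the null ECDF
itself carries sampling error of order 0.06–0.1 in Kolmogorov–Smirnov
distance (190 dependent pair medians from 20 songs); the uniformity check
is expected to sit near its 0.1 bound and is inherently seed-sensitive at
this null size.

## Song detection, segmentation, annotation

Detection emulates song-triggered acquisition: a frame is "song" when
periodogram power in 2.5–8 kHz exceeds 10–50× (default 20×) the power in
50–250 Hz; runs are extended 1.5 s past song offset. The statistic is a
power ratio, so detection is amplitude-scale invariant. Frame length
(10 ms, 5 ms hop, Hann) is a package choice.

Segmentation thresholds the rectified waveform smoothed with a 2 ms
boxcar; runs shorter than 10 ms are dropped and gaps shorter than 5 ms
merged. The threshold level (default 10% of the envelope maximum) is a
package choice exposed in the interface; raising it can only shrink the
segmented time.

Annotation renders each segment as a fixed 5000-element log-spectrogram
grid (50 time × 100 frequency) and classifies it with a small multilayer
perceptron after PCA compression (40 components), reporting held-out
accuracy on a stratified split. The 5000-element input grid preserves the
stated input dimensionality of the original semi-automated annotator; the
hidden layer is reduced to 20 units and a PCA front end added because the
synthetic 3-class task does not need ~500k parameters — the contract is
label assignment plus a held-out accuracy estimate, not an architecture.

## ENG preprocessing and alignment

Common-mode subtraction removes the per-sample across-channel mean: all
electrodes on one device share the same biomechanical/electrochemical
artifact up to gain, so an equal-gain shared component cancels exactly
(rank-1 removal; linear and idempotent, hence commutes with filtering).
Band-pass is a zero-phase (forward–backward) two-pole Butterworth,
0.3–6 kHz. Envelopes are the squared signal smoothed with a boxcar — 5 ms
for every quantitative analysis, 20 ms for display-scale traces — and the
channel-combined envelope is the mean across channels.

Motif alignment uses dynamic time warping over log-spectrogram frames
(10 ms window, 1 ms hop, 0.3–8 kHz band) with Euclidean frame cost, a
Sakoe–Chiba band of ±100 ms, and the slope-constrained symmetric P = 1
step pattern (moves (1,1), (2,1), (1,2); local slope within [1/2, 2]).
The slope constraint is load-bearing: with unconstrained steps,
quasi-stationary stretches of a syllable can collapse onto single frames
(the cost surface is nearly flat there), producing degenerate warps; the
P = 1 pattern forbids this while comfortably covering the ~±25% tempo
variation of interest. The warp is transferred to neural traces as a
piecewise-linear time map interpolated from the frame-level path, applied
by resampling, with no premotor time shift. The template defaults to the
medoid rendition (minimum summed DTW cost).

## Stability metrics

Per motif: Vpp = max − min of the processed voltage; SNR =
10·log10(RMS_singing / RMS_noise) — an RMS ratio, not a power ratio —
against 500 ms of vocalization-free recording from the triggered-capture
post-roll; event rate = upward crossings of a per-motif threshold at
mean + 5 SD of the singing envelope (crossing at sample i means
env[i−1] < θ ≤ env[i], with a one-smoothing-window refractory period),
divided by the unwarped motif duration. The per-motif SD uses the
smoothed envelope (configurable). Envelope correlation is Pearson
correlation to the day-1 mean envelope; day-1 records are correlated
against the leave-one-out day-1 mean so no record contributes to its own
reference — with few motifs per day an in-sample reference inflates day-1
correlations and masquerades as later drift.

The zero-correlation reference band for on/off-nerve comparisons is a
bootstrap CI over circularly time-shifted envelope pairs, which preserves
each envelope's autocorrelation while destroying any true coupling.

Day-level inference uses the field's conventional comparisons: two-tailed paired
t-tests of days 10/20/30 against day 1 for each of the four metrics. The
package's stationarity check applies a Holm correction across those 12
comparisons; uncorrected, twelve 5%-level tests on a truly stationary
recording would flag something spurious in roughly half of all runs.

## Evoked responses

Trials span −5 to +25 ms around stimulation at 24.4 kS/s. The artifact
onset (first sample near t = 0 exceeding 8 robust SDs of the pre-stimulus
baseline) aligns trials; artifact-free trials are flagged and excluded.
Response metrics use the 0.75–4 ms window (consistent with conduction
latencies of small myelinated axons at these distances) against the
10.75–14 ms noise window, on the 20-trial mean trace.

Detection: bootstrap-CI detection rules are stated ambiguously across
this literature — the CI can be of the null statistic or of the observed
one. The default here builds a null distribution of
the SNR statistic by resampling both windows from the noise interval
(10 000 resamples) and detects when the observed SNR exceeds the upper
limit of the two-sided 90% CI — a one-sided exceedance, hence a nominal
5% false-positive rate, which the test suite verifies by Monte-Carlo
(200 null datasets; the calibration run uses 2000 resamples per dataset,
which changes only the quantile estimate's jitter, not the nominal
level). The alternative reading — bootstrap CI of the observed SNR,
detection when its lower limit exceeds 0 dB — is available via
`convention = "ci_of_observed"`.

Recruitment curves fit Vpp(I) = baseline + vmax/(1 + exp(−(I − i50)/slope))
by Levenberg–Marquardt least squares on per-current trial-mean Vpp. The
threshold current is operational — the smallest tested current at which
bootstrap detection fires — and is reported as censored beyond the
largest tested current when nothing fires. Because the sigmoid never
reaches zero, the operational threshold falls with trial count; at high n
even the I = 0 tail response is detectable on synthetic data.

Condition comparisons (baseline/saline/lidocaine/washout) normalize
per-subject amplitudes to the baseline mean, run a repeated-measures
ANOVA on subject-by-condition means with Mauchly's sphericity test where
the covariance permits (at n = 3 subjects it is singular and sphericity
is untestable — the Huynh–Feldt correction is then applied
unconditionally), and Dunnett contrasts against the control condition.

## Stimulation specificity

Current-steering patterns assign each site of the 2 × 3 electrode grid a
role (cathodic-leading source, anodic-leading source, return, off) with
charge-balanced biphasic pulses (1 kHz bursts of 100 pulses, 200 µs per
phase) and constant total current across a pattern set. Fictive
vocalizations are vectorized as log-magnitude spectrograms of the 200 ms
from stimulation onset (5 ms window, 1 ms advance, 512-point transform);
rows above 8 kHz are discarded. Several bin-selection rules are
consistent with an 8 kHz cutoff; the package keeps non-DC bins whose
full band stays at or below 8 kHz, which yields exactly 91 bins
(86–7847 Hz) at 44 150 Hz and hence the 200 × 91 → 18 200 vector shape. Embedding is PCA to 50 components followed by exact
(non-approximate) t-SNE with Euclidean distances and perplexity 35,
initialized from the first two principal components scaled small, so a
fixed seed reproduces the embedding bit for bit. The t-SNE implementation
is the package's own (binary-search bandwidths, early exaggeration 12 for
100 iterations, momentum 0.5→0.8, 500 iterations) — adequate for the
few-hundred-point sets this analysis embeds. Cluster recovery is
summarized by 5-nearest-neighbor label purity and mean silhouette.

## The synthetic-data generator

The generator defines the study conditions under which everything above
is validated. What it emulates, and how:

* **Song**: syllables are harmonic stacks (8 partials, geometric
  roll-off) with a time-varying fundamental, 30 Hz vibrato of
  configurable depth, sinusoidal amplitude modulation, and band-limited
  noise mixed in to set the Wiener-entropy regime — one independent handle
  per acoustic feature. Motifs are highly stereotyped: per-rendition
  multiplicative jitter of 3% SD on duration, pitch and amplitude.
  Unrelated birds draw independent parameters (durations 60–180 ms,
  fundamentals 0.5–2.5 kHz, entropy −6 to −1.5), chosen to span the
  natural diversity of adult song syllables.
* **Nerve activity**: each channel draws an inhomogeneous Poisson event
  train (peak 400 events/s during singing, 2/s otherwise) whose rate
  follows a smooth motif-locked envelope template, convolved with a
  biphasic (Gaussian-derivative, ~0.25 ms) spike kernel at 40 µV scale.
  Channels sample overlapping but distinct fiber populations —
  independent trains from the shared rate profile — so envelopes co-vary
  across channels while the raw traces are not collinear (and
  common-mode subtraction cannot cancel the signal). Compound population
  bursts locked to eight fixed motif phases (±3 ms per-rendition jitter,
  10% drop rate, 2.5× amplitude and 8× rate over ~4 ms) give the envelope
  the repeatable large excursions that the 5 SD event-rate metric counts;
  without them the metric is degenerately zero on smooth-envelope data.
  The amplitude scale was set once so that singing Vpp lands in the
  hundreds-of-microvolts regime reported for chronic recordings.
* **Artifact**: a single band-limited (10–500 Hz) stochastic process
  shared across channels with per-channel gain — rank-1 by construction,
  verifiable by SVD — mimicking movement/EMG invasion; plus independent
  Gaussian noise (8 µV SD). An off-nerve model has zero coupling to the
  envelope template (artifact + noise only).
* **Evoked trials**: a large biphasic artifact in 0–0.5 ms, a compound
  response (Gaussian-windowed biphasic cycle, unit-Vpp-normalized) in the
  0.75–4 ms latency span with amplitude vmax/(1 + exp(−(I − i50)/slope)),
  white noise, and optional per-trial onset jitter for alignment tests.
* **Fictive vocalizations**: each stimulation pattern maps
  deterministically to its own syllable specification; `mapping_spread`
  scales the dispersion of pattern-specific parameters around a common
  base syllable (0 collapses all patterns to one output), and renditions
  add 2% jitter plus a microphone noise floor.

What it does **not** emulate: biophysical nerve-fiber recruitment, syrinx
biomechanics, realistic EMG spectra, electrode impedance drift, or any
day-dependence — the chronic dataset is stationary by construction, so
passing stability checks demonstrates that the pipeline does not
manufacture spurious drift, not that real implants are stable. Likewise
the spike waveform shape is a free choice (no quantitative description of
nXIIts single units was available), so absolute Vpp/SNR values are
regime-matched, not calibrated.

## Problem sizes and numerical choices

The validation suite uses: a 20-song null (190 pair medians); 500 fresh
unrelated pairs (from 100 fresh birds) for the uniformity check; 200 null
datasets of 20 trials for detection calibration (2000 resamples each);
8 currents × 20 trials for recruitment recovery; 24 patterns × 20 trials
for specificity; and 30 days × 4 motifs for the stability run. These
sizes make the full suite run in a few minutes while keeping every check
statistically meaningful; the analysis scripts use the same sizes.

Ties and degeneracies: ECDF ties count as ≤ (so a zero-distance null
would collapse scores and is flagged with a warning); DTW ties prefer the
diagonal move; zero-variance envelope windows are flagged, not dropped;
unvoiced-only tracks flag the pitch summary absent rather than inventing
values; warp spans tolerate 10 ms of boundary rounding before erroring.

## Known limitations

* The similarity score's null has only 190 support points with a 20-song
  null; scores are discrete at ~0.005 resolution and the scale's own
  calibration error is of order 0.1 — more unrelated songs sharpen it.
* DTW alignment accuracy within quasi-stationary syllable interiors is
  limited by the data itself (~2–5 ms typical map error on synthetic
  song); envelope-level conclusions are robust to this, sample-level ones
  are not.
* The exact t-SNE is O(n²) per iteration and intended for at most a few
  thousand points.
* The RM-ANOVA path targets the small-n designs of this literature
  (3–6 subjects); with singular covariances it reports sphericity as
  untestable and corrects unconditionally rather than failing.
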