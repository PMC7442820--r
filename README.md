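# songnerve

Analysis pipeline for chronic peripheral-nerve-interface experiments in
singing birds: vocal behavior quantification, electroneurogram (ENG)
processing, stimulation-evoked response analysis, and current-steering
stimulation specificity — together with a seed-deterministic synthetic-data
generator that emulates the statistical structure of such recordings, so
the whole chain can be exercised and validated without animal data.

## Who this is for

Labs recording from (and stimulating) the songbird tracheosyringeal nerve
(nXIIts) — or any small peripheral nerve — with chronic multichannel
interfaces, who need a reproducible path from raw audio + voltage traces to
the standard figures: song-aligned activity envelopes, longitudinal
stability metrics, recruitment curves, and stimulation-specificity
summaries.

## The statistics at the core

**Acoustic similarity score.** Every vocal element is represented by five
acoustic features computed in 10 ms windows advancing 1 ms (pitch,
frequency modulation, amplitude modulation, Wiener entropy, sound
envelope). Two elements are compared by millisecond-wise distances in the
z-scored five-dimensional feature space; the median distance d is converted
into a P value against the empirical cumulative distribution F of median
distances among 20 unrelated songs:

    similarity(a, b) = 1 − F(d(a, b))

so 1 means acoustically identical and 0 means as different as unrelated
songs. Under the null (unrelated pair), the score is uniform on [0, 1].

**ENG processing.** Common-mode subtraction (per-sample across-channel
mean) cancels the shared movement/electrochemical artifact; zero-phase
two-pole Butterworth band-pass (0.3–6 kHz); motifs are aligned to a common
template by slope-constrained dynamic time warping of log-spectrogram
frames and the warp is transferred to the voltage traces; envelopes are the
squared signal smoothed with a 5 ms boxcar (20 ms for display).

**Stability metrics.** Per motif: Pearson correlation of the song-aligned
envelope to the day-1 mean, peak-to-peak voltage, SNR =
10·log10(RMS_singing / RMS_noise), and the rate of envelope crossings of a
per-motif threshold at mean + 5 SD.

**Evoked responses.** Trials aligned on the stimulation-artifact onset;
response quantified 0.75–4 ms post-stimulus against a 10.75–14 ms noise
window; detection when the observed SNR exceeds the upper bound of a
bootstrap 90% CI of the null statistic (10 000 resamples of the noise
window); recruitment fit Vpp(I) = baseline + vmax / (1 + exp(−(I − i50)/slope)).

**Specificity.** Within- vs across-pattern acoustic similarity of fictive
vocalizations, and a 2-D embedding of their 200 × 91 log-spectrograms
(18 200-dimension vectors, PCA to 50, exact t-SNE at perplexity 35).

## Worked example

```r
library(songnerve)

bird <- bird_spec("demo", seed = 1)          # stereotyped 3-syllable motif
song <- make_song(bird, n_motifs = 2, seed = 1)
segment_syllables(song$clip)[, 1:2]
#>       onset    offset
#> 1 0.1004077 0.1899207
#> 2 0.2312118 0.3902378
#> 3 0.4314609 0.5188448
#> ...                         # six segments, within 5 ms of ground truth

rec  <- make_nerve_recording(song$annotations, nerve_model(), seed = 1)
proc <- bandpass_filter(common_mode_subtract(rec))
motif_vpp(proc$voltages[1, ])
#> ~600                        # singing Vpp in microvolts

m      <- evoked_model(vmax = 300, i50 = 20, slope = 5)
trials <- make_evoked_trials(m, c(0, 5, 10, 15, 20, 25, 30, 40), 20, seed = 1)
fit    <- recruitment_curve(trials)
c(fit$i50, fit$vmax)
#> 20.2 297.0                  # generator used i50 = 20 uA, vmax = 300 uV
```

The numbers printed by the full analysis (the `analysis/` scripts below)
include: classifier held-out accuracy 100% on three clean synthetic
syllable classes; self-similarity exactly 1; within-pattern similarity
0.90 vs across-pattern 0.33 over 24 steering patterns; 5-nearest-neighbor
pattern purity 1.00 in the t-SNE embedding; and no significant drift in
any of the four daily stability metrics over 30 synthetic days.

## Analysis workflow

The study chain is organized as numbered drivers over the package, each
writing its tables under `results/`:

    analysis/01_synthesize_data.R        study design + synthetic subjects
    analysis/02_song_behavior.R          detection, segmentation, annotation,
                                         similarity null, nerve-function assay
    analysis/03_chronic_stability.R      30-day stability + on/off-nerve control
    analysis/04_evoked_responses.R       alignment, detection, recruitment,
                                         lidocaine/saline/washout comparison
    analysis/05_stimulation_specificity.R  within/across similarity + embedding

Run them in order with `Rscript analysis/01_synthesize_data.R` etc.

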