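Package: songnerve
Title: Vocal Behavior and Chronic Nerve-Interface Signal Analysis for Songbirds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for chronic peripheral-nerve-interface
    experiments in singing birds. Provides song-triggered detection and
    amplitude-threshold syllable segmentation, five-feature acoustic
    quantification (pitch, frequency and amplitude modulation, Wiener
    entropy, sound envelope) at millisecond resolution, an acoustic
    similarity statistic referenced to an empirical null of unrelated
    songs, electroneurogram preprocessing (common-mode subtraction,
    zero-phase band-pass filtering, envelope extraction) with dynamic
    time warping of motifs and warp transfer to neural traces,
    longitudinal stability metrics (envelope correlation, peak-to-peak
    voltage, SNR, event rate), stimulation-evoked response detection by
    bootstrap with sigmoidal recruitment-curve fitting, current-steering
    specificity analysis with spectrogram vectorization, PCA and t-SNE
    embedding, and a seed-deterministic synthetic-data generator that
    emulates the statistical structure of the recordings so that every
    stage can be exercised without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    nnet,
    multcomp,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
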