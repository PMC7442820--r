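#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data all later stages analyze.
# One "subject" bird with a stereotyped 3-syllable motif, a chronic
# 6-channel nerve-recording model (on-nerve and off-nerve), a graded
# stimulation model, and 24 current-steering patterns. Everything is
# seed-deterministic; later stages regenerate what they need from the
# same seeds, so this stage only records the study design.

suppressPackageStartupMessages(library(songnerve))
dir.create("results", showWarnings = FALSE)

seed <- 1
bird <- bird_spec("subject-1", seed = seed)
song <- make_song(bird, n_motifs = 5, seed = seed)

cat("Synthesized", nrow(song$annotations), "syllables over",
    sprintf("%.2f s of audio at %g Hz\n",
            clip_duration(song$clip), song$clip$rate))
utils::write.csv(song$annotations, "results/01_song_annotations.csv",
                 row.names = FALSE)

syl <- do.call(rbind, lapply(seq_along(bird$syllable_params), function(i) {
  sp <- bird$syllable_params[[i]]
  data.frame(syllable = paste0("s", i), duration_s = sp$duration,
             pitch_start_hz = sp$pitch_traj[1],
             pitch_end_hz = sp$pitch_traj[length(sp$pitch_traj)],
             am_rate_hz = sp$am_rate, fm_depth_hz = sp$fm_depth,
             entropy_level = sp$entropy_level, amplitude = sp$amplitude)
}))
utils::write.csv(syl, "results/01_syllable_parameters.csv", row.names = FALSE)

rec <- make_nerve_recording(song$annotations, nerve_model(), seed = seed)
cat("Nerve recording:", nrow(rec$voltages), "channels,",
    sprintf("%.2f s at %g kS/s;", ncol(rec$voltages) / rec$rate,
            rec$rate / 1000),
    length(attr(rec, "event_times")), "events on channel 1\n")

pats <- make_steering_patterns(24, amplitude = 100)
stopifnot(validate_pattern(pats)$ok)
pat_tab <- do.call(rbind, lapply(pats, function(p)
  data.frame(pattern_id = p$pattern_id,
             roles = paste(p$roles, collapse = "|"),
             amplitude_uA = p$amplitude, pulses = p$pulses,
             pulse_rate_hz = p$pulse_rate, phase_width_us = p$phase_width)))
utils::write.csv(pat_tab, "results/01_steering_patterns.csv",
                 row.names = FALSE)
cat("Validated", length(pats),
    "steering patterns at constant 100 uA total current\n")
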