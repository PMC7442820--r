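test_that("detector triggers on song-band energy and ignores low-frequency tones", {
  rate <- 44150
  t <- seq(0, 1, by = 1 / rate)
  low <- audio_clip(0.5 * sin(2 * pi * 100 * t), rate)
  expect_equal(nrow(detect_song(low)), 0)
  silence <- audio_clip(rep(0, rate), rate)
  expect_equal(nrow(detect_song(silence)), 0)
  song <- audio_clip(0.3 * sin(2 * pi * 4000 * t) + 1e-4 * sin(2 * pi * 100 * t), rate)
  eps <- detect_song(song)
  expect_equal(nrow(eps), 1)
  expect_lt(eps$onset[1], 0.02)
})

test_that("detected episodes cover annotated syllables and include the post-roll", {
  s <- fx_song()
  eps <- detect_song(s$clip)
  ann <- s$annotations
  covered <- vapply(seq_len(nrow(ann)), function(i)
    any(eps$onset <= ann$onset[i] & eps$offset >= ann$offset[i]), logical(1))
  expect_gte(mean(covered), 0.99)
  # post-roll extends 1.5 s past the last syllable (clamped to clip end)
  expect_equal(max(eps$offset),
               min(clip_duration(s$clip), max(ann$offset) + 1.5),
               tolerance = 0.05)
})

test_that("detection is invariant to amplitude scaling", {
  s <- fx_song()
  eps1 <- detect_song(s$clip)
  scaled <- audio_clip(s$clip$samples * 7.3, s$clip$rate)
  expect_equal(detect_song(scaled), eps1)
})

test_that("detector configuration is validated", {
  expect_error(detector_config(ratio_threshold = 0.5), "ratio_threshold")
  expect_error(detector_config(song_band = c(100, 8000)), "overlap")
  clip <- audio_clip(rnorm(1000), 8000)
  expect_error(detect_song(clip, detector_config()), "Nyquist")
})

test_that("segmentation merges short gaps and drops short runs; thresholds are monotone", {
  s <- fx_song()
  segs <- segment_syllables(s$clip)
  # a min_gap larger than intersyllable gaps merges each motif into one run
  merged <- segment_syllables(s$clip, min_gap = 0.06)
  expect_equal(nrow(merged), 2)
  # silence yields no segments
  expect_equal(nrow(segment_syllables(audio_clip(rep(0, 44150), 44150))), 0)
  # raising the threshold never increases total segmented duration
  durs <- vapply(c(0.05, 0.1, 0.2, 0.4), function(thr) {
    sg <- segment_syllables(s$clip, threshold = thr)
    if (nrow(sg) == 0) 0 else sum(sg$offset - sg$onset)
  }, numeric(1))
  expect_true(all(diff(durs) <= 1e-12))
})

test_that("syllable classifier reaches high held-out accuracy on clean synthetic song", {
  b <- bird_spec("A", seed = 1)
  s <- make_song(b, 10, seed = 1)
  ann <- s$annotations
  train <- ann[ann$motif <= 7, c("onset", "offset", "label")]
  query <- ann[ann$motif > 7, c("onset", "offset")]
  res <- annotate_syllables(s$clip, query, train, seed = 1)
  expect_gt(res$holdout_accuracy, 0.95)
  expect_equal(res$segments$label, ann$label[ann$motif > 7])
  expect_length(res$classes, 3)
  # a query identical to a training exemplar receives its training label
  self <- annotate_syllables(s$clip, ann[1, c("onset", "offset")],
                             train, seed = 1)
  expect_equal(self$segments$label, ann$label[1])
})

test_that("classifier rejects degenerate training sets", {
  s <- fx_song()
  ann <- s$annotations
  one_class <- ann[ann$label == "s1", c("onset", "offset", "label")]
  expect_error(annotate_syllables(s$clip, ann[1, ], one_class), "classes")
  thin <- ann[c(1, 2, 3), c("onset", "offset", "label")]
  expect_error(annotate_syllables(s$clip, ann[1, ], thin), "exemplars")
})
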