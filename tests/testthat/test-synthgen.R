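test_that("song synthesis produces the annotated syllable count and is seed-deterministic", {
  b <- bird_spec("A", seed = 1)
  s <- make_song(b, 2, seed = 1)
  expect_equal(nrow(s$annotations), 2 * length(b$motif_order))
  expect_true(all(s$annotations$offset > s$annotations$onset))
  expect_equal(s$clip$rate, 44150)
  s2 <- make_song(b, 2, seed = 1)
  expect_identical(s$clip$samples, s2$clip$samples)
  expect_identical(s$annotations, s2$annotations)
  s3 <- make_song(b, 2, seed = 2)
  expect_false(identical(s$clip$samples, s3$clip$samples))
})

test_that("syllable spec validation rejects out-of-range parameters", {
  expect_error(syllable_spec(0.01, 1000), "duration")
  expect_error(syllable_spec(0.5, 1000), "duration")
  expect_error(syllable_spec(0.1, 100), "pitch")
  expect_error(syllable_spec(0.1, 9000), "pitch")
  expect_error(syllable_spec(0.1, 1000, entropy_level = 1), "entropy")
})

test_that("distinct birds are far less similar than renditions of one bird", {
  nl <- fx_null()
  sA <- make_song(bird_spec("farA", seed = 11), 1, seed = 21)
  sA2 <- make_song(bird_spec("farA", seed = 11), 1, seed = 22)
  sB <- make_song(bird_spec("farB", seed = 11), 1, seed = 21)
  tr <- function(s) compute_features(s$clip, s$annotations$onset[1],
                                     s$annotations$offset[3])
  same <- similarity(tr(sA), tr(sA2), nl$null)$value
  cross <- similarity(tr(sA), tr(sB), nl$null)$value
  # a bird's own renditions sit at the top of the similarity scale; an
  # unrelated pair scores like a draw from the null (strictly below)
  expect_gt(same, 0.95)
  expect_lt(cross, same - 0.2)
})

test_that("segmentation on clean synthetic song recovers annotated boundaries within 5 ms", {
  s <- fx_song()
  segs <- segment_syllables(s$clip)
  ann <- s$annotations
  expect_equal(nrow(segs), nrow(ann))
  matched <- sum(abs(segs$onset - ann$onset) < 0.005 &
                   abs(segs$offset - ann$offset) < 0.005)
  expect_gte(matched / nrow(ann), 0.95)
})

test_that("nerve recording honours degenerate and artifact-only models", {
  s <- fx_song()
  zero <- nerve_model(unit_rate_scale = 0, noise_sd = 0, artifact_gain = 0)
  r0 <- make_nerve_recording(s$annotations, zero, seed = 1)
  expect_true(all(r0$voltages == 0))
  # artifact-only output is rank 1 across channels
  art <- nerve_model(unit_rate_scale = 0, noise_sd = 0,
                     artifact_gain = c(10, 20, 30, 40, 50, 60))
  ra <- make_nerve_recording(s$annotations, art, seed = 2)
  sv <- svd(ra$voltages)$d
  expect_lt(sv[2] / sv[1], 1e-8)
  # equal artifact gains: CMS removes the artifact exactly
  eq <- nerve_model(unit_rate_scale = 0, noise_sd = 0, artifact_gain = 50)
  re <- make_nerve_recording(s$annotations, eq, seed = 3)
  expect_lt(max(abs(common_mode_subtract(re)$voltages)), 1e-9)
})

test_that("on-nerve envelopes track the generative rate profile and off-nerve do not", {
  s <- fx_song()
  on <- make_nerve_recording(s$annotations, nerve_model(), seed = 4)
  off <- make_nerve_recording(s$annotations, nerve_model(on_nerve = FALSE),
                              seed = 5)
  expect_identical(off$role, "off-nerve")
  rp <- attr(on, "envelope_drive")[seq(1, ncol(on$voltages), by = 30)]
  e_on <- envelope_trace(bandpass_filter(common_mode_subtract(on)), 5, 1)
  e_off <- envelope_trace(bandpass_filter(common_mode_subtract(off)), 5, 1)
  k <- min(length(e_on$values), length(rp))
  expect_gt(cor(e_on$values[1:k], rp[1:k]), 0.5)
  r_off <- cor(e_off$values[1:k], rp[1:k])
  # off-nerve correlation indistinguishable from 0 (|r| < ~3/sqrt(n_indep))
  expect_lt(abs(r_off), 0.15)
})

test_that("evoked trials follow the sigmoid in current and saturate at vmax", {
  m <- evoked_model(vmax = 300, i50 = 20, slope = 5, baseline_noise = 0)
  # I = 0: response near vmax/(1+exp(i50/slope))
  t0 <- make_evoked_trials(m, 0, 1, seed = 1)[[1]]
  w <- response_windows()
  vpp0 <- response_metrics(t0, w)$vpp
  expect_equal(vpp0, 300 / (1 + exp(20 / 5)), tolerance = 0.1)
  # large current: Vpp ~ vmax
  t_inf <- make_evoked_trials(m, 500, 1, seed = 1)[[1]]
  expect_equal(response_metrics(t_inf, w)$vpp, 300, tolerance = 0.02)
})

test_that("fictive vocalizations map patterns to distinct, repeatable syllables", {
  pats <- make_steering_patterns(3)
  expect_error(make_fictive_vocalizations(c(pats, pats[1]), 2),
               "duplicate")
  fv <- make_fictive_vocalizations(pats, 3, mapping_spread = 1.5, seed = 1)
  expect_length(fv$clips, 9)
  expect_equal(sort(unique(fv$labels)),
               sort(vapply(pats, function(p) p$pattern_id, character(1))))
  expect_equal(length(fv$clips[[1]]$samples), round(0.2 * 44150))
  # degenerate mapping collapses all patterns to one spec
  fv0 <- make_fictive_vocalizations(pats, 2, mapping_spread = 0, seed = 1)
  expect_identical(fv0$specs[[1]], fv0$specs[[2]])
  expect_identical(fv0$specs[[1]], fv0$specs[[3]])
})
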