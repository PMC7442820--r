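test_that("stationary tone yields its pitch with near-zero AM and FM", {
  rate <- 44150
  t <- seq(0, 0.2, by = 1 / rate)
  clip <- audio_clip(0.5 * sin(2 * pi * 1000 * t), rate)
  tr <- compute_features(clip)
  expect_equal(nrow(tr), 200)
  mid <- tr[20:180, ]
  expect_true(all(mid$voiced))
  expect_equal(mean(mid$pitch), 1000, tolerance = 0.01)
  expect_lt(max(abs(mid$am)), 1)
  expect_lt(max(abs(mid$fm)), 0.05)
  expect_lt(mean(mid$wiener_entropy), -4)  # strongly tonal
})

test_that("white noise has Wiener entropy near 0 and no voicing", {
  set.seed(7)
  clip <- audio_clip(stats::rnorm(44150 %/% 2) * 0.3, 44150)
  tr <- compute_features(clip)
  expect_true(all(tr$wiener_entropy <= 0))
  expect_gt(mean(tr$wiener_entropy), -1.2)
  expect_lt(mean(tr$voiced), 0.2)
})

test_that("track length equals the segment length in milliseconds", {
  rate <- 44150
  t <- seq(0, 0.3, by = 1 / rate)
  clip <- audio_clip(0.5 * sin(2 * pi * 2000 * t), rate)
  for (len_ms in c(15, 50, 150)) {
    tr <- compute_features(clip, onset = 0.01, offset = 0.01 + len_ms / 1000)
    expect_equal(nrow(tr), len_ms)
  }
  expect_error(compute_features(clip, 0, 0.005), "window")
})

test_that("harmonic stack pitch matches the fundamental within 2%", {
  rate <- 44150
  t <- seq(0, 0.15, by = 1 / rate)
  for (f0 in c(500, 800, 1300, 2100)) {
    y <- Reduce(`+`, lapply(1:6, function(h) 0.7^(h - 1) * sin(2 * pi * h * f0 * t)))
    tr <- compute_features(audio_clip(0.2 * y / max(abs(y)), rate))
    mid <- tr[20:130, ]
    expect_lt(abs(mean(mid$pitch[mid$voiced]) - f0) / f0, 0.02)
  }
})

test_that("entropy and envelope transform correctly under amplitude gain", {
  s <- fx_song()
  ann <- s$annotations
  tr1 <- compute_features(s$clip, ann$onset[1], ann$offset[1])
  g <- 3.5
  clip2 <- audio_clip(pmin(1, pmax(-1, s$clip$samples * g)), s$clip$rate)
  # use unclipped gain on the isolated segment to avoid saturation
  seg <- s$clip$samples[round(ann$onset[1] * s$clip$rate):round(ann$offset[1] * s$clip$rate)]
  tr2 <- compute_features(audio_clip(seg * 0.5, s$clip$rate))
  tr0 <- compute_features(audio_clip(seg, s$clip$rate))
  k <- seq_len(min(nrow(tr0), nrow(tr2)))
  expect_equal(tr2$wiener_entropy[k], tr0$wiener_entropy[k], tolerance = 1e-8)
  expect_equal(tr2$envelope[k] - tr0$envelope[k],
               rep(20 * log10(0.5), length(k)), tolerance = 1e-6)
  expect_equal(tr2$am[k], tr0$am[k], tolerance = 1e-8)
  expect_equal(tr2$fm[k], tr0$fm[k], tolerance = 1e-8)
})

test_that("feature summaries handle constant tracks, concatenation and pitch ramps", {
  rate <- 44150
  t <- seq(0, 0.2, by = 1 / rate)
  clip <- audio_clip(0.5 * sin(2 * pi * 1500 * t), rate)
  tr <- compute_features(clip)
  sm <- summarize_features(tr)
  expect_false(sm$pitch_absent)
  expect_true(all(is.finite(sm$summary$mean)))
  # duplicating a track leaves the means unchanged
  tr2 <- rbind(tr, tr)
  class(tr2) <- class(tr)
  sm2 <- summarize_features(tr2)
  expect_equal(sm2$summary$mean, sm$summary$mean)
  # linear pitch ramp: mean pitch ~ midpoint
  f0 <- 800; f1 <- 1600
  finst <- f0 + (f1 - f0) * t / max(t)
  phase <- 2 * pi * cumsum(finst) / rate
  ramp <- compute_features(audio_clip(0.5 * sin(phase), rate))
  mid <- ramp[15:185, ]
  expect_equal(mean(mid$pitch[mid$voiced]), (f0 + f1) / 2, tolerance = 0.04)
  # all-unvoiced input flags the pitch summary absent
  noise <- compute_features(audio_clip(stats::rnorm(22050) * 0.1, rate))
  if (!any(noise$voiced)) expect_true(summarize_features(noise)$pitch_absent)
})
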