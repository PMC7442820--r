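test_that("common-mode subtraction removes shared components exactly and is idempotent", {
  set.seed(1)
  s <- sin(2 * pi * 1000 * seq(0, 0.1, by = 1 / 30000))
  c_shared <- stats::rnorm(length(s))
  tr <- neural_traces(rbind(s + c_shared, -s + c_shared), 30000)
  out <- common_mode_subtract(tr)
  expect_equal(out$voltages[1, ], s, tolerance = 1e-12)
  expect_equal(out$voltages[2, ], -s, tolerance = 1e-12)
  # identical channels cancel to zero
  same <- neural_traces(rbind(c_shared, c_shared, c_shared), 30000)
  expect_lt(max(abs(common_mode_subtract(same)$voltages)), 1e-12)
  # idempotence and single-channel error
  expect_equal(common_mode_subtract(out)$voltages, out$voltages)
  expect_error(common_mode_subtract(neural_traces(matrix(s, 1), 30000)),
               "single channel")
})

test_that("zero-phase band-pass kills DC, preserves the passband and does not shift pulses", {
  rate <- 24400
  n <- 4096
  dc <- neural_traces(matrix(rep(5, n), 1), rate)
  out <- bandpass_filter(dc, 300, 6000)
  expect_lt(max(abs(out$voltages[, 500:(n - 500)])) / 5, 1e-3)
  # 1 kHz sine passes within 5%
  t <- (seq_len(n) - 1) / rate
  sine <- neural_traces(matrix(sin(2 * pi * 1000 * t), 1), rate)
  fs <- bandpass_filter(sine, 300, 6000)
  mid <- fs$voltages[1, 1000:(n - 1000)]
  expect_equal(max(abs(mid)), 1, tolerance = 0.05)
  # symmetric Gaussian pulse keeps its peak sample
  pulse <- exp(-((seq_len(n) - n / 2)^2) / (2 * 20^2))
  fp <- bandpass_filter(neural_traces(matrix(pulse, 1), rate), 300, 6000)
  expect_equal(which.max(abs(fp$voltages[1, ])), n / 2)
  expect_error(bandpass_filter(sine, 300, 13000), "Nyquist")
})

test_that("filtering and CMS commute (both linear)", {
  set.seed(2)
  v <- matrix(stats::rnorm(6 * 5000), nrow = 6)
  tr <- neural_traces(v, 24400)
  a <- bandpass_filter(common_mode_subtract(tr))$voltages
  b <- common_mode_subtract(bandpass_filter(tr))$voltages
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("envelope squares, smooths and scales quadratically", {
  rate <- 30000
  const <- neural_traces(matrix(rep(3, rate / 2), 1), rate)
  env <- envelope_trace(const, window_ms = 5, step_ms = 1)
  interior <- env$values[10:(length(env$values) - 10)]
  expect_equal(mean(interior), 9, tolerance = 1e-9)
  set.seed(3)
  v <- matrix(stats::rnorm(3 * rate / 2), nrow = 3)
  e1 <- envelope_trace(neural_traces(v, rate), 5, 1)
  e2 <- envelope_trace(neural_traces(2 * v, rate), 5, 1)
  expect_equal(e2$values, 4 * e1$values, tolerance = 1e-9)
  # burst of known power: plateau ~ burst power
  burst <- rep(0, rate / 2)
  burst[10000:12000] <- sqrt(2) * sin(2 * pi * 1000 * (1:2001) / rate)
  eb <- envelope_trace(burst, window_ms = 5, step_ms = 1, rate = rate)
  plateau <- eb$values[round(10500 / 30):round(11500 / 30)]
  expect_equal(mean(plateau), 1, tolerance = 0.05)
})

test_that("aligning a template to itself gives the identity warp at zero cost", {
  b <- fx_tempo_bird()
  s <- make_song(b, 1, seed = 1, lead_s = 0.05)
  al <- align_motifs(list(s$clip), template = s$clip)
  p <- al$paths[[1]]
  expect_true(all(p$path[, 1] == p$path[, 2]))
  env <- envelope_trace(abs(s$clip$samples), 20, 1, rate = s$clip$rate)
  w <- warp_neural(env, p)
  k <- min(length(w$values), length(env$values))
  expect_equal(w$values[1:k], env$values[1:k], tolerance = 0.05)
})

test_that("a uniform tempo stretch is recovered: slope ~1.25 and high round-trip correlation", {
  b <- fx_tempo_bird()
  templ <- make_song(b, 1, seed = 1, lead_s = 0.05, gap_s = 0.04)
  slow <- make_song(scale_tempo(b, 1.25), 1, seed = 1,
                    lead_s = 0.0625, gap_s = 0.05)
  al <- align_motifs(list(slow$clip), template = templ$clip)
  p <- al$paths[[1]]
  expect_true(all(diff(p$path[, 1]) >= 0))
  expect_true(all(diff(p$path[, 2]) >= 0))
  # fitted overall slope of the warp
  slope <- stats::coef(stats::lm(p$path[, 1] ~ p$path[, 2]))[2]
  expect_equal(unname(slope), 1.25, tolerance = 0.05)
  env_t <- envelope_trace(abs(templ$clip$samples), 20, 1, rate = 44150)
  env_s <- envelope_trace(abs(slow$clip$samples), 20, 1, rate = 44150)
  w <- warp_neural(env_s, p)
  k <- min(length(w$values), length(env_t$values))
  expect_gt(cor(w$values[1:k], env_t$values[1:k]), 0.95)
})

test_that("warp paths of a rendition batch are monotone and boundary-anchored", {
  b <- bird_spec("warpbatch", seed = 5)
  rends <- lapply(1:5, function(i) {
    s <- make_song(b, 1, seed = 10 + i)
    s$clip
  })
  al <- align_motifs(rends)
  expect_true(al$template_index %in% 1:5)
  for (p in al$paths) {
    expect_true(all(diff(p$path[, 1]) >= 0))
    expect_true(all(diff(p$path[, 2]) >= 0))
    expect_equal(p$path[1, ], c(1, 1), ignore_attr = TRUE)
  }
})

test_that("alignment improves the match between two renditions of one motif", {
  b <- bird_spec("warppair", seed = 6, rendition_jitter = 0.06)
  s1 <- make_song(b, 1, seed = 21)
  s2 <- make_song(b, 1, seed = 22)
  al <- align_motifs(list(s2$clip), template = s1$clip)
  e1 <- envelope_trace(abs(s1$clip$samples), 20, 1, rate = 44150)
  e2 <- envelope_trace(abs(s2$clip$samples), 20, 1, rate = 44150)
  w <- warp_neural(e2, al$paths[[1]])
  k <- min(length(w$values), length(e1$values))
  k2 <- min(length(e2$values), length(e1$values))
  expect_gte(cor(w$values[1:k], e1$values[1:k]),
             cor(e2$values[1:k2], e1$values[1:k2]))
})
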