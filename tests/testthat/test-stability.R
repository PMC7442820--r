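test_that("running correlation is 1 for identical envelopes and ~0 for noise", {
  ref <- sin(seq(0, 4 * pi, length.out = 200))^2
  envs <- matrix(rep(ref, 30), nrow = 30, byrow = TRUE)
  rc <- running_correlation(envs, ref, window_trials = 25)
  expect_true(all(abs(rc$correlation - 1) < 1e-12))
  set.seed(4)
  noise <- matrix(stats::rexp(30 * 200), nrow = 30)
  rn <- running_correlation(noise, ref, window_trials = 25)
  expect_lt(max(abs(rn$correlation)), 0.5)
  expect_lt(abs(mean(rn$correlation)), 0.3)
  # zero-variance windows are flagged, not dropped
  flat <- matrix(1, nrow = 25, ncol = 200)
  rf <- running_correlation(flat, ref, window_trials = 25)
  expect_true(all(rf$flagged))
  expect_equal(nrow(rf), 1)
})

test_that("Vpp and SNR follow their defining formulas", {
  tr <- c(rep(0, 10), 250, rep(0, 10), -250, rep(0, 10))
  expect_equal(motif_vpp(tr), 500)
  expect_equal(motif_vpp(rep(4, 100)), 0)
  x <- stats::rnorm(1000)
  expect_equal(singing_snr(x, x), 0)
  expect_equal(singing_snr(10 * x, x), 10)
  expect_error(singing_snr(x, rep(0, 100)), "zero noise")
  # invariance to common gain
  expect_equal(singing_snr(3 * x, 3 * x[1:500]), singing_snr(x, x[1:500]))
})

test_that("event rate counts threshold crossings and is scale invariant", {
  base <- rep(1, 1000)
  expect_equal(event_rate(base, 1, step_s = 0.001), 0)
  env <- rep(1, 1000)
  peaks <- c(100, 300, 500, 700, 900)
  for (p in peaks) env[p:(p + 3)] <- 50
  r <- event_rate(env, unwarped_duration = 2, step_s = 0.001)
  expect_equal(r, length(peaks) / 2)
  expect_equal(event_rate(1000 * env, 2, step_s = 0.001), r)
})

test_that("event rate recovers the generative burst rate from Poisson envelopes", {
  set.seed(11)
  true_rate <- 4  # bursts per second
  dur <- 1
  rates <- vapply(1:50, function(i) {
    n_ev <- stats::rpois(1, true_rate * dur)
    env <- rep(1, 1000) + stats::rnorm(1000, sd = 0.02)
    for (e in seq_len(n_ev)) {
      p <- sample(20:980, 1)
      env[p:(p + 4)] <- env[p:(p + 4)] + 100
    }
    event_rate(env, dur, step_s = 0.001)
  }, numeric(1))
  expect_lt(abs(mean(rates) - true_rate) / true_rate, 0.15)
})

test_that("a stable 30-day synthetic dataset shows no drift in any daily metric", {
  set.seed(21)
  days <- rep(1:10, each = 8)
  tmpl <- sin(seq(0, 3 * pi, length.out = 150))^2 + 0.1
  envs <- t(vapply(days, function(d) tmpl * stats::rlnorm(1, 0, 0.05) +
                     stats::rnorm(150, sd = 0.02)^2, numeric(150)))
  rec <- data.frame(day = days,
                    vpp = 400 + stats::rnorm(length(days), sd = 25),
                    snr = 12 + stats::rnorm(length(days), sd = 1),
                    event_rate = 20 + stats::rnorm(length(days), sd = 2))
  rep_ <- stability_report(rec, envs)
  expect_equal(nrow(rep_$daily), 10)
  expect_true(all(rep_$daily$n == 8))
  expect_gt(min(rep_$tests$p_value), 0.05 / nrow(rep_$tests))
  # regression slope CI covers zero for each metric (99% to keep the
  # familywise type-I rate of this stationarity check low)
  for (mt in c("vpp", "snr", "event_rate")) {
    fit <- stats::lm(rep_$daily[[mt]] ~ rep_$daily$day)
    ci <- stats::confint(fit, level = 0.99)[2, ]
    expect_true(ci[1] < 0 && ci[2] > 0)
  }
})

test_that("on/off-nerve comparison separates structured from unstructured envelopes", {
  set.seed(31)
  nt <- 30; len <- 200
  tmpl <- sin(seq(0, 4 * pi, length.out = len))^2
  on_env <- t(vapply(seq_len(nt), function(i)
    tmpl + stats::rnorm(len, sd = 0.1)^2, numeric(len)))
  off_env <- t(vapply(seq_len(nt), function(i)
    stats::rnorm(len, sd = 0.3)^2, numeric(len)))
  on_snr <- 10 + stats::rnorm(nt); off_snr <- stats::rnorm(nt, 0, 0.5)
  cmp <- on_off_nerve_compare(on_env, off_env, on_snr, off_snr,
                              n_boot = 2000, seed = 1)
  expect_gt(mean(cmp$snr$on > cmp$snr$off), 0.9)
  # independent envelopes: mean correlation inside the zero CI
  expect_gt(cmp$mean_correlation, cmp$zero_corr_ci[1])
  expect_lt(cmp$mean_correlation, cmp$zero_corr_ci[2])
  # positive control: off = on sits outside the zero CI
  cmp2 <- on_off_nerve_compare(on_env, on_env, on_snr, on_snr,
                               n_boot = 2000, seed = 2)
  expect_true(all(abs(cmp2$correlations - 1) < 1e-12))
  expect_gt(mean(cmp2$correlations), cmp2$zero_corr_ci[2])
  expect_error(on_off_nerve_compare(on_env[1:5, ], off_env, on_snr, off_snr),
               "paired")
})
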