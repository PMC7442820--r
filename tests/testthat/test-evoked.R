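test_that("artifact alignment removes onset jitter and flags artifact-free trials", {
  m <- evoked_model(baseline_noise = 5)
  trials <- make_evoked_trials(m, 30, 12, seed = 3, onset_jitter_ms = 0.2)
  al <- align_trials(trials)
  expect_length(al$excluded, 0)
  onsets <- vapply(al$trials, function(tr) which(abs(tr$trace) > 1000)[1],
                   numeric(1))
  expect_lte(diff(range(onsets)), 1)
  # idempotence: aligning aligned trials changes nothing
  al2 <- align_trials(al$trials)
  expect_equal(al2$trials[[1]]$trace, al$trials[[1]]$trace)
  # a flat trial has no artifact
  flat <- al$trials[[1]]
  flat$trace <- stats::rnorm(length(flat$trace))
  al3 <- align_trials(list(flat, al$trials[[2]]))
  expect_equal(al3$excluded, 1)
})

test_that("response metrics: flat traces give zero Vpp and 0 dB SNR", {
  m <- evoked_model()
  tr <- make_evoked_trials(m, 0, 1, seed = 1)[[1]]
  tr$trace <- rep(2, length(tr$trace))
  rm_ <- response_metrics(tr)
  expect_equal(rm_$vpp, 0)
  expect_equal(rm_$snr_db, 0)
  # known noise-free amplitude is recovered
  clean <- evoked_model(vmax = 250, i50 = 10, slope = 3, baseline_noise = 0)
  big <- make_evoked_trials(clean, 100, 1, seed = 1)[[1]]
  out <- response_metrics(big)
  expect_equal(out$vpp, 250, tolerance = 0.02)
  expect_gt(out$snr_db, 20)
  # windows outside the trace error out
  expect_error(response_metrics(big, response_windows(c(26, 30), c(40, 44))),
               "disjoint|outside")
})

test_that("bootstrap detection fires on real responses and respects its conventions", {
  m <- evoked_model(vmax = 300, i50 = 20, slope = 5, baseline_noise = 10)
  trials <- make_evoked_trials(m, 60, 20, seed = 5)
  d <- detect_response(trials, n_boot = 2000, seed = 1)
  expect_true(d$detected)
  expect_gt(d$observed_snr_db, 10)
  # null data: not detected (single dataset sanity check)
  null_m <- evoked_model(vmax = 1e-9, i50 = 20, slope = 5, baseline_noise = 10)
  nt <- make_evoked_trials(null_m, 0, 20, seed = 6)
  dn <- detect_response(nt, n_boot = 2000, seed = 1)
  expect_false(dn$detected)
  # alternative convention runs and agrees on the strong response
  d2 <- detect_response(trials, n_boot = 2000, seed = 1,
                        convention = "ci_of_observed")
  expect_true(d2$detected)
  expect_error(detect_response(trials[1:4]), ">= 8 trials")
  zero <- lapply(trials, function(tr) { tr$trace[] <- 1; tr })
  expect_error(detect_response(zero), "degenerate")
})

test_that("recruitment fit recovers generator parameters within 10% and finds the threshold", {
  m <- evoked_model(vmax = 300, i50 = 20, slope = 5, baseline_noise = 10)
  trials <- make_evoked_trials(m, c(0, 5, 10, 15, 20, 25, 30, 40), 20, seed = 1)
  fit <- recruitment_curve(trials, seed = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$i50 - 20) / 20, 0.1)
  expect_lt(abs(fit$vmax - 300) / 300, 0.1)
  expect_true(is.finite(fit$threshold_current))
  expect_lte(fit$threshold_current, 20)
  # noise-free sigmoid samples: near-zero residuals
  clean <- evoked_model(vmax = 200, i50 = 15, slope = 4, baseline_noise = 0)
  ct <- make_evoked_trials(clean, seq(0, 40, by = 5), 2, seed = 2)
  cf <- recruitment_curve(ct, n_boot = 500, seed = 1)
  pred <- cf$baseline + cf$vmax / (1 + exp(-(cf$table$current - cf$i50) / cf$slope))
  expect_lt(max(abs(pred - cf$table$vpp)), 5)
  # currents far below threshold: at most sporadic (false-positive-level)
  # detections, and the censoring report is consistent with the table
  low <- make_evoked_trials(m, c(0, 0.5, 1, 1.5, 2), 10, seed = 3)
  lf <- recruitment_curve(low, n_boot = 500, seed = 1)
  n_det <- sum(lf$table$detected %in% TRUE)
  expect_lte(n_det, 2)
  if (n_det == 0) {
    expect_true(lf$censored)
    expect_false(is.finite(lf$threshold_current))
  } else {
    expect_equal(lf$threshold_current,
                 min(lf$table$current[lf$table$detected %in% TRUE]))
  }
  expect_equal(lf$max_tested, 2)
  expect_error(recruitment_curve(trials[1:20][vapply(trials[1:20], function(t) t$current, numeric(1)) %in% c(0, 5)]),
               "distinct currents")
})

test_that("recruitment estimator bias shrinks with trials per current", {
  m <- evoked_model(vmax = 300, i50 = 20, slope = 5, baseline_noise = 10)
  cur <- c(0, 5, 10, 15, 20, 25, 30, 40)
  errs <- vapply(c(5, 20, 80), function(npc) {
    fits <- vapply(1:4, function(r) {
      tr <- make_evoked_trials(m, cur, npc, seed = 100 * npc + r)
      recruitment_curve(tr, n_boot = 200, seed = r)$i50
    }, numeric(1))
    abs(mean(fits) - 20)
  }, numeric(1))
  expect_lt(errs[3], errs[1] + 0.5)
  expect_lt(errs[3], 1)
})

test_that("condition comparison flags a lidocaine-like block and clears identical conditions", {
  m <- evoked_model(vmax = 300, i50 = 20, slope = 5, baseline_noise = 8)
  mk <- function(scale, cond, subj, seed) {
    tr <- make_evoked_trials(m, 60, 16, seed = seed)
    vapply(tr, function(t) {
      t$trace <- t$trace * scale + stats::rnorm(1, sd = 1)
      rm_ <- response_metrics(t)
      rm_$vpp
    }, numeric(1))
  }
  set.seed(41)
  rows <- list()
  for (s in 1:3) {
    for (cond in c("baseline", "saline", "lidocaine", "washout")) {
      scale <- switch(cond, lidocaine = 0.05, 1) * stats::runif(1, 0.9, 1.1)
      rows[[length(rows) + 1]] <- data.frame(
        subject = paste0("b", s), condition = cond,
        amplitude = mk(scale, cond, s, seed = 500 + 10 * s))
    }
  }
  dat <- do.call(rbind, rows)
  cc <- condition_compare(dat, control = "saline")
  expect_lt(cc$anova$p, 0.05)
  lido <- cc$dunnett[grepl("lidocaine", cc$dunnett$contrast), ]
  expect_lt(lido$p_value, 0.05)
  wash <- cc$dunnett[grepl("washout", cc$dunnett$contrast), ]
  expect_gt(wash$p_value, 0.05)
  # identical conditions: nothing significant
  same <- dat
  set.seed(42)
  same$amplitude <- 100 + stats::rnorm(nrow(same))
  cs <- condition_compare(same, control = "saline")
  expect_true(all(cs$dunnett$p_value > 0.05))
  expect_error(condition_compare(dat[dat$condition != "saline" | dat$subject != "b1", ]),
               "paired")
})

test_that("compression force converts pressure x area with the exact mmHg factor", {
  expect_equal(compression_force_limit(30, 0.03), 119.99, tolerance = 1e-3)
  expect_equal(compression_force_limit(0, 0.03), 0)
  expect_equal(compression_force_limit(30, 0.06),
               2 * compression_force_limit(30, 0.03))
})
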