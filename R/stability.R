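#' Sliding-window envelope correlation against a day-1 reference
#'
#' Pearson correlation between the mean song-aligned activity envelope in
#' a sliding window of trials (width 25, advance 1) and the day-1 mean
#' envelope. All envelopes must share the template time base.
#'
#' @param envelopes matrix, trials x template-time samples (song-aligned
#'   envelopes in chronological order)
#' @param reference day-1 mean envelope (numeric, same length as columns)
#' @param window_trials sliding-window width in trials (default 25)
#' @param advance window advance in trials (default 1)
#' @return data.frame: window (index of first trial), correlation, flagged
#'   (TRUE when a window had zero variance and no correlation is defined)
#' @export
running_correlation <- function(envelopes, reference, window_trials = 25,
                                advance = 1) {
  envelopes <- as.matrix(envelopes)
  stopifnot(ncol(envelopes) == length(reference),
            nrow(envelopes) >= window_trials)
  starts <- seq(1L, nrow(envelopes) - window_trials + 1L, by = advance)
  res <- lapply(starts, function(s) {
    m <- colMeans(envelopes[s:(s + window_trials - 1L), , drop = FALSE])
    if (stats::sd(m) == 0 || stats::sd(reference) == 0)
      data.frame(window = s, correlation = NA_real_, flagged = TRUE)
    else
      data.frame(window = s, correlation = stats::cor(m, reference),
                 flagged = FALSE)
  })
  do.call(rbind, res)
}

#' Peak-to-peak voltage of a motif window
#'
#' @param x numeric voltage vector (processed single-channel trace over the
#'   motif), or a `neural_traces` whose channels are reduced by `reduce`
#' @param reduce how to combine channels of a `neural_traces`:
#'   `"best"` (largest Vpp) or `"mean"` (mean trace)
#' @return Vpp = max - min, in the input's units (microvolts)
#' @export
motif_vpp <- function(x, reduce = c("best", "mean")) {
  reduce <- match.arg(reduce)
  if (inherits(x, "neural_traces")) {
    v <- x$voltages
    if (reduce == "mean") return(diff(range(colMeans(v))))
    return(max(apply(v, 1, function(ch) diff(range(ch)))))
  }
  if (length(x) == 0) stop("empty trace")
  diff(range(x))
}

#' Singing-period SNR in dB
#'
#' `10 * log10(RMS_singing / RMS_noise)` — a ratio of RMS amplitudes, not
#' of powers. The noise segment is vocalization-free recording captured
#' after song offset (the triggered-recording post-roll), 500 ms by
#' convention.
#'
#' @param singing numeric voltage trace during singing
#' @param noise numeric voltage trace with no vocalization (same units and
#'   preprocessing)
#' @return SNR in dB
#' @export
singing_snr <- function(singing, noise) {
  rn <- rms(noise)
  if (rn == 0) stop("zero noise RMS: SNR undefined")
  10 * log10(rms(singing) / rn)
}

#' Envelope threshold-crossing event rate
#'
#' Events are upward crossings of a per-motif threshold set at the mean
#' plus 5 SD of the motif's singing envelope (an upward crossing at sample
#' i means env[i-1] < threshold <= env[i]); a refractory period of one
#' smoothing window suppresses double counts. The rate divides the count
#' by the motif's unwarped duration. Because the threshold scales with the
#' envelope, the rate is invariant to envelope gain.
#'
#' @param env an `envelope_trace` (song-aligned motif envelope), or a
#'   numeric vector with `step_s` supplied
#' @param unwarped_duration duration of the unwarped motif, s
#' @param sd_mult threshold in SDs above the mean (default 5)
#' @param step_s envelope sample step, s (taken from the object if given)
#' @param refractory_s minimum spacing between counted events; defaults to
#'   the envelope's smoothing window
#' @return events per second
#' @export
event_rate <- function(env, unwarped_duration, sd_mult = 5, step_s = NULL,
                       refractory_s = NULL) {
  if (inherits(env, "envelope_trace")) {
    v <- env$values
    if (is.null(step_s)) step_s <- env$step_s
    if (is.null(refractory_s)) refractory_s <- env$smoothing_ms / 1000
  } else {
    v <- as.numeric(env)
    if (is.null(step_s)) stop("step_s required for bare vectors")
    if (is.null(refractory_s)) refractory_s <- 0.005
  }
  stopifnot(unwarped_duration > 0)
  thr <- mean(v) + sd_mult * stats::sd(v)
  if (!is.finite(thr) || stats::sd(v) == 0) return(0)
  up <- which(v[-1] >= thr & v[-length(v)] < thr) + 1L
  if (length(up) > 1) {
    refr <- max(1L, round(refractory_s / step_s))
    keep <- c(TRUE, diff(up) >= refr)
    up <- up[keep]
  }
  length(up) / unwarped_duration
}

#' Daily stability report over a chronic recording
#'
#' Summarizes per-day means of the four longitudinal metrics (correlation
#' to the day-1 mean envelope, Vpp, SNR, event rate) and tests each later
#' day against day 1 with two-tailed paired t-tests across motifs (paired
#' by within-day motif index).
#'
#' @param records data.frame with one row per motif: `day`, plus list
#'   columns or precomputed numeric columns `vpp`, `snr`, `event_rate`,
#'   and an `envelope` matrix (motifs x template samples) given separately
#' @param envelopes matrix, motifs x template samples, rows matching
#'   `records`
#' @return list: `daily` (per-day metric means with trial counts),
#'   `tests` (per-day paired-t p-values vs day 1 for each metric)
#' @export
stability_report <- function(records, envelopes) {
  stopifnot(all(c("day", "vpp", "snr", "event_rate") %in% names(records)),
            nrow(records) == nrow(envelopes), 1 %in% records$day)
  d1 <- which(records$day == 1)
  ref_sum <- colSums(envelopes[d1, , drop = FALSE])
  ref <- ref_sum / length(d1)
  corr <- vapply(seq_len(nrow(envelopes)), function(i) {
    e <- envelopes[i, ]
    # day-1 records correlate against the leave-one-out day-1 mean, so a
    # record never contributes to its own reference
    r <- if (i %in% d1 && length(d1) > 1)
      (ref_sum - e) / (length(d1) - 1) else ref
    if (stats::sd(e) > 0 && stats::sd(r) > 0) stats::cor(e, r) else NA_real_
  }, numeric(1))
  records$correlation <- corr
  days <- sort(unique(records$day))
  metrics <- c("correlation", "vpp", "snr", "event_rate")
  daily <- do.call(rbind, lapply(days, function(d) {
    sub <- records[records$day == d, ]
    data.frame(day = d, n = nrow(sub),
               correlation = mean(sub$correlation, na.rm = TRUE),
               vpp = mean(sub$vpp), snr = mean(sub$snr),
               event_rate = mean(sub$event_rate))
  }))
  d1 <- records[records$day == 1, ]
  tests <- do.call(rbind, lapply(setdiff(days, 1), function(d) {
    sub <- records[records$day == d, ]
    k <- min(nrow(sub), nrow(d1))
    ps <- vapply(metrics, function(mt) {
      a <- d1[[mt]][seq_len(k)]; b <- sub[[mt]][seq_len(k)]
      if (stats::sd(a - b, na.rm = TRUE) == 0) return(1)
      stats::t.test(a, b, paired = TRUE)$p.value
    }, numeric(1))
    data.frame(day = d, metric = metrics, p_value = as.numeric(ps))
  }))
  list(daily = daily, tests = tests)
}

#' Compare simultaneous on-nerve and off-nerve recordings
#'
#' Per-trial SNR for both devices, per-trial Pearson correlation between
#' the on- and off-nerve envelopes, and a bootstrap 95% CI for zero
#' correlation built by circularly time-shifting one member of each pair
#' (which preserves each envelope's autocorrelation while destroying any
#' true coupling).
#'
#' @param on_envelopes,off_envelopes matrices, trials x time, simultaneous
#'   and row-paired
#' @param on_snr,off_snr per-trial SNR vectors (dB), row-paired
#' @param n_boot bootstrap resamples (default 10000)
#' @param level CI level (default 0.95)
#' @param seed integer seed
#' @return list: per-trial `correlations`, `snr` data.frame,
#'   `zero_corr_ci` (length-2), `mean_correlation`
#' @export
on_off_nerve_compare <- function(on_envelopes, off_envelopes,
                                 on_snr, off_snr,
                                 n_boot = 10000, level = 0.95, seed = 1) {
  on_envelopes <- as.matrix(on_envelopes)
  off_envelopes <- as.matrix(off_envelopes)
  if (nrow(on_envelopes) != nrow(off_envelopes) ||
      length(on_snr) != length(off_snr) ||
      nrow(on_envelopes) != length(on_snr))
    stop("on/off trials must be paired")
  nt <- nrow(on_envelopes)
  nc <- ncol(on_envelopes)
  correlations <- vapply(seq_len(nt), function(i)
    stats::cor(on_envelopes[i, ], off_envelopes[i, ]), numeric(1))
  null_corrs <- with_seed(child_seed(seed, 8), {
    vapply(seq_len(n_boot), function(b) {
      i <- sample.int(nt, 1)
      sh <- sample.int(nc - 1, 1)
      stats::cor(on_envelopes[i, ],
                 off_envelopes[i, c((sh + 1):nc, 1:sh)])
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- stats::quantile(null_corrs, c(alpha, 1 - alpha), names = FALSE)
  list(correlations = correlations,
       snr = data.frame(on = on_snr, off = off_snr),
       zero_corr_ci = ci,
       mean_correlation = mean(correlations))
}
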