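#' Five-feature acoustic track of a vocal segment
#'
#' Computes pitch, frequency modulation, amplitude modulation, Wiener
#' entropy, and sound envelope for 10 ms windows advancing in 1 ms steps,
#' one estimate per millisecond of the segment. The segment edges are
#' reflect-padded so the track length equals the segment length in
#' milliseconds.
#'
#' Conventions (the community-standard ones behind the similarity measure):
#' \itemize{
#'   \item envelope: total log power in the 0.3-8 kHz band, dB;
#'   \item Wiener entropy: log(geometric mean / arithmetic mean) of the
#'     band power spectrum, always <= 0, 0 for white noise, strongly
#'     negative for pure tones; amplitude-scale invariant;
#'   \item pitch: autocorrelation fundamental estimator restricted to
#'     0.3-8 kHz with parabolic peak interpolation and an unvoiced flag
#'     when periodicity confidence is low;
#'   \item AM: relative time-derivative of band power (1/s), scale
#'     invariant;
#'   \item FM: arctangent of the normalized spectral-centroid velocity
#'     (rad), scale invariant.
#' }
#'
#' @param clip an `audio_clip`
#' @param onset,offset segment bounds, s; the segment must be >= 10 ms
#' @param window_s analysis window, s (default 0.010)
#' @param voicing_threshold autocorrelation peak confidence below which a
#'   frame is flagged unvoiced (default 0.2)
#' @return a `feature_track` data.frame: times, pitch, fm, am,
#'   wiener_entropy, envelope, voiced
#' @export
compute_features <- function(clip, onset = 0, offset = clip_duration(clip),
                             window_s = 0.010, voicing_threshold = 0.2) {
  stopifnot(inherits(clip, "audio_clip"))
  if (offset - onset < window_s)
    stop("segment shorter than one analysis window")
  rate <- clip$rate
  i0 <- max(1L, round(onset * rate) + 1L)
  i1 <- min(length(clip$samples), round(offset * rate))
  x <- clip$samples[i0:i1]
  n_ms <- round((offset - onset) * 1000)
  sp <- stft_power(x, rate, window_s = window_s, hop_s = 0.001,
                   nfft = 1024, pad = "reflect")
  nf <- min(n_ms, ncol(sp$power))
  band <- sp$freq >= 300 & sp$freq <= 8000
  P <- sp$power[band, seq_len(nf), drop = FALSE]
  freqs <- sp$freq[band]
  eps <- 1e-30
  ptot <- colSums(P) + eps
  envelope <- 10 * log10(ptot)
  went <- apply(P, 2, function(p) {
    p <- p + eps
    mean(log(p)) - log(mean(p))
  })
  went <- pmin(0, went)
  centroid <- colSums(P * freqs) / ptot
  # AM: symmetric relative power derivative, 1/s
  dt <- 0.001
  am <- c(0, (ptot[-(1:2)] - ptot[seq_len(nf - 2)]) / (2 * dt * ptot[2:(nf - 1)]), 0)
  if (nf >= 2) {
    am[1] <- (ptot[2] - ptot[1]) / (dt * ptot[1])
    am[nf] <- (ptot[nf] - ptot[nf - 1]) / (dt * ptot[nf - 1])
  }
  # FM: arctan of centroid velocity normalized by 50 kHz/s
  dc <- c(centroid[2] - centroid[1],
          if (nf > 2) (centroid[-(1:2)] - centroid[seq_len(nf - 2)]) / 2 else numeric(0),
          centroid[nf] - centroid[nf - 1])
  fm <- atan(dc / dt / 5e4)
  # pitch per ms window by autocorrelation
  wlen <- round(window_s * rate)
  half <- wlen %/% 2
  lag_min <- max(2L, floor(rate / 8000))
  lag_max <- min(wlen - 2L, ceiling(rate / 300))
  xp <- c(rev(x[seq_len(min(half, length(x) - 1)) + 1]), x,
          x[length(x) - seq_len(min(wlen, length(x) - 1))])
  pitch <- rep(NA_real_, nf)
  voiced <- rep(FALSE, nf)
  for (i in seq_len(nf)) {
    c0 <- round((i - 1) / 1000 * rate) + 1L
    seg <- xp[c0:(c0 + wlen - 1L)]
    seg <- seg - mean(seg)
    if (sum(seg^2) == 0) next
    ac <- stats::acf(seg, lag.max = lag_max, plot = FALSE,
                     demean = FALSE)$acf[, 1, 1]
    if (lag_max < lag_min + 2) next
    search <- (lag_min + 1):(lag_max + 1)
    pk <- search[which.max(ac[search])]
    conf <- ac[pk] / ac[1]
    if (is.finite(conf) && conf >= voicing_threshold &&
        pk > lag_min + 1 && pk <= lag_max) {
      # parabolic interpolation around the peak lag
      y1 <- ac[pk - 1]; y2 <- ac[pk]; y3 <- ac[pk + 1]
      denom <- y1 - 2 * y2 + y3
      delta <- if (abs(denom) > 0) 0.5 * (y1 - y3) / denom else 0
      lag <- (pk - 1) + max(-0.5, min(0.5, delta))
      f <- rate / lag
      if (f >= 300 && f <= 8000) {
        pitch[i] <- f
        voiced[i] <- TRUE
      }
    }
  }
  structure(data.frame(times = (seq_len(nf) - 1) / 1000,
                       pitch = pitch, fm = fm, am = am,
                       wiener_entropy = went, envelope = envelope,
                       voiced = voiced),
            class = c("feature_track", "data.frame"))
}

#' Per-feature summary of a feature track
#'
#' Means and SDs per feature; unvoiced frames are excluded from the pitch
#' summary and their count reported. If every frame is unvoiced, the pitch
#' summary is `NA` and flagged.
#'
#' @param track a `feature_track`
#' @return list with `summary` (data.frame: feature, mean, sd),
#'   `n_unvoiced`, and `pitch_absent`
#' @export
summarize_features <- function(track) {
  stopifnot(nrow(track) > 0)
  feats <- c("pitch", "fm", "am", "wiener_entropy", "envelope")
  res <- lapply(feats, function(f) {
    v <- track[[f]]
    if (f == "pitch") v <- v[track$voiced]
    if (length(v) == 0 || all(is.na(v)))
      c(mean = NA_real_, sd = NA_real_)
    else c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE))
  })
  out <- data.frame(feature = feats,
                    mean = vapply(res, `[[`, numeric(1), "mean"),
                    sd = vapply(res, `[[`, numeric(1), "sd"))
  list(summary = out,
       n_unvoiced = sum(!track$voiced),
       pitch_absent = !any(track$voiced))
}
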