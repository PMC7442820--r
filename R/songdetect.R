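#' Song-detector configuration
#'
#' Triggered recording emulation: a frame counts as song when power in the
#' song band exceeds `ratio_threshold` times the power in the low-frequency
#' noise band, and each detected run is extended by `post_roll` seconds, as
#' in song-triggered acquisition.
#'
#' @param song_band Hz pair, default 2500-8000 (song energy)
#' @param noise_band Hz pair, default 50-250 (low-frequency background)
#' @param ratio_threshold band-power ratio trigger, dimensionless; the
#'   operating range is 10-50, default 20
#' @param post_roll extension after song offset, s (default 1.5)
#' @param frame,hop analysis frame length and advance, s
#' @return a `detector_config`
#' @export
detector_config <- function(song_band = c(2500, 8000),
                            noise_band = c(50, 250),
                            ratio_threshold = 20, post_roll = 1.5,
                            frame = 0.010, hop = 0.005) {
  stopifnot(ratio_threshold >= 1, frame > 0, hop > 0, post_roll >= 0)
  if (max(noise_band) > min(song_band) && min(noise_band) < max(song_band))
    stop("song and noise bands must not overlap")
  structure(list(song_band = song_band, noise_band = noise_band,
                 ratio_threshold = ratio_threshold, post_roll = post_roll,
                 frame = frame, hop = hop),
            class = "detector_config")
}

#' Detect song episodes by band-power ratio
#'
#' Periodogram band powers per Hann-windowed frame; episodes are maximal
#' runs of frames whose song/noise power ratio meets the threshold, each
#' extended by the post-roll and merged if overlapping. The statistic is a
#' power ratio, so detection is invariant to overall amplitude scaling.
#'
#' @param clip an `audio_clip`
#' @param cfg a `detector_config`
#' @return data.frame with columns `onset`, `offset` (s); zero rows when
#'   nothing is detected
#' @export
detect_song <- function(clip, cfg = detector_config()) {
  stopifnot(inherits(clip, "audio_clip"))
  nyq <- clip$rate / 2
  if (max(cfg$song_band) >= nyq || max(cfg$noise_band) >= nyq)
    stop("detector bands must lie below Nyquist")
  if (clip_duration(clip) <= cfg$frame) stop("clip shorter than one frame")
  sp <- stft_power(clip$samples, clip$rate, window_s = cfg$frame,
                   hop_s = cfg$hop, nfft = 1024, pad = "valid")
  in_band <- function(band) sp$freq >= band[1] & sp$freq <= band[2]
  p_song <- colSums(sp$power[in_band(cfg$song_band), , drop = FALSE])
  p_noise <- colSums(sp$power[in_band(cfg$noise_band), , drop = FALSE])
  # silence in both bands is not song; song power with zero noise power is
  ratio <- ifelse(p_noise > 0, p_song / p_noise,
                  ifelse(p_song > 0, Inf, 0))
  hit <- ratio >= cfg$ratio_threshold
  runs <- logical_runs(hit)
  if (is.null(runs) || nrow(runs) == 0)
    return(data.frame(onset = numeric(0), offset = numeric(0)))
  iv <- cbind(sp$times[runs[, 1]] - cfg$frame / 2,
              sp$times[runs[, 2]] + cfg$frame / 2 + cfg$post_roll)
  iv[, 1] <- pmax(0, iv[, 1])
  iv[, 2] <- pmin(clip_duration(clip), iv[, 2])
  iv <- merge_intervals(iv)
  data.frame(onset = iv[, 1], offset = iv[, 2])
}

#' Segment syllables by amplitude thresholding
#'
#' Rectified waveform smoothed with a short boxcar; segments are runs above
#' threshold, after merging gaps shorter than `min_gap` and dropping runs
#' shorter than `min_dur`. Raising the threshold can only shrink the
#' segmented time.
#'
#' @param clip an `audio_clip`
#' @param threshold amplitude threshold; either an absolute value, or with
#'   `threshold_mode = "relative"` a fraction of the envelope maximum
#' @param threshold_mode `"relative"` (default, threshold x max envelope)
#'   or `"absolute"`
#' @param min_dur minimum syllable duration, s (default 0.010)
#' @param min_gap gaps shorter than this are merged, s (default 0.005)
#' @param smooth_ms envelope boxcar width, ms (default 2)
#' @return data.frame of segments: onset, offset (s), label (`NA`,
#'   unassigned)
#' @export
segment_syllables <- function(clip, threshold = 0.1,
                              threshold_mode = c("relative", "absolute"),
                              min_dur = 0.010, min_gap = 0.005,
                              smooth_ms = 2) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(inherits(clip, "audio_clip"), threshold > 0)
  env <- boxcar_smooth(abs(clip$samples),
                       round(smooth_ms / 1000 * clip$rate))
  thr <- if (threshold_mode == "relative") threshold * max(env) else threshold
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      label = character(0), stringsAsFactors = FALSE)
  if (max(env) == 0 || thr <= 0) return(empty)
  runs <- logical_runs(env > thr)
  if (is.null(runs) || nrow(runs) == 0) return(empty)
  iv <- cbind((runs[, 1] - 1) / clip$rate, runs[, 2] / clip$rate)
  iv <- merge_intervals(iv, gap = min_gap)
  keep <- (iv[, 2] - iv[, 1]) >= min_dur
  iv <- iv[keep, , drop = FALSE]
  if (nrow(iv) == 0) return(empty)
  data.frame(onset = iv[, 1], offset = iv[, 2],
             label = NA_character_, stringsAsFactors = FALSE)
}

# Fixed-size log-spectrogram image of a segment: time x frequency grid
# resized by interpolation to n_time x n_freq and flattened (default
# 50 x 100 = 5000 inputs, the classifier's input dimensionality).
syllable_image <- function(clip, onset, offset, n_time = 50, n_freq = 100) {
  i0 <- max(1L, round(onset * clip$rate) + 1L)
  i1 <- min(length(clip$samples), round(offset * clip$rate))
  seg <- clip$samples[i0:i1]
  ls <- log_spec_frames(seg, clip$rate, hop_s = 0.002)
  fr <- ls$frames
  # bilinear resize to the fixed grid
  src_t <- seq(0, 1, length.out = ncol(fr))
  src_f <- seq(0, 1, length.out = nrow(fr))
  out_t <- seq(0, 1, length.out = n_time)
  out_f <- seq(0, 1, length.out = n_freq)
  tmp <- apply(fr, 1, function(row) stats::approx(src_t, row, xout = out_t)$y)
  img <- apply(tmp, 1, function(col) stats::approx(src_f, col, xout = out_f)$y)
  # img is n_freq x n_time
  as.numeric(img)
}

#' Classify syllable segments against a labeled training set
#'
#' Each segment is rendered as a fixed 5000-element log-spectrogram grid
#' (50 time x 100 frequency) and classified with a small multilayer
#' perceptron (default) or multinomial logistic regression after a PCA
#' compression of the grid. Held-out accuracy is estimated on a stratified
#' split of the training set.
#'
#' @param clip an `audio_clip` containing the segments
#' @param segments data.frame (onset, offset) of segments to label
#' @param training data.frame (onset, offset, label) with >= 2 exemplars
#'   per class and >= 2 classes; may reference a different clip via
#'   `training_clip`
#' @param training_clip `audio_clip` for the training segments (default:
#'   `clip`)
#' @param method `"mlp"` (nnet) or `"multinom"`
#' @param hidden hidden-layer size for the MLP (default 20)
#' @param pca_dim PCA dimensionality ahead of the classifier (default 40,
#'   capped at n-1)
#' @param holdout fraction of training exemplars held out per class for the
#'   accuracy estimate (default 1/3)
#' @param seed integer seed for the split and classifier initialization
#' @return list with `segments` (input segments with `label` filled in),
#'   `holdout_accuracy`, `classes`, and `confusion` (held-out confusion
#'   matrix)
#' @export
annotate_syllables <- function(clip, segments, training,
                               training_clip = clip,
                               method = c("mlp", "multinom"),
                               hidden = 20, pca_dim = 40, holdout = 1 / 3,
                               seed = 1) {
  method <- match.arg(method)
  classes <- sort(unique(training$label))
  if (length(classes) < 2) stop("training set must contain >= 2 classes")
  tab <- table(training$label)
  if (any(tab < 2)) stop("each class needs >= 2 labeled exemplars")
  X <- t(vapply(seq_len(nrow(training)), function(i)
    syllable_image(training_clip, training$onset[i], training$offset[i]),
    numeric(5000)))
  y <- factor(training$label, levels = classes)
  with_seed(child_seed(seed, 6), {
    # stratified held-out split
    test_idx <- unlist(lapply(classes, function(cl) {
      idx <- which(y == cl)
      sample(idx, max(1L, floor(length(idx) * holdout)))
    }))
    train_idx <- setdiff(seq_len(nrow(X)), test_idx)
    pc_rank <- min(pca_dim, length(train_idx) - 1)
    pc <- stats::prcomp(X[train_idx, , drop = FALSE], rank. = pc_rank)
    Ztr <- stats::predict(pc, X[train_idx, , drop = FALSE])
    Zte <- stats::predict(pc, X[test_idx, , drop = FALSE])
    fit <- if (method == "mlp") {
      nnet::nnet(Ztr, nnet::class.ind(y[train_idx]), size = hidden,
                 softmax = TRUE, decay = 1e-3, maxit = 300,
                 MaxNWts = 1e5, trace = FALSE)
    } else {
      nnet::multinom(cls ~ ., data = data.frame(cls = y[train_idx], Ztr),
                     trace = FALSE, MaxNWts = 1e5)
    }
    pred_lab <- function(Z) {
      if (method == "mlp") {
        p <- stats::predict(fit, Z)
        classes[max.col(p)]
      } else {
        as.character(stats::predict(fit, newdata = data.frame(Z)))
      }
    }
    te_pred <- pred_lab(Zte)
    conf <- table(truth = y[test_idx], predicted = factor(te_pred, levels = classes))
    acc <- mean(te_pred == as.character(y[test_idx]))
    out <- segments
    if (nrow(segments) > 0) {
      Xq <- t(vapply(seq_len(nrow(segments)), function(i)
        syllable_image(clip, segments$onset[i], segments$offset[i]),
        numeric(5000)))
      Zq <- stats::predict(pc, Xq)
      out$label <- pred_lab(Zq)
    }
    list(segments = out, holdout_accuracy = acc, classes = classes,
         confusion = conf)
  })
}
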