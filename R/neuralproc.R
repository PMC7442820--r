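#' Multichannel extracellular voltage traces
#'
#' @param voltages channels x samples matrix, microvolts
#' @param rate sampling rate, Hz
#' @param role `"on-nerve"` or `"off-nerve"`
#' @param channel_ids optional channel labels
#' @return a `neural_traces` object
#' @export
neural_traces <- function(voltages, rate, role = c("on-nerve", "off-nerve"),
                          channel_ids = NULL) {
  role <- match.arg(role)
  voltages <- as.matrix(voltages)
  stopifnot(nrow(voltages) >= 1, rate > 0)
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(nrow(voltages)))
  structure(list(voltages = voltages, rate = rate, role = role,
                 channel_ids = channel_ids),
            class = "neural_traces")
}

#' @export
print.neural_traces <- function(x, ...) {
  cat(sprintf("<neural_traces: %d ch x %.3f s at %g Hz (%s)>\n",
              nrow(x$voltages), ncol(x$voltages) / x$rate, x$rate, x$role))
  invisible(x)
}

#' Common-mode subtraction
#'
#' Removes the per-sample mean across channels from every channel. Because
#' every electrode on one device is subject to the same biomechanical and
#' electrochemical artifact sources up to gain, this cancels the shared
#' (rank-1, equal-gain) component exactly; the operation is linear and
#' idempotent.
#'
#' @param traces a `neural_traces` with >= 2 channels
#' @return a `neural_traces` whose across-channel mean is identically zero
#' @export
common_mode_subtract <- function(traces) {
  stopifnot(inherits(traces, "neural_traces"))
  if (nrow(traces$voltages) < 2)
    stop("common-mode subtraction undefined for a single channel")
  cm <- colMeans(traces$voltages)
  out <- traces
  out$voltages <- sweep(traces$voltages, 2, cm)
  out
}

#' Zero-phase two-pole Butterworth band-pass filter
#'
#' Forward-backward filtering, so a symmetric pulse keeps its peak sample
#' (no phase shift). Defaults to the 0.3-6 kHz band used for singing-related
#' nerve activity.
#'
#' @param traces a `neural_traces`
#' @param lo,hi band edges, Hz; `hi` must be below the Nyquist frequency
#' @return filtered `neural_traces`
#' @export
bandpass_filter <- function(traces, lo = 300, hi = 6000) {
  stopifnot(inherits(traces, "neural_traces"), lo < hi)
  if (hi >= traces$rate / 2)
    stop("upper band edge must be below Nyquist (", traces$rate / 2, " Hz)")
  bf <- signal::butter(2, c(lo, hi) / (traces$rate / 2), type = "pass")
  out <- traces
  out$voltages <- t(apply(traces$voltages, 1,
                          function(v) signal::filtfilt(bf, v)))
  out
}

#' Signal envelope: square, boxcar-smooth, optionally downsample to 1 ms
#'
#' Per-channel squaring followed by boxcar smoothing; the channel-combined
#' envelope is the mean across channels. Units are squared microvolts
#' (smoothed instantaneous power).
#'
#' @param traces a `neural_traces` (or a numeric vector with `rate` given)
#' @param window_ms boxcar width, ms (20 for display-scale envelopes, 5 for
#'   all quantitative analyses)
#' @param step_ms output step, ms; `NULL` keeps the full sampling rate
#' @param rate required when `traces` is a bare numeric vector
#' @return an `envelope_trace`: list(values, times, step_s, smoothing_ms)
#' @export
envelope_trace <- function(traces, window_ms = 5, step_ms = 1, rate = NULL) {
  if (inherits(traces, "neural_traces")) {
    v <- traces$voltages
    rate <- traces$rate
  } else {
    v <- matrix(as.numeric(traces), nrow = 1)
    if (is.null(rate)) stop("rate required for bare vectors")
  }
  w <- max(1L, round(window_ms / 1000 * rate))
  sm <- t(apply(v, 1, function(ch) boxcar_smooth(ch^2, w)))
  env <- colMeans(sm)
  times <- (seq_along(env) - 1) / rate
  if (!is.null(step_ms)) {
    idx <- seq(1L, length(env), by = max(1L, round(step_ms / 1000 * rate)))
    env <- env[idx]
    times <- times[idx]
    step_s <- step_ms / 1000
  } else step_s <- 1 / rate
  structure(list(values = env, times = times, step_s = step_s,
                 smoothing_ms = window_ms),
            class = "envelope_trace")
}

#' Align motif renditions to a common template by dynamic time warping
#'
#' Frames each rendition as a log-spectrogram (10 ms window, 1 ms hop) and
#' computes a band-constrained monotone warp of each rendition onto the
#' template, minimizing cumulative Euclidean frame distance. If no template
#' is supplied, the medoid rendition (minimum summed DTW cost to the
#' others) is used.
#'
#' @param renditions list of `audio_clip` motif renditions
#' @param template an `audio_clip`, an index into `renditions`, or `NULL`
#'   for the medoid
#' @param band_ms Sakoe-Chiba band half-width, ms (default 100)
#' @return list with `paths` (one `warp_path` per rendition), `template`
#'   (the template clip) and `template_index` (or NA if supplied directly)
#' @export
align_motifs <- function(renditions, template = NULL, band_ms = 100) {
  if (length(renditions) < 1) stop("no renditions supplied")
  feat <- lapply(renditions, function(cl)
    log_spec_frames(cl$samples, cl$rate)$frames)
  t_idx <- NA_integer_
  if (is.null(template)) {
    n <- length(renditions)
    if (n == 1) {
      t_idx <- 1L
    } else {
      cost <- matrix(0, n, n)
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        d <- dtw_align(feat[[i]], feat[[j]], band = band_ms)$cost
        cost[i, j] <- d; cost[j, i] <- d
      }
      t_idx <- which.min(rowSums(cost))
    }
    template_clip <- renditions[[t_idx]]
    tf <- feat[[t_idx]]
  } else if (is.numeric(template)) {
    t_idx <- as.integer(template)
    template_clip <- renditions[[t_idx]]
    tf <- feat[[t_idx]]
  } else {
    template_clip <- template
    tf <- log_spec_frames(template$samples, template$rate)$frames
  }
  paths <- lapply(seq_along(renditions), function(i) {
    al <- dtw_align(feat[[i]], tf, band = band_ms)
    warp_path(al$path, hop_s = 0.001,
              rendition_dur = clip_duration(renditions[[i]]),
              template_dur = clip_duration(template_clip))
  })
  list(paths = paths, template = template_clip, template_index = t_idx)
}

#' Monotone warp path from rendition time to template time
#'
#' @param path 2-column matrix of (rendition frame, template frame) index
#'   pairs from DTW, 1-based, boundary-anchored
#' @param hop_s frame hop in seconds
#' @param rendition_dur,template_dur clip durations, s
#' @return a `warp_path` carrying a piecewise-linear time map
#' @export
warp_path <- function(path, hop_s = 0.001, rendition_dur = NULL,
                      template_dur = NULL) {
  stopifnot(all(diff(path[, 1]) >= 0), all(diff(path[, 2]) >= 0))
  structure(list(path = path, hop_s = hop_s,
                 rendition_dur = rendition_dur, template_dur = template_dur),
            class = "warp_path")
}

# Piecewise-linear map template time -> rendition time, built by averaging
# rendition frames matched to each template frame then interpolating.
template_to_rendition_time <- function(wp, t_template) {
  p <- wp$path
  tt <- (p[, 2] - 1) * wp$hop_s
  rt <- (p[, 1] - 1) * wp$hop_s
  agg <- tapply(rt, tt, mean)
  xs <- as.numeric(names(agg))
  ys <- as.numeric(agg)
  # anchor ends to the true clip spans
  if (!is.null(wp$template_dur) && !is.null(wp$rendition_dur)) {
    xs <- c(xs, wp$template_dur)
    ys <- c(ys, wp$rendition_dur)
  }
  stats::approx(xs, ys, xout = t_template, rule = 2)$y
}

#' Apply a warp path to an envelope or voltage trace
#'
#' Resamples the trace onto the template time base through the
#' piecewise-linear time map carried by the warp path; no premotor time
#' shift is applied. The identity path returns the input unchanged.
#'
#' @param x an `envelope_trace` or `neural_traces`
#' @param path a `warp_path`
#' @param step_s output step on the template time base, s (default the
#'   input's own step)
#' @return object of the same class as `x`, on template time
#' @export
warp_neural <- function(x, path, step_s = NULL) {
  stopifnot(inherits(path, "warp_path"))
  tmax <- if (!is.null(path$template_dur)) path$template_dur else
    (max(path$path[, 2]) - 1) * path$hop_s
  if (inherits(x, "envelope_trace")) {
    if (is.null(step_s)) step_s <- x$step_s
    t_out <- seq(0, tmax, by = step_s)
    t_src <- template_to_rendition_time(path, t_out)
    if (max(t_src) > max(x$times) + 0.010)
      stop("warp path extends beyond the trace's time span")
    vals <- stats::approx(x$times, x$values, xout = t_src, rule = 2)$y
    structure(list(values = vals, times = t_out, step_s = step_s,
                   smoothing_ms = x$smoothing_ms), class = "envelope_trace")
  } else if (inherits(x, "neural_traces")) {
    if (is.null(step_s)) step_s <- 1 / x$rate
    t_out <- seq(0, tmax, by = step_s)
    t_src <- template_to_rendition_time(path, t_out)
    t_in <- (seq_len(ncol(x$voltages)) - 1) / x$rate
    if (max(t_src) > max(t_in) + 0.010)
      stop("warp path extends beyond the trace's time span")
    v <- t(apply(x$voltages, 1, function(ch)
      stats::approx(t_in, ch, xout = t_src, rule = 2)$y))
    neural_traces(v, rate = 1 / step_s, role = x$role,
                  channel_ids = x$channel_ids)
  } else stop("x must be an envelope_trace or neural_traces")
}
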