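#' Syllable specification for the song synthesizer
#'
#' Syllables are synthesized as harmonic stacks with a time-varying
#' fundamental plus band-limited shaped noise; the noise fraction controls
#' Wiener entropy, a vibrato term controls frequency modulation, and a
#' sinusoidal gain term controls amplitude modulation. This gives an
#' independent handle on each of the five acoustic features downstream
#' analyses measure.
#'
#' @param duration syllable length, seconds; must lie in [0.02, 0.3]
#' @param pitch_traj fundamental-frequency trajectory in Hz, given at
#'   equally spaced points over normalized syllable time (length >= 1);
#'   must lie in [300, 8000]
#' @param am_rate amplitude-modulation rate, Hz
#' @param fm_depth vibrato depth, Hz (30 Hz vibrato rate)
#' @param entropy_level target Wiener-entropy regime, dimensionless (<= 0);
#'   more negative means more tonal (less noise admixture)
#' @param amplitude linear gain in (0, 1]
#' @return a `syllable_spec`
#' @export
syllable_spec <- function(duration, pitch_traj, am_rate = 10, fm_depth = 0,
                          entropy_level = -3, amplitude = 0.6) {
  if (!is.numeric(duration) || duration < 0.02 || duration > 0.3)
    stop("syllable duration must be in [0.02, 0.3] s")
  if (any(pitch_traj < 300) || any(pitch_traj > 8000))
    stop("pitch trajectory must stay within [300, 8000] Hz")
  if (entropy_level > 0) stop("entropy_level must be <= 0")
  structure(list(duration = duration, pitch_traj = as.numeric(pitch_traj),
                 am_rate = am_rate, fm_depth = fm_depth,
                 entropy_level = entropy_level, amplitude = amplitude),
            class = "syllable_spec")
}

#' Bird specification: a stereotyped motif of parametric syllables
#'
#' Distinct `bird_id`s draw independent syllable parameters, emulating the
#' fact that unrelated adult birds sing acoustically unrelated songs while
#' each bird's own motif is highly stereotyped across renditions.
#'
#' @param bird_id token identifying the bird; also seeds the parameter draw
#' @param n_syllables number of syllable types in the motif (default 3)
#' @param rendition_jitter fractional SD of per-rendition feature scaling
#' @param seed integer seed combined with `bird_id` for the parameter draw
#' @return a `bird_spec` with fields `syllable_params` and `motif_order`
#' @export
bird_spec <- function(bird_id, n_syllables = 3, rendition_jitter = 0.03,
                      seed = 1) {
  stopifnot(n_syllables >= 1, rendition_jitter >= 0)
  id_hash <- sum(utf8ToInt(as.character(bird_id)) * seq_len(nchar(as.character(bird_id))))
  syl <- with_seed(child_seed(seed, id_hash), {
    lapply(seq_len(n_syllables), function(i) {
      f0 <- stats::runif(1, 500, 2500)
      f1 <- max(400, min(7000, f0 * stats::runif(1, 0.6, 1.6)))
      syllable_spec(
        duration = stats::runif(1, 0.06, 0.18),
        pitch_traj = c(f0, f1),
        am_rate = stats::runif(1, 5, 40),
        fm_depth = stats::runif(1, 0, 150),
        entropy_level = stats::runif(1, -6, -1.5),
        amplitude = stats::runif(1, 0.4, 0.9)
      )
    })
  })
  structure(list(bird_id = as.character(bird_id), syllable_params = syl,
                 motif_order = seq_len(n_syllables),
                 rendition_jitter = rendition_jitter),
            class = "bird_spec")
}

#' Uniformly change a bird's song tempo
#'
#' Scales every syllable duration (and the amplitude-modulation period)
#' by `scale` while leaving pitch untouched — a pitch-preserving tempo
#' change, the ground-truth warp used to validate motif alignment.
#' Inter-syllable gaps scale through the `gap_s`/`lead_s` arguments of
#' [make_song()].
#'
#' @param bird a `bird_spec`
#' @param scale tempo factor (> 1 slows the song down)
#' @return a `bird_spec` singing the same motif at the new tempo
#' @export
scale_tempo <- function(bird, scale) {
  stopifnot(inherits(bird, "bird_spec"), scale > 0)
  out <- bird
  out$syllable_params <- lapply(bird$syllable_params, function(sp) {
    sp$duration <- min(0.3, max(0.02, sp$duration * scale))
    sp$am_rate <- sp$am_rate / scale
    sp
  })
  out
}

# Render one syllable to a waveform. Harmonic stack (8 partials, geometric
# roll-off) + band-limited noise; 3 ms raised-cosine on/off ramps.
render_syllable <- function(spec, rate) {
  n <- max(2L, round(spec$duration * rate))
  t <- (seq_len(n) - 1) / rate
  u <- t / spec$duration
  f0 <- stats::approx(seq(0, 1, length.out = max(2, length(spec$pitch_traj))),
                      if (length(spec$pitch_traj) == 1)
                        rep(spec$pitch_traj, 2) else spec$pitch_traj,
                      xout = u)$y
  f0 <- f0 + spec$fm_depth * sin(2 * pi * 30 * t)
  phase <- 2 * pi * cumsum(f0) / rate
  harm <- rep(0, n)
  for (h in 1:8) {
    hf <- h * f0
    w <- 0.7^(h - 1)
    harm <- harm + w * sin(h * phase) * (hf < 0.45 * rate)
  }
  harm <- harm / rms(harm)
  noise <- stats::rnorm(n)
  bf <- signal::butter(4, c(300, 8000) / (rate / 2), type = "pass")
  noise <- signal::filtfilt(bf, noise)
  noise <- noise / rms(noise)
  w_noise <- min(1, exp(spec$entropy_level))
  y <- sqrt(1 - w_noise^2) * harm + w_noise * noise
  am <- 1 + 0.5 * sin(2 * pi * spec$am_rate * t)
  ramp_n <- min(round(0.003 * rate), n %/% 3)
  ramp <- rep(1, n)
  if (ramp_n > 1) {
    r <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
    ramp[seq_len(ramp_n)] <- r
    ramp[n + 1 - seq_len(ramp_n)] <- r
  }
  y <- y * am * ramp
  spec$amplitude * y / max(abs(y))
}

# Apply per-rendition jitter to a syllable spec: multiplicative scaling of
# duration, pitch, and amplitude with fractional SD `jit`.
jitter_spec <- function(spec, jit) {
  if (jit <= 0) return(spec)
  s <- spec
  s$duration <- min(0.3, max(0.02, spec$duration * (1 + jit * stats::rnorm(1))))
  s$pitch_traj <- pmin(8000, pmax(300, spec$pitch_traj * (1 + jit * stats::rnorm(1))))
  s$amplitude <- min(1, max(0.05, spec$amplitude * (1 + jit * stats::rnorm(1))))
  s
}

#' Synthesize a song bout with ground-truth annotations
#'
#' Concatenates `n_motifs` renditions of the bird's motif, separated by
#' silence, with per-rendition multiplicative jitter on syllable duration,
#' pitch and amplitude. Identical `(bird, n_motifs, seed)` inputs give
#' bit-identical audio.
#'
#' @param bird a `bird_spec`
#' @param n_motifs number of motif renditions (>= 1)
#' @param seed integer seed
#' @param rate audio sampling rate, Hz (default 44150)
#' @param gap_s silent gap between syllables within a motif, s
#' @param inter_motif_s silent gap between motif renditions, s
#' @param lead_s leading/trailing silence, s
#' @return list with `clip` (an `audio_clip`) and `annotations`
#'   (data.frame: onset, offset, label, motif)
#' @export
make_song <- function(bird, n_motifs, seed = 1, rate = 44150,
                      gap_s = 0.04, inter_motif_s = 0.3, lead_s = 0.1) {
  stopifnot(inherits(bird, "bird_spec"), n_motifs >= 1)
  with_seed(child_seed(seed, 1), {
    pieces <- list()
    ann <- list()
    t_cursor <- lead_s
    pieces[[1]] <- rep(0, round(lead_s * rate))
    for (m in seq_len(n_motifs)) {
      for (k in seq_along(bird$motif_order)) {
        spec <- jitter_spec(bird$syllable_params[[bird$motif_order[k]]],
                            bird$rendition_jitter)
        y <- render_syllable(spec, rate)
        pieces[[length(pieces) + 1]] <- y
        ann[[length(ann) + 1]] <- data.frame(
          onset = t_cursor, offset = t_cursor + length(y) / rate,
          label = paste0("s", bird$motif_order[k]), motif = m,
          stringsAsFactors = FALSE)
        t_cursor <- t_cursor + length(y) / rate
        if (k < length(bird$motif_order)) {
          pieces[[length(pieces) + 1]] <- rep(0, round(gap_s * rate))
          t_cursor <- t_cursor + round(gap_s * rate) / rate
        }
      }
      gap <- if (m < n_motifs) inter_motif_s else lead_s
      pieces[[length(pieces) + 1]] <- rep(0, round(gap * rate))
      t_cursor <- t_cursor + round(gap * rate) / rate
    }
    list(clip = audio_clip(unlist(pieces), rate = rate),
         annotations = do.call(rbind, ann))
  })
}

#' Multi-unit nerve-recording model
#'
#' Singing-locked multi-unit activity is modeled as an inhomogeneous
#' Poisson event train whose rate follows a per-motif envelope template,
#' convolved with a biphasic spike kernel; all channels share a band-limited
#' (10-500 Hz) common-mode artifact up to per-channel gain (rank-1 by
#' construction), plus independent Gaussian noise. An off-nerve model has
#' zero coupling to the envelope template.
#'
#' @param envelope_template numeric vector, target activity envelope over
#'   normalized motif time (arbitrary units, >= 0); default is a smooth
#'   three-lobed profile
#' @param unit_rate_scale peak event rate during singing, events/s
#' @param spike_amp_uV per-event amplitude scale, microvolts
#' @param burst_phases normalized motif phases (in [0, 1]) at which
#'   compound population bursts occur; bursts are locked to the motif (as
#'   singing-related nerve activity is), shared across channels, and
#'   transiently boost both event rate and amplitude, producing the large
#'   envelope excursions the threshold-crossing event-rate metric counts.
#'   `NULL` disables bursts.
#' @param burst_jitter_ms per-rendition SD of each burst's timing, ms
#' @param burst_drop probability that a given burst is skipped in a
#'   rendition
#' @param burst_gain amplitude multiplier inside a burst
#' @param artifact_gain per-channel common-mode gain, microvolts RMS
#'   (scalar recycled across channels)
#' @param noise_sd independent noise SD per channel, microvolts
#' @param on_nerve logical; FALSE gives an artifact+noise-only control
#' @param n_channels number of recording channels (default 6)
#' @param rate sampling rate of the chronic recordings, Hz (default 30000)
#' @return a `nerve_model`
#' @export
nerve_model <- function(envelope_template = NULL, unit_rate_scale = 400,
                        spike_amp_uV = 40,
                        burst_phases = c(0.08, 0.2, 0.33, 0.45, 0.55,
                                         0.68, 0.8, 0.92),
                        burst_jitter_ms = 3, burst_drop = 0.1,
                        burst_gain = 2.5, artifact_gain = 60,
                        noise_sd = 8, on_nerve = TRUE,
                        n_channels = 6, rate = 30000) {
  if (is.null(envelope_template)) {
    u <- seq(0, 1, length.out = 200)
    envelope_template <- (0.15 + sin(pi * u)^2 * (1 + 0.6 * sin(3 * pi * u)))
  }
  stopifnot(all(envelope_template >= 0), n_channels >= 1)
  gains <- rep_len(artifact_gain, n_channels)
  structure(list(envelope_template = envelope_template,
                 unit_rate_scale = unit_rate_scale,
                 spike_amp_uV = spike_amp_uV,
                 burst_phases = burst_phases,
                 burst_jitter_ms = burst_jitter_ms,
                 burst_drop = burst_drop,
                 burst_gain = burst_gain,
                 artifact_gain = gains, noise_sd = noise_sd,
                 on_nerve = on_nerve, n_channels = n_channels, rate = rate),
            class = "nerve_model")
}

# Biphasic extracellular spike kernel (~1 ms): derivative of a Gaussian.
spike_kernel <- function(rate, sigma_ms = 0.25) {
  s <- sigma_ms / 1000
  t <- seq(-4 * s, 4 * s, by = 1 / rate)
  k <- -t / s^2 * exp(-t^2 / (2 * s^2))
  k / max(abs(k))
}

#' Generate a synthetic multichannel nerve recording aligned to a song
#'
#' @param annotations song annotation data.frame from [make_song()] (uses
#'   per-motif first onset / last offset to place singing-locked activity)
#' @param model a `nerve_model`
#' @param seed integer seed
#' @param duration_s total recording length, s; default covers the
#'   annotations plus 1.5 s
#' @return a `neural_traces` object; attributes `event_times` (s) and
#'   `rate_profile` carry the generator's ground truth
#' @export
make_nerve_recording <- function(annotations, model, seed = 1,
                                 duration_s = NULL) {
  stopifnot(inherits(model, "nerve_model"))
  if (is.null(duration_s)) duration_s <- max(annotations$offset) + 1.5
  rate <- model$rate
  n <- round(duration_s * rate)
  nc <- model$n_channels
  with_seed(child_seed(seed, 2), {
    # instantaneous event rate: template stretched over each motif's span
    r <- rep(2, n)  # low spontaneous rate between songs
    motifs <- split(annotations, annotations$motif)
    motif_spans <- list()
    for (mo in motifs) {
      i0 <- max(1L, round(min(mo$onset) * rate))
      i1 <- min(n, round(max(mo$offset) * rate))
      if (i1 <= i0) next
      u <- seq(0, 1, length.out = i1 - i0 + 1)
      tmpl <- stats::approx(seq(0, 1, length.out = length(model$envelope_template)),
                            model$envelope_template, xout = u)$y
      r[i0:i1] <- model$unit_rate_scale * tmpl / max(model$envelope_template)
      motif_spans[[length(motif_spans) + 1]] <- c(i0, i1)
    }
    v <- matrix(0, nrow = nc, ncol = n)
    event_idx <- integer(0)
    burst_times <- numeric(0)
    if (model$on_nerve && model$unit_rate_scale > 0 && model$spike_amp_uV > 0) {
      # compound population bursts, locked to motif phase with small
      # per-rendition timing jitter and occasional drops; shared across
      # channels, boosting event rate and amplitude over a ~4 ms window
      rate_boost <- rep(1, n)
      amp_boost <- rep(1, n)
      if (!is.null(model$burst_phases) && length(model$burst_phases) > 0) {
        half_b <- round(0.002 * rate)
        b_idx <- integer(0)
        for (sp in motif_spans) {
          for (ph in model$burst_phases) {
            if (stats::runif(1) < model$burst_drop) next
            bi <- round(sp[1] + ph * (sp[2] - sp[1]) +
                          stats::rnorm(1, sd = model$burst_jitter_ms / 1000 * rate))
            bi <- max(1L, min(n, bi))
            b_idx <- c(b_idx, bi)
            lo <- max(1L, bi - half_b); hi <- min(n, bi + half_b)
            rate_boost[lo:hi] <- 8
            amp_boost[lo:hi] <- model$burst_gain
          }
        }
        burst_times <- (b_idx - 1) / rate
      }
      p <- pmin(1, r * rate_boost / rate)
      kern <- spike_kernel(rate)
      chan_gain <- seq(1, 0.7, length.out = nc)
      # each site samples its own (overlapping) fiber population: event
      # trains are drawn independently per channel from the shared rate
      # profile, so envelopes co-vary across channels while the raw traces
      # are not collinear (and CMS cannot cancel the neural signal)
      for (c in seq_len(nc)) {
        idx <- which(stats::runif(n) < p)
        if (!length(idx)) next
        train <- rep(0, n)
        train[idx] <- model$spike_amp_uV * amp_boost[idx] *
          stats::rlnorm(length(idx), 0, 0.25)
        # short FIR convolution with the centered spike kernel
        sig <- stats::filter(train, kern, method = "convolution", sides = 2)
        sig[is.na(sig)] <- 0
        v[c, ] <- chan_gain[c] * as.numeric(sig)
        if (c == 1) event_idx <- idx
      }
    }
    if (any(model$artifact_gain > 0)) {
      art <- stats::rnorm(n)
      bf <- signal::butter(2, c(10, 500) / (rate / 2), type = "pass")
      art <- signal::filtfilt(bf, art)
      art <- art / rms(art)
      v <- v + outer(model$artifact_gain, art)
    }
    if (model$noise_sd > 0) {
      v <- v + matrix(stats::rnorm(nc * n, sd = model$noise_sd), nrow = nc)
    }
    tr <- neural_traces(v, rate = rate,
                        role = if (model$on_nerve) "on-nerve" else "off-nerve")
    attr(tr, "event_times") <- (event_idx - 1) / rate
    attr(tr, "burst_times") <- burst_times
    if (model$on_nerve && exists("rate_boost", inherits = FALSE)) {
      attr(tr, "rate_profile") <- r * rate_boost
      # expected envelope shape: event rate times squared event amplitude
      attr(tr, "envelope_drive") <- r * rate_boost * amp_boost^2
    } else {
      attr(tr, "rate_profile") <- r
      attr(tr, "envelope_drive") <- r
    }
    tr
  })
}

#' Evoked-response model: sigmoidal recruitment with additive noise
#'
#' Each simulated trial is a -5 to +25 ms peri-stimulus voltage window at
#' the acute acquisition rate, containing a large biphasic stimulation
#' artifact in `artifact_span` and a compound response in `latency_span`
#' whose peak-to-peak amplitude follows
#' `vmax / (1 + exp(-(I - i50)/slope))` in the stimulation current I.
#'
#' @param vmax saturating response amplitude, microvolts (> 0)
#' @param i50 half-activation current, microamps
#' @param slope sigmoid slope constant, microamps
#' @param baseline_noise additive white-noise RMS, microvolts
#' @param latency_span response window, ms pair (default 0.75-4)
#' @param artifact_span stimulation-artifact window, ms pair (default 0-0.5)
#' @param rate sampling rate, Hz (default 24400, the acute acquisition rate)
#' @return an `evoked_model`
#' @export
evoked_model <- function(vmax = 300, i50 = 20, slope = 5, baseline_noise = 10,
                         latency_span = c(0.75, 4), artifact_span = c(0, 0.5),
                         rate = 24400) {
  stopifnot(vmax > 0, slope > 0, latency_span[2] <= 25)
  structure(list(vmax = vmax, i50 = i50, slope = slope,
                 baseline_noise = baseline_noise,
                 latency_span = latency_span, artifact_span = artifact_span,
                 rate = rate),
            class = "evoked_model")
}

# Compound-response shape: one biphasic cycle under a Gaussian window,
# normalized to unit peak-to-peak amplitude.
response_shape <- function(t_s, center_ms = 2, sigma_ms = 0.5, f_hz = 600) {
  c0 <- center_ms / 1000
  s <- sigma_ms / 1000
  y <- sin(2 * pi * f_hz * (t_s - c0)) * exp(-(t_s - c0)^2 / (2 * s^2))
  y / (max(y) - min(y))
}

#' Simulate stimulation-evoked trials over a set of currents
#'
#' @param model an `evoked_model`
#' @param currents stimulation current amplitudes, microamps (>= 0)
#' @param n_per_current trials per current
#' @param seed integer seed
#' @param onset_jitter_ms SD of a per-trial shift of the whole trial
#'   (artifact + response) relative to the window, ms; exercises artifact
#'   alignment
#' @return list of `evoked_trial` objects (fields: current, times (s),
#'   trace (uV), rate, condition, true_onset_ms)
#' @export
make_evoked_trials <- function(model, currents, n_per_current, seed = 1,
                               onset_jitter_ms = 0) {
  stopifnot(inherits(model, "evoked_model"), all(currents >= 0))
  rate <- model$rate
  t <- seq(-5e-3, 25e-3, by = 1 / rate)
  with_seed(child_seed(seed, 3), {
    trials <- list()
    for (cur in currents) {
      amp <- model$vmax / (1 + exp(-(cur - model$i50) / model$slope))
      for (k in seq_len(n_per_current)) {
        dt <- onset_jitter_ms / 1000 * stats::rnorm(1)
        ts <- t - dt
        art <- numeric(length(t))
        a_span <- model$artifact_span / 1000
        half <- mean(a_span)
        art[ts >= a_span[1] & ts < half] <- 2000
        art[ts >= half & ts <= a_span[2]] <- -2000
        resp <- amp * response_shape(ts, center_ms = mean(model$latency_span),
                                     sigma_ms = diff(model$latency_span) / 6)
        tr <- art + resp + stats::rnorm(length(t), sd = model$baseline_noise)
        trials[[length(trials) + 1]] <- structure(
          list(current = cur, times = t, trace = tr, rate = rate,
               pattern = NA_character_, condition = "baseline",
               true_onset_ms = dt * 1000),
          class = "evoked_trial")
      }
    }
    trials
  })
}

#' Map current-steering patterns to fictive vocalizations
#'
#' Each distinct stimulation pattern maps deterministically (given the
#' seed) to its own syllable specification; `mapping_spread` scales how far
#' pattern-specific parameters deviate from a common base syllable, so 0
#' collapses all patterns onto one acoustic output. Renditions within a
#' pattern share the spec plus per-rendition jitter.
#'
#' @param patterns list of `stim_pattern` objects (distinct pattern_ids)
#' @param trials_per_pattern renditions per pattern (>= 2)
#' @param mapping_spread dimensionless spread of the pattern-to-acoustics
#'   mapping (0 = degenerate)
#' @param seed integer seed
#' @param rendition_jitter fractional per-rendition feature jitter
#' @param rate audio rate, Hz
#' @return list with `clips` (list of 200-ms `audio_clip`s), `labels`
#'   (pattern_id per clip), and `specs` (per-pattern syllable specs)
#' @export
make_fictive_vocalizations <- function(patterns, trials_per_pattern,
                                       mapping_spread = 1, seed = 1,
                                       rendition_jitter = 0.02, rate = 44150) {
  ids <- vapply(patterns, function(p) p$pattern_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate stimulation patterns")
  stopifnot(trials_per_pattern >= 2, mapping_spread >= 0)
  n_pat <- length(patterns)
  specs <- with_seed(child_seed(seed, 4), {
    lapply(seq_len(n_pat), function(i) {
      # base syllable, displaced per pattern by mapping_spread
      f0 <- 1500 * exp(mapping_spread * stats::runif(1, -0.7, 0.7))
      f1 <- f0 * exp(mapping_spread * stats::runif(1, -0.35, 0.35))
      syllable_spec(
        duration = min(0.3, max(0.05, 0.12 * (1 + mapping_spread * stats::runif(1, -0.4, 0.4)))),
        pitch_traj = pmin(7500, pmax(350, c(f0, f1))),
        am_rate = 15 * exp(mapping_spread * stats::runif(1, -0.8, 0.8)),
        fm_depth = mapping_spread * stats::runif(1, 0, 120),
        entropy_level = -3 + mapping_spread * stats::runif(1, -2, 1.5),
        amplitude = 0.6)
    })
  })
  with_seed(child_seed(seed, 5), {
    clips <- list()
    labels <- character(0)
    n200 <- round(0.2 * rate)
    for (i in seq_len(n_pat)) {
      for (k in seq_len(trials_per_pattern)) {
        sp <- jitter_spec(specs[[i]], rendition_jitter)
        y <- render_syllable(sp, rate)
        pad <- n200 - length(y)
        if (pad < 0) y <- y[seq_len(n200)] else y <- c(y, rep(0, pad))
        y <- y + stats::rnorm(n200, sd = 1e-4)  # mic noise floor
        clips[[length(clips) + 1]] <- audio_clip(y, rate = rate)
        labels <- c(labels, ids[i])
      }
    }
    list(clips = clips, labels = labels, specs = specs)
  })
}
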