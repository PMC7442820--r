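#' Audio clip container
#'
#' A mono waveform with its sampling rate and an absolute start time. All
#' vocal analyses in the package operate on this container. Amplitudes are
#' dimensionless in [-1, 1] (full-scale PCM maps to +/-1).
#'
#' @param samples numeric vector of amplitudes in [-1, 1]
#' @param rate sampling rate in Hz (default 44150, the acquisition rate of
#'   the song recordings this pipeline targets)
#' @param start_time clip start in seconds on the experiment clock
#' @return an object of class `audio_clip`
#' @export
audio_clip <- function(samples, rate = 44150, start_time = 0) {
  stopifnot(is.numeric(samples), rate > 0, all(is.finite(samples)))
  structure(
    list(samples = as.numeric(samples), rate = rate, start_time = start_time),
    class = "audio_clip"
  )
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip: %.3f s at %g Hz, start %.3f s>\n",
              length(x$samples) / x$rate, x$rate, x$start_time))
  invisible(x)
}

#' Duration of an audio clip in seconds
#' @param clip an `audio_clip`
#' @export
clip_duration <- function(clip) length(clip$samples) / clip$rate

#' Write an audio clip to a 16-bit PCM WAV file
#'
#' @param clip an `audio_clip`; samples are clipped to [-1, 1]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- pmax(-1, pmin(1, clip$samples))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(pcm)
  data_bytes <- 2L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(clip$rate), con, size = 4, endian = "little")
  writeBin(as.integer(clip$rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file into an audio clip
#' @param path WAV file path
#' @return an `audio_clip`
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file: ", path)
  rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      channels <- fmt[2]
      rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (sz > 16) invisible(readBin(con, raw(), n = sz - 16))
    } else if (identical(id, "data")) {
      samples <- readBin(con, integer(), n = sz / 2, size = 2,
                         signed = TRUE, endian = "little")
      break
    } else {
      invisible(readBin(con, raw(), n = sz))
    }
  }
  if (is.null(samples)) stop("no data chunk in ", path)
  if (!identical(bits, 16L)) stop("only 16-bit PCM supported")
  if (!identical(channels, 1L)) stop("only mono WAV supported")
  audio_clip(pmax(-1, samples / 32767), rate = rate)
}

#' Short-time power spectrogram
#'
#' Hann-windowed power spectra on a regular grid of frame centers. When
#' `pad = "reflect"` the waveform is reflect-padded so a frame exists for
#' every requested center, including the edges.
#'
#' @param x numeric waveform
#' @param rate sampling rate, Hz
#' @param window_s analysis window length, seconds
#' @param hop_s frame advance, seconds
#' @param nfft FFT length (zero-padded if longer than the window)
#' @param pad `"reflect"` (frame centers every hop over the whole signal) or
#'   `"valid"` (only fully supported frames)
#' @return list with `power` (bins x frames), `freq` (Hz), `times` (s, frame
#'   centers)
#' @export
stft_power <- function(x, rate, window_s = 0.010, hop_s = 0.001,
                       nfft = 512, pad = c("reflect", "valid")) {
  pad <- match.arg(pad)
  wlen <- max(2L, round(window_s * rate))
  hop <- max(1L, round(hop_s * rate))
  nfft <- max(nfft, wlen)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(wlen) / (wlen + 1))  # Hann
  n <- length(x)
  half <- wlen %/% 2
  if (pad == "reflect") {
    centers <- seq(1L, n, by = hop)
    lpad <- min(half, n - 1)
    rpad <- min(wlen, n - 1)
    xp <- c(rev(x[seq_len(lpad) + 1]), x, x[n - seq_len(rpad)])
    starts <- centers - half + lpad
    starts <- pmax(1L, pmin(starts, length(xp) - wlen + 1L))
  } else {
    starts <- seq(1L, n - wlen + 1L, by = hop)
    centers <- starts + half
    xp <- x
    starts <- starts
  }
  nb <- nfft %/% 2 + 1L
  pow <- matrix(0, nrow = nb, ncol = length(starts))
  for (j in seq_along(starts)) {
    seg <- xp[starts[j]:(starts[j] + wlen - 1L)]
    seg <- seg * win
    sp <- stats::fft(c(seg, rep(0, nfft - wlen)))
    pow[, j] <- Mod(sp[seq_len(nb)])^2
  }
  list(power = pow,
       freq = (seq_len(nb) - 1) * rate / nfft,
       times = (centers - 1) / rate)
}

# Log-magnitude spectrogram frames restricted to the song band; the common
# frame representation used by the song detector, DTW alignment and the
# syllable classifier.
log_spec_frames <- function(x, rate, window_s = 0.010, hop_s = 0.001,
                            nfft = 512, band = c(300, 8000), floor_db = -100) {
  sp <- stft_power(x, rate, window_s, hop_s, nfft)
  keep <- sp$freq >= band[1] & sp$freq <= band[2]
  lp <- 10 * log10(sp$power[keep, , drop = FALSE] + 10^(floor_db / 10))
  list(frames = lp, freq = sp$freq[keep], times = sp$times)
}
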