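#' Current-steering stimulation pattern on the 2 x 3 electrode grid
#'
#' Each of the six electrode sites takes a role: cathodic-leading source
#' (`"source"`), anodic-leading source (`"anodic"`), `"return"`, or
#' `"off"`. Stimulation is delivered as 1 kHz bursts of 100 biphasic
#' pulses, 200 us per phase, charge-balanced by construction (equal phase
#' widths and amplitudes of opposite sign).
#'
#' @param pattern_id token naming the pattern
#' @param roles character vector of length 6 (grid in row-major order,
#'   2 rows x 3 columns) over {"source", "anodic", "return", "off"}
#' @param amplitude total source current, uA
#' @param pulses pulses per burst (default 100)
#' @param pulse_rate intra-burst rate, Hz (default 1000)
#' @param phase_width phase width, us (default 200)
#' @return a `stim_pattern`
#' @export
stim_pattern <- function(pattern_id, roles, amplitude = 100, pulses = 100,
                         pulse_rate = 1000, phase_width = 200) {
  roles <- match.arg(roles, c("source", "anodic", "return", "off"),
                     several.ok = TRUE)
  if (length(roles) != 6) stop("roles must cover the 2 x 3 grid (6 sites)")
  structure(list(pattern_id = as.character(pattern_id), roles = roles,
                 amplitude = amplitude, pulses = pulses,
                 pulse_rate = pulse_rate, phase_width = phase_width,
                 phase_width_anodic = phase_width),
            class = "stim_pattern")
}

#' Validate a stimulation pattern or pattern set
#'
#' Checks each pattern for at least one source, at least one return, and
#' per-pulse charge balance (equal cathodic/anodic phase widths); across a
#' set, checks that the total source current is constant, as required when
#' contrasting spatial patterns at matched net current.
#'
#' @param patterns a `stim_pattern` or list of them
#' @return list: `ok` (logical), `violations` (character vector, empty
#'   when ok)
#' @export
validate_pattern <- function(patterns) {
  if (inherits(patterns, "stim_pattern")) patterns <- list(patterns)
  v <- character(0)
  amps <- numeric(0)
  for (p in patterns) {
    src <- sum(p$roles %in% c("source", "anodic"))
    ret <- sum(p$roles == "return")
    if (src < 1) v <- c(v, paste0(p$pattern_id, ": no source electrode"))
    if (ret < 1) v <- c(v, paste0(p$pattern_id, ": no return electrode"))
    if (!isTRUE(all.equal(p$phase_width, p$phase_width_anodic)))
      v <- c(v, paste0(p$pattern_id, ": unbalanced phase widths"))
    if (p$amplitude <= 0)
      v <- c(v, paste0(p$pattern_id, ": non-positive amplitude"))
    amps <- c(amps, p$amplitude)
  }
  if (length(patterns) > 1 && length(unique(amps)) > 1)
    v <- c(v, "total source current differs across the pattern set")
  list(ok = length(v) == 0, violations = v)
}

#' Build a set of distinct steering patterns at constant total current
#'
#' Enumerates single-source and paired-source role assignments over the
#' 2 x 3 grid until `n` distinct patterns are produced, all at the same
#' total current.
#'
#' @param n number of patterns (<= 24)
#' @param amplitude total source current, uA
#' @return list of `stim_pattern`s
#' @export
make_steering_patterns <- function(n = 24, amplitude = 100) {
  stopifnot(n >= 1, n <= 24)
  pats <- list()
  add <- function(roles) {
    id <- sprintf("p%02d", length(pats) + 1L)
    pats[[length(pats) + 1L]] <<- stim_pattern(id, roles, amplitude)
  }
  # single source, single return over distinct site pairs
  for (s in 1:6) for (r in 1:6) {
    if (length(pats) >= n) break
    if (s == r) next
    roles <- rep("off", 6)
    roles[s] <- "source"; roles[r] <- "return"
    add(roles)
  }
  pats[seq_len(n)]
}

#' Vectorize a fictive vocalization as a flattened log-spectrogram
#'
#' Takes the 200 ms of audio from stimulation onset, computes a
#' spectrogram with a 5 ms window, 1 ms advance and a 512-point transform,
#' discards rows above 8 kHz (leaving 91 frequency bins at the 44 150 Hz
#' acquisition rate: bins 1-91, 86-7847 Hz, DC excluded), and flattens the
#' 200 x 91 matrix to an 18 200-element vector (log magnitude with a fixed
#' floor).
#'
#' @param clip an `audio_clip` covering `onset` + 200 ms
#' @param onset stimulation onset within the clip, s
#' @param duration_s analysis span, s (default 0.2)
#' @param nfft transform length (default 512)
#' @param floor_db log floor, dB (default -120)
#' @return numeric vector of length timesteps x bins (default 18 200),
#'   with attributes `dim_spec = c(timesteps, bins)` and `label` unset
#' @export
vectorize_vocalization <- function(clip, onset = 0, duration_s = 0.2,
                                   nfft = 512, floor_db = -120) {
  stopifnot(inherits(clip, "audio_clip"))
  n_need <- round((onset + duration_s) * clip$rate)
  if (n_need > length(clip$samples))
    stop("clip too short: needs ", duration_s, " s of audio after onset")
  i0 <- round(onset * clip$rate) + 1L
  x <- clip$samples[i0:(i0 + round(duration_s * clip$rate) - 1L)]
  n_steps <- round(duration_s * 1000)
  sp <- stft_power(x, clip$rate, window_s = 0.005, hop_s = 0.001,
                   nfft = nfft, pad = "reflect")
  pow <- sp$power[, seq_len(min(n_steps, ncol(sp$power))), drop = FALSE]
  if (ncol(pow) < n_steps)
    pow <- cbind(pow, pow[, rep(ncol(pow), n_steps - ncol(pow))])
  # DC excluded; a bin is kept only if its full band (one bin width above
  # its center) stays at or below 8 kHz — 91 bins at the default 512-point
  # transform and 44 150 Hz rate (86-7847 Hz)
  bw <- clip$rate / nfft
  keep <- which(sp$freq > 0 & sp$freq + bw <= 8000)
  pow <- pow[keep, , drop = FALSE]
  lsp <- 10 * log10(pow + 10^(floor_db / 10))
  v <- as.numeric(lsp)  # timestep blocks of 91 bins (bin varies fastest)
  attr(v, "dim_spec") <- c(timesteps = n_steps, bins = nrow(lsp))
  v
}

#' Embed vocalization vectors in 2-D (PCA to 50, then t-SNE)
#'
#' Dimensionality is first reduced to 50 principal components (capped at
#' n - 1 with a warning when fewer vectors are supplied), then embedded in
#' two dimensions by t-SNE with Euclidean distances and perplexity 35
#' (auto-reduced with a warning when the sample is too small to support
#' it). The t-SNE run is initialized from the first two principal
#' components, scaled small, so the embedding is reproducible for a fixed
#' seed.
#'
#' @param vectors matrix (vocalizations x dimensions) or list of vectors
#'   from [vectorize_vocalization()]
#' @param n_components PCA dimensionality (default 50)
#' @param perplexity t-SNE perplexity (default 35)
#' @param n_iter t-SNE iterations (default 500)
#' @param seed integer seed
#' @return data.frame with `x`, `y`; attributes `seed`, `perplexity`,
#'   `n_components`
#' @export
embed_vocalizations <- function(vectors, n_components = 50, perplexity = 35,
                                n_iter = 500, seed = 1) {
  X <- if (is.list(vectors)) do.call(rbind, vectors) else as.matrix(vectors)
  n <- nrow(X)
  if (n <= n_components) {
    warning("fewer vectors than requested components; capping at n - 1")
    n_components <- n - 1
  }
  if (3 * perplexity >= n - 1) {
    perplexity <- max(2, floor((n - 2) / 3))
    warning("perplexity too large for ", n, " points; reduced to ",
            perplexity)
  }
  pc <- stats::prcomp(X, rank. = n_components, center = TRUE, scale. = FALSE)
  Z <- pc$x
  init <- Z[, 1:2, drop = FALSE]
  init <- init / stats::sd(init[, 1]) * 1e-4
  Y <- tsne_embed(Z, dims = 2, perplexity = perplexity, n_iter = n_iter,
                  init = init, seed = seed)
  out <- data.frame(x = Y[, 1], y = Y[, 2])
  attr(out, "seed") <- seed
  attr(out, "perplexity") <- perplexity
  attr(out, "n_components") <- n_components
  out
}

#' k-nearest-neighbor label purity of an embedding
#'
#' Fraction of points whose k nearest neighbors (Euclidean, excluding the
#' point itself) share the point's label, averaged over points — a simple
#' cluster-recovery diagnostic for labeled embeddings.
#'
#' @param coords matrix or data.frame of embedded coordinates
#' @param labels one label per point
#' @param k neighbors (default 5)
#' @return mean neighbor label agreement in [0, 1]
#' @export
knn_label_purity <- function(coords, labels, k = 5) {
  X <- as.matrix(coords)
  n <- nrow(X)
  sq <- rowSums(X^2)
  D <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  diag(D) <- Inf
  mean(vapply(seq_len(n), function(i) {
    nb <- order(D[i, ])[seq_len(k)]
    mean(labels[nb] == labels[i])
  }, numeric(1)))
}

#' Mean silhouette width of an embedding under given labels
#'
#' @param coords embedded coordinates
#' @param labels cluster labels
#' @return mean silhouette width (positive values mean points sit closer
#'   to their own pattern's vocalizations than to any other pattern's)
#' @export
embedding_silhouette <- function(coords, labels) {
  X <- as.matrix(coords)
  n <- nrow(X)
  labs <- unique(labels)
  if (length(labs) < 2) stop("need >= 2 labels")
  sq <- rowSums(X^2)
  D <- sqrt(pmax(outer(sq, sq, "+") - 2 * tcrossprod(X), 0))
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(labs[labs != labels[i]], function(l)
      mean(D[i, labels == l]), numeric(1)))
    if (is.nan(a)) return(0)
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
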