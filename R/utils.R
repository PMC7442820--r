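#' Evaluate an expression under a fixed RNG seed, restoring RNG state
#'
#' All generators in the package route their randomness through this helper
#' so that identical (spec, seed) inputs produce identical outputs without
#' disturbing the caller's random stream.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream index; keeps every
# derived seed inside the 32-bit signed-integer range R requires.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k) * 104729 + 12345) %% 2147483647)
}

# Boxcar (moving-average) smoothing with edge renormalization: each output
# sample is the mean of the available input samples in the window, so the
# ends are not biased toward zero.
boxcar_smooth <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width == 1L) return(x)
  k <- rep(1, width)
  num <- stats::filter(x, k, sides = 2)
  den <- stats::filter(rep(1, length(x)), k, sides = 2)
  # stats::filter leaves NA where the window overhangs; recompute edges
  out <- as.numeric(num / den)
  na <- which(is.na(out))
  half <- width %/% 2
  for (i in na) {
    lo <- max(1L, i - half)
    hi <- min(length(x), i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

rms <- function(x) sqrt(mean(x^2))

# Runs of TRUE in a logical vector, as a 2-column matrix of start/end indices.
logical_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Merge sorted intervals (2-col matrix, seconds) closer than `gap`.
merge_intervals <- function(iv, gap = 0) {
  if (is.null(iv) || nrow(iv) == 0) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
    if (iv[i, 1] <= out[nrow(out), 2] + gap) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[i, 2])
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  out
}
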