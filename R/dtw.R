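#' Band-constrained dynamic time warping of feature-frame sequences
#'
#' DTW over columns of two feature matrices with Euclidean frame cost,
#' the slope-constrained symmetric P = 1 step pattern (allowed moves
#' (1,1), (2,1) and (1,2), so the local warp slope stays within [1/2, 2])
#' and a Sakoe-Chiba band. The slope constraint prevents the degenerate
#' collapse of quasi-stationary stretches onto single frames that
#' unconstrained step patterns permit. Boundary-anchored: the path maps
#' first frame to first frame and last frame to last frame.
#'
#' @param a,b feature matrices (features x frames); frames are compared by
#'   Euclidean distance
#' @param band Sakoe-Chiba half-width in frames (frames are 1 ms apart for
#'   the song spectrogram frontend, so the default 100 means +/-100 ms);
#'   `Inf` disables the constraint
#' @return list with `path` (2-column matrix of (a-frame, b-frame) index
#'   pairs, monotone, boundary-anchored) and `cost` (accumulated weighted
#'   distance normalized by n + m)
#' @export
dtw_align <- function(a, b, band = 100) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  n <- ncol(a)
  m <- ncol(b)
  if (n < 1 || m < 1) stop("empty frame sequence")
  if (n > 2 * m || m > 2 * n)
    stop("sequences differ by more than 2x; slope-constrained warp infeasible")
  if (n == 1 && m == 1)
    return(list(path = cbind(1L, 1L), cost = 0))
  if (n == 1 || m == 1) stop("sequences too short to warp")
  band <- max(band, abs(n - m) + 2)
  D <- matrix(Inf, n, m)
  B <- matrix(0L, n, m)  # 1 = (1,1); 2 = (2,1); 3 = (1,2)
  a2 <- colSums(a^2)
  b2 <- colSums(b^2)
  dist_row <- function(i, jj)
    sqrt(pmax(0, a2[i] + b2[jj] - 2 *
                as.numeric(crossprod(a[, i], b[, jj, drop = FALSE]))))
  # frame distances are needed for the current and previous row
  jidx <- function(i) {
    jc <- round(i * m / n)
    max(1L, jc - band):min(m, jc + band)
  }
  dprev <- rep(Inf, m)
  jj <- jidx(1)
  dcur <- rep(Inf, m)
  dcur[jj] <- dist_row(1, jj)
  D[1, 1] <- 2 * dcur[1]
  for (i in 2:n) {
    dprev2 <- dprev
    dprev <- dcur
    jj <- jidx(i)
    dcur <- rep(Inf, m)
    dcur[jj] <- dist_row(i, jj)
    for (j in jj) {
      if (j == 1) {
        # only a vertical-ish entry could reach column 1, but the slope
        # constraint forbids it beyond the origin
        next
      }
      best <- Inf; move <- 0L
      v <- D[i - 1, j - 1] + 2 * dcur[j]
      if (v < best) { best <- v; move <- 1L }
      if (i > 2) {
        v <- D[i - 2, j - 1] + 2 * dprev[j] + dcur[j]
        if (v < best) { best <- v; move <- 2L }
      }
      if (j > 2) {
        v <- D[i - 1, j - 2] + 2 * dcur[j - 1] + dcur[j]
        if (v < best) { best <- v; move <- 3L }
      }
      if (is.finite(best)) {
        D[i, j] <- best
        B[i, j] <- move
      }
    }
  }
  if (!is.finite(D[n, m])) stop("no admissible warp path within the band")
  # backtrack, inserting the intermediate cell of the (2,1)/(1,2) steps
  path <- matrix(0L, 2 * (n + m), 2)
  i <- n; j <- m; k <- 0L
  repeat {
    k <- k + 1L
    path[k, ] <- c(i, j)
    if (i == 1 && j == 1) break
    mv <- B[i, j]
    if (mv == 1L) { i <- i - 1L; j <- j - 1L }
    else if (mv == 2L) {
      k <- k + 1L; path[k, ] <- c(i - 1L, j)
      i <- i - 2L; j <- j - 1L
    } else if (mv == 3L) {
      k <- k + 1L; path[k, ] <- c(i, j - 1L)
      i <- i - 1L; j <- j - 2L
    } else stop("broken backtrack state")
  }
  path <- path[k:1, , drop = FALSE]
  list(path = path, cost = D[n, m] / (n + m))
}
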