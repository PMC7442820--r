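#' Exact t-SNE embedding
#'
#' Full (non-approximate) t-distributed stochastic neighbor embedding with
#' Euclidean input distances: per-point Gaussian bandwidths found by
#' binary search to match the target perplexity, symmetrized affinities,
#' early exaggeration, and momentum gradient descent on the
#' Student-t low-dimensional affinities. Suitable for the few hundred to
#' few thousand points this pipeline embeds. Deterministic for a fixed
#' seed and initialization.
#'
#' @param X numeric matrix, points x dimensions
#' @param dims output dimensionality (default 2)
#' @param perplexity target perplexity (effective neighborhood size);
#'   must satisfy `3 * perplexity < n - 1`
#' @param n_iter gradient-descent iterations (default 500)
#' @param eta learning rate (default 200)
#' @param exaggeration early-exaggeration factor over the first 100
#'   iterations (default 12)
#' @param init optional n x dims initial configuration (e.g. a scaled PCA
#'   projection); default small seeded Gaussian
#' @param seed integer seed
#' @return n x dims matrix of embedded coordinates
#' @export
tsne_embed <- function(X, dims = 2, perplexity = 35, n_iter = 500,
                       eta = 200, exaggeration = 12, init = NULL, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("too few points to embed")
  if (3 * perplexity >= n - 1)
    stop("perplexity too large for ", n, " points")
  # pairwise squared Euclidean distances
  sq <- rowSums(X^2)
  D2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(X), 0)
  diag(D2) <- 0
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1; beta_lo <- -Inf; beta_hi <- Inf
    for (it in 1:60) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { H <- 0 } else {
        H <- log(sw) + beta * sum(di * w) / sw
      }
      err <- H - logU
      if (abs(err) < 1e-5) break
      if (err > 0) {
        beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else {
        beta_hi <- beta
        beta <- if (is.finite(beta_lo)) (beta + beta_lo) / 2 else beta / 2
      }
    }
    w <- exp(-di * beta)
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- if (is.null(init)) {
    with_seed(child_seed(seed, 10),
              matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims))
  } else {
    as.matrix(init)
  }
  stopifnot(nrow(Y) == n, ncol(Y) == dims)
  gains <- matrix(1, n, dims)
  inc <- matrix(0, n, dims)
  Pex <- P * exaggeration
  for (iter in seq_len(n_iter)) {
    Puse <- if (iter <= 100) Pex else P
    momentum <- if (iter <= 250) 0.5 else 0.8
    sqy <- rowSums(Y^2)
    num <- 1 / (1 + pmax(outer(sqy, sqy, "+") - 2 * tcrossprod(Y), 0))
    diag(num) <- 0
    Q <- num / sum(num)
    Q <- pmax(Q, 1e-12)
    L <- (Puse - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- momentum * inc - eta * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
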