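#' Empirical similarity null from unrelated songs
#'
#' The similarity scale is defined by unrelated song pairs: for every pair
#' of feature tracks from distinct birds, the median five-dimensional
#' Euclidean distance over millisecond-by-millisecond frame comparisons is
#' computed; the sorted set of these per-pair median distances is the null
#' cumulative distribution that converts an observed median distance into
#' a P value (the similarity score). Features are z-scored by the pooled
#' per-frame mean/SD of the null songs before any distance is taken, so
#' the five features contribute on commensurate scales and a global gain
#' change (a pure envelope-dB shift) is absorbed by the centering.
#'
#' @param tracks list of `feature_track`s of unrelated songs (>= 2)
#' @param bird_ids character vector, one id per track; >= 2 distinct ids
#'   required, and only cross-bird pairs enter the null
#' @param pair_cap maximum frame pairs per song pair for the median
#'   (uniform deterministic subsample above the cap)
#' @param pairing `"aligned"` (default) pairs frame i of one track with
#'   frame i of the other, so identical tracks have median distance 0 and
#'   score exactly 1; `"cartesian"` uses the full cross product of frames
#' @return a `similarity_null`: sorted `distances` (one per unrelated
#'   pair), `n_songs`, `scaler` (per-feature center/scale), `n_pairs`,
#'   `pairing`
#' @export
build_null <- function(tracks, bird_ids, pair_cap = 1e6,
                       pairing = c("aligned", "cartesian")) {
  pairing <- match.arg(pairing)
  stopifnot(length(tracks) >= 2, length(bird_ids) == length(tracks))
  if (length(unique(bird_ids)) < 2)
    stop("null requires tracks from >= 2 distinct birds")
  scaler <- fit_feature_scaler(tracks)
  mats <- lapply(tracks, scale_track, scaler = scaler)
  dists <- c()
  n <- length(tracks)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (bird_ids[i] == bird_ids[j]) next
    dists <- c(dists, median_frame_distance(mats[[i]], mats[[j]], pair_cap,
                                            pairing))
  }
  if (any(dists == 0))
    warning("degenerate null: zero distances between 'unrelated' songs; ",
            "downstream scores will collapse")
  structure(list(distances = sort(dists), n_songs = n, scaler = scaler,
                 n_pairs = length(dists), pairing = pairing),
            class = "similarity_null")
}

# Pooled per-feature center/scale over all frames of the supplied tracks.
# Pitch statistics use voiced frames only.
fit_feature_scaler <- function(tracks) {
  feats <- c("pitch", "fm", "am", "wiener_entropy", "envelope")
  pooled <- do.call(rbind, lapply(tracks, function(tr)
    as.matrix(tr[, feats])))
  voiced <- unlist(lapply(tracks, function(tr) tr$voiced))
  center <- numeric(5); scale <- numeric(5)
  for (k in seq_along(feats)) {
    v <- pooled[, k]
    if (feats[k] == "pitch") v <- v[voiced]
    v <- v[is.finite(v)]
    center[k] <- mean(v)
    s <- stats::sd(v)
    scale[k] <- if (is.finite(s) && s > 0) s else 1
  }
  list(features = feats, center = center, scale = scale)
}

# Track -> frames x 5 matrix of z-scored features; unvoiced pitch is NA.
scale_track <- function(track, scaler) {
  m <- as.matrix(track[, scaler$features])
  m[!track$voiced, 1] <- NA
  sweep(sweep(m, 2, scaler$center), 2, scaler$scale, "/")
}

# Median Euclidean distance over ms-frame pairs of two scaled tracks.
# "aligned" pairs frame i with frame i (truncating to the common length);
# "cartesian" uses the full cross product, thinning each track's frames
# evenly above `cap` total pairs (deterministic and symmetric). Frame
# pairs with an unvoiced member drop the pitch dimension and rescale by
# sqrt(5/4) so distances stay comparable.
median_frame_distance <- function(a, b, cap = 1e6,
                                  pairing = c("aligned", "cartesian")) {
  pairing <- match.arg(pairing)
  if (pairing == "aligned") {
    nn <- min(nrow(a), nrow(b))
    if (nn > cap) {
      idx <- unique(round(seq(1, nn, length.out = cap)))
    } else idx <- seq_len(nn)
    aa <- a[idx, , drop = FALSE]; bb <- b[idx, , drop = FALSE]
    dp <- (aa[, 1] - bb[, 1])^2
    d4 <- rowSums((aa[, 2:5, drop = FALSE] - bb[, 2:5, drop = FALSE])^2)
    d <- ifelse(is.na(dp), sqrt(d4 * 5 / 4), sqrt(d4 + dp))
    return(stats::median(d))
  }
  na <- nrow(a); nb <- nrow(b)
  if (na * nb > cap) {
    keep <- ceiling(sqrt(cap))
    a <- a[unique(round(seq(1, na, length.out = min(na, keep)))), , drop = FALSE]
    b <- b[unique(round(seq(1, nb, length.out = min(nb, keep)))), , drop = FALSE]
  }
  a4 <- a[, 2:5, drop = FALSE]; b4 <- b[, 2:5, drop = FALSE]
  # squared distances over the 4 always-present features
  d4 <- outer(rowSums(a4^2), rowSums(b4^2), "+") - 2 * a4 %*% t(b4)
  pa <- a[, 1]; pb <- b[, 1]
  dp <- outer(pa, pb, function(x, y) (x - y)^2)
  have_pitch <- !is.na(dp)
  d <- matrix(0, nrow(a), nrow(b))
  d[have_pitch] <- sqrt(pmax(0, d4[have_pitch] + dp[have_pitch]))
  d[!have_pitch] <- sqrt(pmax(0, d4[!have_pitch]) * 5 / 4)
  stats::median(d)
}

#' Acoustic similarity score of two feature tracks
#'
#' The median z-scored five-dimensional distance over
#' millisecond-by-millisecond frame pairs is converted into a P value
#' against the null's cumulative distribution: score = 1 - ECDF(median
#' distance), with right-continuous ECDF and ties counted as less-or-equal.
#' A score of 1 means acoustically identical (median distance below every
#' null distance); 0 means as different as unrelated songs.
#'
#' @param a,b `feature_track`s
#' @param null a `similarity_null`
#' @param pair_cap frame-pair cap, as in [build_null()]
#' @return a `similarity_score`: list(value in [0,1], median_distance,
#'   n_pairs)
#' @export
similarity <- function(a, b, null, pair_cap = 1e6) {
  stopifnot(inherits(null, "similarity_null"), nrow(a) > 0, nrow(b) > 0)
  ma <- scale_track(a, null$scaler)
  mb <- scale_track(b, null$scaler)
  d <- median_frame_distance(ma, mb, pair_cap, null$pairing)
  value <- 1 - mean(null$distances <= d)
  structure(list(value = value, median_distance = d,
                 n_pairs = min(nrow(ma) * nrow(mb), pair_cap)),
            class = "similarity_score")
}

#' Baseline-to-post acoustic-similarity time course
#'
#' Quantifies how similar post-manipulation song is to pre-manipulation
#' song, day by day: similarity is computed for syllable-matched
#' comparisons (pre vs post renditions of the same syllable label), the
#' per-day mean is taken over all comparisons, and the course is
#' normalized to the mean pre-vs-pre (baseline) similarity.
#'
#' @param pre_tracks list of `feature_track`s of pre-manipulation syllables
#' @param pre_labels syllable labels for `pre_tracks`
#' @param post_by_day named list (one element per day) of lists of
#'   `feature_track`s
#' @param post_labels_by_day labels parallel to `post_by_day`
#' @param null a `similarity_null`
#' @param max_pairs_per_class cap on pre x post comparisons per syllable
#'   class and day
#' @return data.frame: day, mean_similarity, normalized, n_comparisons;
#'   attribute `missing_classes` lists labels absent on some day
#' @export
baseline_similarity_course <- function(pre_tracks, pre_labels, post_by_day,
                                       post_labels_by_day, null,
                                       max_pairs_per_class = 50) {
  stopifnot(length(pre_tracks) >= 1, length(post_by_day) >= 1)
  # baseline: pre vs pre within class
  base_scores <- class_matched_scores(pre_tracks, pre_labels,
                                      pre_tracks, pre_labels, null,
                                      max_pairs_per_class, skip_self = TRUE)
  base_mean <- mean(base_scores$score)
  missing <- character(0)
  rows <- lapply(seq_along(post_by_day), function(d) {
    sc <- class_matched_scores(pre_tracks, pre_labels,
                               post_by_day[[d]], post_labels_by_day[[d]],
                               null, max_pairs_per_class)
    absent <- setdiff(unique(pre_labels), unique(post_labels_by_day[[d]]))
    if (length(absent))
      missing <<- union(missing, paste0("day", d, ":", absent))
    data.frame(day = d, mean_similarity = mean(sc$score),
               normalized = mean(sc$score) / base_mean,
               n_comparisons = nrow(sc))
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline_mean") <- base_mean
  attr(out, "missing_classes") <- missing
  out
}

# All cross-set similarity scores between same-label tracks (intersection
# of label sets), capped per class.
class_matched_scores <- function(tracks_a, labels_a, tracks_b, labels_b,
                                 null, cap = 50, skip_self = FALSE) {
  common <- intersect(unique(labels_a), unique(labels_b))
  res <- list()
  for (cl in common) {
    ia <- which(labels_a == cl)
    ib <- which(labels_b == cl)
    pairs <- expand.grid(i = ia, j = ib)
    if (skip_self) pairs <- pairs[pairs$i != pairs$j, , drop = FALSE]
    if (nrow(pairs) == 0) next
    if (nrow(pairs) > cap)
      pairs <- pairs[round(seq(1, nrow(pairs), length.out = cap)), ]
    sc <- vapply(seq_len(nrow(pairs)), function(k)
      similarity(tracks_a[[pairs$i[k]]], tracks_b[[pairs$j[k]]], null)$value,
      numeric(1))
    res[[cl]] <- data.frame(label = cl, score = sc)
  }
  if (!length(res)) stop("no shared syllable classes to compare")
  do.call(rbind, res)
}

#' Within- vs across-label similarity
#'
#' Mean pairwise similarity among same-label vocalizations versus the mean
#' over different-label pairs — the specificity statistic for
#' current-steering stimulation (labels = stimulation patterns) and for
#' natural song (labels = syllable types). Labels with a single trial
#' cannot contribute within-pairs and are reported.
#'
#' @param tracks list of `feature_track`s
#' @param labels one label per track (>= 2 labels, >= 2 trials per label
#'   for the within mean)
#' @param null a `similarity_null`
#' @param max_pairs cap on sampled pairs in each class of pair
#' @param seed seed for pair subsampling when above the cap
#' @return list: within_mean, across_mean, n_within, n_across,
#'   singleton_labels
#' @export
within_across_similarity <- function(tracks, labels, null,
                                     max_pairs = 400, seed = 1) {
  stopifnot(length(tracks) == length(labels))
  if (length(unique(labels)) < 2) stop("need >= 2 labels")
  n <- length(tracks)
  pairs <- t(utils::combn(n, 2))
  same <- labels[pairs[, 1]] == labels[pairs[, 2]]
  singletons <- names(which(table(labels) < 2))
  score_pairs <- function(pp) {
    if (nrow(pp) > max_pairs) {
      pp <- with_seed(child_seed(seed, 7),
                      pp[sample(nrow(pp), max_pairs), , drop = FALSE])
    }
    vapply(seq_len(nrow(pp)), function(k)
      similarity(tracks[[pp[k, 1]]], tracks[[pp[k, 2]]], null)$value,
      numeric(1))
  }
  w <- score_pairs(pairs[same, , drop = FALSE])
  a <- score_pairs(pairs[!same, , drop = FALSE])
  list(within_mean = mean(w), across_mean = mean(a),
       n_within = length(w), n_across = length(a),
       singleton_labels = singletons)
}
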