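test_that("similarity scale: identical tracks score 1, scores stay in [0,1], symmetry holds", {
  nl <- fx_null()
  null <- nl$null
  expect_true(all(null$distances > 0))
  tr <- nl$tracks[[1]]
  expect_equal(similarity(tr, tr, null)$value, 1)
  ab <- similarity(nl$tracks[[1]], nl$tracks[[2]], null)
  ba <- similarity(nl$tracks[[2]], nl$tracks[[1]], null)
  expect_equal(ab$value, ba$value)
  vals <- vapply(2:6, function(i)
    similarity(nl$tracks[[1]], nl$tracks[[i]], null)$value, numeric(1))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("null construction requires distinct birds and flags degenerate nulls", {
  nl <- fx_null()
  expect_error(build_null(nl$tracks[1:3], c("x", "x", "x")), "distinct")
  expect_warning(build_null(list(nl$tracks[[1]], nl$tracks[[1]]),
                            c("a", "b")), "degenerate")
  expect_equal(nl$null$n_pairs, choose(12, 2))
  expect_false(is.unsorted(nl$null$distances))
})

test_that("the null is invariant to a global amplitude gain on its input songs", {
  tracks <- lapply(1:4, function(i) {
    b <- bird_spec(paste0("g", i), seed = 200 + i)
    s <- make_song(b, 1, seed = 250 + i)
    compute_features(s$clip, s$annotations$onset[1], s$annotations$offset[3])
  })
  gained <- lapply(tracks, function(tr) {
    tr$envelope <- tr$envelope + 20 * log10(2)  # gain x2 shifts only dB
    tr
  })
  n1 <- build_null(tracks, paste0("g", 1:4))
  n2 <- build_null(gained, paste0("g", 1:4))
  expect_equal(n1$distances, n2$distances, tolerance = 1e-10)
})

test_that("a pitch offset weakly decreases similarity", {
  nl <- fx_null()
  a <- nl$tracks[[1]]
  prev <- similarity(a, a, nl$null)$value
  for (off in c(50, 150, 400)) {
    b <- a
    b$pitch <- b$pitch + off
    v <- similarity(a, b, nl$null)$value
    expect_lte(v, prev + 1e-12)
    prev <- v
  }
})

test_that("baseline similarity course: self-comparison ~1, cross-bird comparison collapses", {
  nl <- fx_null()
  mk_tracks <- function(bird_id, seed_b, seed_s, n_motifs = 3) {
    b <- bird_spec(bird_id, seed = seed_b)
    s <- make_song(b, n_motifs, seed = seed_s)
    ann <- s$annotations
    list(tracks = lapply(seq_len(nrow(ann)), function(i)
      compute_features(s$clip, ann$onset[i], ann$offset[i])),
      labels = ann$label)
  }
  pre <- mk_tracks("course", 9, 31)
  same_day <- mk_tracks("course", 9, 32)
  other <- mk_tracks("crushed", 77, 33)
  course <- baseline_similarity_course(
    pre$tracks, pre$labels,
    post_by_day = list(same_day$tracks, other$tracks),
    post_labels_by_day = list(same_day$labels, other$labels),
    null = nl$null)
  expect_equal(course$normalized[1], 1, tolerance = 0.15)
  expect_lt(course$normalized[2], 0.5 * course$normalized[1])
})

test_that("within/across separates true pattern structure and not permuted labels", {
  nl <- fx_null()
  pats <- make_steering_patterns(4)
  fv <- make_fictive_vocalizations(pats, 5, mapping_spread = 1.5, seed = 6)
  tracks <- lapply(fv$clips, function(cl) compute_features(cl, 0, 0.2))
  wa <- within_across_similarity(tracks, fv$labels, nl$null)
  expect_gt(wa$within_mean, wa$across_mean + 0.1)
  set.seed(8)
  perm <- sample(fv$labels)
  wp <- within_across_similarity(tracks, perm, nl$null)
  expect_lt(abs(wp$within_mean - wp$across_mean), 0.12)
  # identical waveforms in every trial: within = across = 1
  same <- rep(tracks[1], 6)
  ws <- within_across_similarity(same, rep(c("a", "b"), each = 3), nl$null)
  expect_equal(ws$within_mean, 1)
  expect_equal(ws$across_mean, 1)
  # singleton labels are excluded from the within mean and reported
  wsing <- within_across_similarity(tracks[1:5],
                                    c("a", "a", "b", "b", "c"), nl$null)
  expect_equal(wsing$singleton_labels, "c")
})
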