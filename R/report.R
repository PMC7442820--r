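#' Run the synthetic end-to-end pipeline
#'
#' Drives the full analysis chain on synthetic data: song synthesis,
#' song detection, syllable segmentation, acoustic features, a similarity
#' null with a self-similarity check, nerve-recording generation,
#' preprocessing (common-mode subtraction, band-pass, envelope) and the
#' per-motif stability metrics. Writes every table as CSV into
#' `config$out_dir` together with the resolved configuration, and is
#' byte-reproducible for a fixed config + seed.
#'
#' @param config list; recognized keys (all optional except `out_dir`):
#'   `seed` (default 1), `stages` (subset of c("synth", "detect",
#'   "features", "similarity", "neural", "stability"); default all),
#'   `n_motifs` (default 5), `n_null_songs` (default 20), `out_dir`
#' @return invisibly, a named list of written file paths
#' @export
run_pipeline <- function(config) {
  known <- c("seed", "stages", "n_motifs", "n_null_songs", "out_dir")
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  seed <- config$seed %||% 1
  stages <- config$stages %||%
    c("synth", "detect", "features", "similarity", "neural", "stability")
  n_motifs <- config$n_motifs %||% 5
  n_null <- config$n_null_songs %||% 20
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  wr <- function(df, name) {
    p <- file.path(config$out_dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
    p
  }
  resolved <- list(seed = seed, stages = stages, n_motifs = n_motifs,
                   n_null_songs = n_null, out_dir = config$out_dir)
  jsonlite::write_json(resolved,
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  paths$config <- file.path(config$out_dir, "config.json")

  bird <- bird_spec("pipeline-bird", seed = seed)
  song <- NULL
  if ("synth" %in% stages) {
    song <- make_song(bird, n_motifs = n_motifs, seed = seed)
    wr(song$annotations, "annotations")
  }
  if ("detect" %in% stages) {
    if (is.null(song)) stop("detect stage requires the synth stage")
    eps <- detect_song(song$clip)
    wr(eps, "detection_episodes")
    segs <- segment_syllables(song$clip)
    wr(segs, "segments")
  }
  tracks <- NULL
  if ("features" %in% stages) {
    if (is.null(song)) stop("features stage requires the synth stage")
    ann <- song$annotations
    tracks <- lapply(seq_len(nrow(ann)), function(i)
      compute_features(song$clip, ann$onset[i], ann$offset[i]))
    summ <- do.call(rbind, lapply(seq_along(tracks), function(i) {
      s <- summarize_features(tracks[[i]])$summary
      s$segment <- i
      s
    }))
    wr(summ, "feature_summaries")
  }
  if ("similarity" %in% stages) {
    if (is.null(tracks)) stop("similarity stage requires the features stage")
    null_tracks <- lapply(seq_len(n_null), function(i) {
      b <- bird_spec(paste0("null-bird-", i), seed = child_seed(seed, 100 + i))
      s <- make_song(b, 1, seed = child_seed(seed, 200 + i))
      compute_features(s$clip, s$annotations$onset[1],
                       s$annotations$offset[nrow(s$annotations)])
    })
    null <- build_null(null_tracks, paste0("null-bird-", seq_len(n_null)))
    self <- similarity(tracks[[1]], tracks[[1]], null)
    wr(data.frame(check = "self_similarity", value = self$value,
                  median_distance = self$median_distance),
       "similarity_checks")
  }
  rec <- NULL
  if ("neural" %in% stages) {
    if (is.null(song)) stop("neural stage requires the synth stage")
    model <- nerve_model()
    rec <- make_nerve_recording(song$annotations, model, seed = seed)
    proc <- bandpass_filter(common_mode_subtract(rec))
    env <- envelope_trace(proc, window_ms = 5, step_ms = 1)
    wr(data.frame(time_s = env$times, envelope = env$values),
       "neural_envelope")
  }
  if ("stability" %in% stages) {
    if (is.null(rec)) stop("stability stage requires the neural stage")
    proc <- bandpass_filter(common_mode_subtract(rec))
    ann <- song$annotations
    rows <- lapply(sort(unique(ann$motif)), function(m) {
      a <- ann[ann$motif == m, ]
      i0 <- max(1L, round(min(a$onset) * proc$rate))
      i1 <- min(ncol(proc$voltages), round(max(a$offset) * proc$rate))
      w <- proc$voltages[, i0:i1, drop = FALSE]
      env <- envelope_trace(neural_traces(w, proc$rate, proc$role),
                            window_ms = 5, step_ms = 1)
      ns <- proc$voltages[1, max(1, ncol(proc$voltages) - round(0.5 * proc$rate)):ncol(proc$voltages)]
      data.frame(motif = m,
                 vpp = motif_vpp(neural_traces(w, proc$rate, proc$role)),
                 snr = singing_snr(w[1, ], ns),
                 event_rate = event_rate(env, (i1 - i0 + 1) / proc$rate))
    })
    wr(do.call(rbind, rows), "stability_metrics")
  }
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group summary with the reporting conventions of the pipeline
#'
#' Means +/- SD per group, the requested test, and significance stars at
#' the 0.05 / 0.01 / 0.001 thresholds.
#'
#' @param values numeric measurements
#' @param groups group label per measurement
#' @param design `"paired_t"`, `"unpaired_t"` (two groups), or
#'   `"rm_anova_dunnett"` (requires `subjects`)
#' @param subjects subject id per measurement (paired designs)
#' @param control control group for Dunnett contrasts
#' @return a `stat_summary` data.frame of group rows plus test results in
#'   attributes `test` (name), `statistic`, `p_value`, `stars`,
#'   `correction`
#' @export
summarize_groups <- function(values, groups,
                             design = c("paired_t", "unpaired_t",
                                        "rm_anova_dunnett"),
                             subjects = NULL, control = NULL) {
  design <- match.arg(design)
  g <- factor(groups)
  rows <- do.call(rbind, lapply(levels(g), function(l) {
    v <- values[g == l]
    data.frame(group = l, n = length(v), mean = mean(v), sd = stats::sd(v))
  }))
  star <- function(p) if (is.na(p)) "" else if (p < 0.001) "***" else
    if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  if (design %in% c("paired_t", "unpaired_t")) {
    if (nlevels(g) != 2) stop("t-test designs need exactly 2 groups")
    a <- values[g == levels(g)[1]]
    b <- values[g == levels(g)[2]]
    if (design == "paired_t") {
      if (is.null(subjects)) {
        if (length(a) != length(b)) stop("paired design needs equal n")
      } else {
        sa <- subjects[g == levels(g)[1]]; sb <- subjects[g == levels(g)[2]]
        b <- b[match(sa, sb)]
      }
      tt <- stats::t.test(a, b, paired = TRUE)
    } else tt <- stats::t.test(a, b)
    attr(rows, "test") <- tt$method
    attr(rows, "statistic") <- unname(tt$statistic)
    attr(rows, "p_value") <- tt$p.value
    attr(rows, "stars") <- star(tt$p.value)
    attr(rows, "correction") <- "none"
  } else {
    if (is.null(subjects)) stop("rm_anova_dunnett requires subjects")
    cc <- condition_compare(
      data.frame(subject = subjects, condition = groups,
                 amplitude = values),
      control = control,
      baseline = if (!is.null(control)) control else levels(g)[1])
    dun <- cc$dunnett
    dun$stars <- vapply(dun$p_value, star, character(1))
    attr(rows, "test") <- "repeated-measures ANOVA + Dunnett"
    attr(rows, "statistic") <- cc$anova$F
    attr(rows, "p_value") <- cc$anova$p
    attr(rows, "stars") <- star(cc$anova$p)
    attr(rows, "correction") <-
      sprintf("Huynh-Feldt epsilon = %.3f; Dunnett", cc$anova$epsilon)
    attr(rows, "contrasts") <- dun
  }
  class(rows) <- c("stat_summary", "data.frame")
  rows
}
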