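# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fx)) assign(name, force(expr), envir = .fx)
  get(name, envir = .fx)
}

# One song of bird "A" with 2 motifs, plus its annotations.
fx_song <- function() fixture("song", make_song(bird_spec("A", seed = 1), 2, seed = 1))

# Feature tracks of 12 unrelated one-motif songs and their similarity null.
fx_null <- function() fixture("null", {
  tracks <- lapply(1:12, function(i) {
    b <- bird_spec(paste0("nullbird", i), seed = 40 + i)
    s <- make_song(b, 1, seed = 70 + i)
    compute_features(s$clip, s$annotations$onset[1], s$annotations$offset[3])
  })
  list(null = build_null(tracks, paste0("nullbird", 1:12)), tracks = tracks)
})

# A deterministic three-syllable test bird without vibrato, at a given
# tempo scale; used for known-warp alignment checks.
fx_tempo_bird <- function() fixture("tempo_bird", {
  b <- bird_spec("tempo", seed = 3, rendition_jitter = 0)
  b$syllable_params <- lapply(b$syllable_params, function(sp) {
    sp$fm_depth <- 0
    sp$entropy_level <- -5
    sp
  })
  b
})
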