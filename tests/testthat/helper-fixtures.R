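# Build a video_au_table from a list of per-frame AU presence sets.
# `universe` fixes the emitted AU columns; frames default to all-valid.
make_table <- function(presence_sets, universe = emotion_ruleset()$universe,
                       video_id = "id0_0000", variant = "dynamic",
                       success = TRUE, confidence = 0.98,
                       frame_index = seq_along(presence_sets),
                       target = 0L, donor = NA_integer_) {
  n <- length(presence_sets)
  mat <- matrix(0L, nrow = n, ncol = length(universe),
                dimnames = list(NULL, universe))
  for (i in seq_len(n)) {
    hit <- match(intersect(presence_sets[[i]], universe), universe)
    mat[i, hit] <- 1L
  }
  video_au_table(
    video_id = video_id,
    frames = tibble::tibble(frame_index = as.integer(frame_index),
                            timestamp_s = (frame_index - 1) / 30,
                            confidence = rep_len(confidence, n),
                            success = rep_len(success, n)),
    presence = mat, target_performer = target, donor_performer = donor,
    model_variant = variant)
}

# Independent brute-force re-implementation of the subset rule tests, used
# as the oracle against classify_frame / label_video. Deliberately naive.
oracle_classify <- function(presence, rules) {
  flags <- logical(0)
  for (e in names(rules$rules)) {
    ok <- TRUE
    for (au in rules$rules[[e]]) {
      if (!(au %in% presence)) ok <- FALSE
    }
    flags[e] <- ok
  }
  neutral <- TRUE
  for (au in presence) {
    if (au %in% rules$universe) neutral <- FALSE
  }
  c(flags, Neutral = neutral)
}

# all subsets of a set, as a list of integer vectors (for exhaustive tests)
all_subsets <- function(set) {
  n <- length(set)
  lapply(seq_len(2^n) - 1, function(mask) {
    set[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
  })
}
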