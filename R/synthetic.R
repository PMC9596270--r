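#' Configuration of the synthetic paired-AU generator
#'
#' Defines a complete synthetic study: a roster of performers, each with
#' original recordings and several face-swap fakes per original, emitted as
#' per-frame binary AU streams in the same form the AU extractor produces.
#'
#' The latent model per original video is a two-state episode process:
#' outside episodes every AU of the rule universe switches on independently
#' with the spontaneous rate `q_spont` per frame; an emotion episode starts
#' from idle with probability `episode_rate` per frame, lasts a uniform
#' number of frames in `episode_length`, and while it runs each AU required
#' by the episode's emotion is on with probability `p_on` (others stay at
#' `q_spont`). Episode emotions are drawn from `episode_emotion_weights`
#' after a per-performer log-normal perturbation (`performer_weight_sd`),
#' emulating how expressiveness differs strongly between performers.
#'
#' A fake copies its original frame-synchronously: per frame and per AU the
#' original's bit is kept with probability `fidelity`, otherwise the bit is
#' resampled as spontaneous noise — so partial rule breakage (a frame losing
#' one of several required AUs) emerges naturally, and multi-AU emotions
#' degrade fastest as fidelity drops. The `static` and `dynamic` streams of
#' every video are two observation-noise realisations of one latent state,
#' each bit flipped independently with probability `stream_flip`.
#'
#' One root `seed` drives everything; each video draws its own RNG substream
#' from a hash of (role, performer, donor, sequence), so extending a dataset
#' never perturbs already-generated videos.
#'
#' @param n_performers,originals_per_performer,fakes_per_original Roster
#'   sizes (fakes per original get distinct donor performers, cycling).
#' @param frames_per_video Photograms per video (30 fps timestamps).
#' @param episode_rate Per-frame probability of starting an episode when idle.
#' @param episode_length Integer `c(min, max)` of the uniform episode length.
#' @param episode_emotion_weights Named non-negative weights over the rule
#'   set's emotions (default: equal).
#' @param p_on,q_spont Per-frame AU activation probabilities inside /
#'   outside an episode's required set.
#' @param fidelity Copy probability rho of the fake channel, in `[0, 1]`.
#' @param stream_flip Per-bit flip probability between the two model-variant
#'   streams and the latent state.
#' @param performer_weight_sd Log-normal sd of the per-performer emotion
#'   weight perturbation (0 = all performers identical).
#' @param rules [emotion_ruleset()] used both to drive episodes and as the
#'   emitted AU universe.
#' @param seed Root integer seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_performers = 5,
                             originals_per_performer = 2,
                             fakes_per_original = 3,
                             frames_per_video = 300,
                             episode_rate = 0.02,
                             episode_length = c(10, 30),
                             episode_emotion_weights = NULL,
                             p_on = 0.9,
                             q_spont = 0.02,
                             fidelity = 0.7,
                             stream_flip = 0.02,
                             performer_weight_sd = 0.5,
                             rules = emotion_ruleset(),
                             seed = 1) {
  probs <- c(episode_rate = episode_rate, p_on = p_on, q_spont = q_spont,
             fidelity = fidelity, stream_flip = stream_flip)
  bad <- names(probs)[probs < 0 | probs > 1]
  if (length(bad) > 0) {
    stop_config(paste0("probabilities outside [0, 1]: ", paste(bad, collapse = ", ")))
  }
  counts <- c(n_performers, originals_per_performer, fakes_per_original,
              frames_per_video)
  if (any(counts < 1) || any(counts != floor(counts))) {
    stop_config("roster sizes and frames_per_video must be positive integers")
  }
  if (length(episode_length) != 2 || episode_length[1] > episode_length[2] ||
      episode_length[1] < 1) {
    stop_config("episode_length must be c(min, max) with 1 <= min <= max")
  }
  w <- episode_emotion_weights %||%
    setNames(rep(1, length(rules$rules)), names(rules$rules))
  if (!setequal(names(w), names(rules$rules)) || any(w < 0) || sum(w) == 0) {
    stop_config("episode_emotion_weights must cover the rule set's emotions, be non-negative and not all zero")
  }
  structure(
    list(n_performers = as.integer(n_performers),
         originals_per_performer = as.integer(originals_per_performer),
         fakes_per_original = as.integer(fakes_per_original),
         frames_per_video = as.integer(frames_per_video),
         episode_rate = episode_rate,
         episode_length = as.integer(episode_length),
         episode_emotion_weights = w[names(rules$rules)],
         p_on = p_on, q_spont = q_spont, fidelity = fidelity,
         stream_flip = stream_flip,
         performer_weight_sd = performer_weight_sd,
         rules = rules, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# per-performer emotion weights: deterministic log-normal tilt of the base
# weights, from the performer's own substream
performer_weights <- function(config, performer) {
  w <- config$episode_emotion_weights
  if (config$performer_weight_sd > 0) {
    tilt <- with_substream(config$seed, "weights", performer, fn = function() {
      exp(stats::rnorm(length(w), sd = config$performer_weight_sd))
    })
    w <- w * tilt
  }
  w / sum(w)
}

# draw the episode log for one video: tibble(start_frame, end_frame, emotion)
draw_episodes <- function(config, weights) {
  n <- config$frames_per_video
  len_min <- config$episode_length[1]
  len_max <- config$episode_length[2]
  starts <- integer(0); ends <- integer(0); emos <- character(0)
  f <- 1L
  while (f <= n) {
    if (runif(1) < config$episode_rate) {
      len <- if (len_min == len_max) len_min else
        sample(len_min:len_max, 1)
      end <- min(f + len - 1L, n)
      starts <- c(starts, f); ends <- c(ends, end)
      emos <- c(emos, sample(names(weights), 1, prob = weights))
      f <- end + 1L
    } else {
      f <- f + 1L
    }
  }
  tibble::tibble(start_frame = starts, end_frame = ends, emotion = emos)
}

# latent AU activation matrix given an episode log
latent_from_episodes <- function(config, episodes) {
  n <- config$frames_per_video
  uni <- config$rules$universe
  pmat <- matrix(config$q_spont, nrow = n, ncol = length(uni),
                 dimnames = list(NULL, uni))
  for (i in seq_len(nrow(episodes))) {
    aus <- as.character(config$rules$rules[[episodes$emotion[i]]])
    pmat[episodes$start_frame[i]:episodes$end_frame[i], aus] <- config$p_on
  }
  matrix(as.integer(runif(length(pmat)) < pmat), nrow = n,
         dimnames = dimnames(pmat))
}

observe_stream <- function(latent, flip) {
  if (flip == 0) return(latent)
  flips <- runif(length(latent)) < flip
  out <- latent
  out[flips] <- 1L - out[flips]
  out
}

frames_skeleton <- function(n) {
  tibble::tibble(frame_index = seq_len(n),
                 timestamp_s = (seq_len(n) - 1) / 30,
                 confidence = 0.98, success = TRUE)
}

#' Generate one synthetic original recording
#'
#' Draws the episode log and latent AU states for one original video of a
#' performer, then emits the two model-variant observation streams. Fully
#' deterministic given the config's seed: the video has its own RNG
#' substream keyed by (role, performer, sequence).
#'
#' @param config A [synthetic_config()].
#' @param performer Integer performer id.
#' @param seq Integer sequence number of the recording.
#' @param episodes Optional forced episode log (tibble with `start_frame`,
#'   `end_frame`, `emotion`) replacing the random episode draw.
#' @return List with `static` and `dynamic` [video_au_table()]s, the
#'   `episodes` log, and the `latent` state matrix.
#' @export
generate_original <- function(config, performer, seq, episodes = NULL) {
  vid <- sprintf("id%d_%04d", performer, seq)
  with_substream(config$seed, "orig", performer, seq, fn = function() {
    eps <- episodes %||% draw_episodes(config, performer_weights(config, performer))
    latent <- latent_from_episodes(config, eps)
    frames <- frames_skeleton(config$frames_per_video)
    mk <- function(variant) {
      video_au_table(vid, frames,
                     observe_stream(latent, config$stream_flip),
                     target_performer = performer, model_variant = variant)
    }
    list(static = mk("static"), dynamic = mk("dynamic"),
         episodes = dplyr::mutate(eps, video_id = vid, .before = 1),
         latent = latent)
  })
}

#' Derive a synthetic fake from an original AU table
#'
#' Frame-synchronous copy-or-resample channel: per frame and per AU the
#' original's bit is kept with probability `config$fidelity`, otherwise
#' redrawn as Bernoulli(`q_spont`) noise. Frame count and indices are
#' preserved. At fidelity 1 the fake is bit-identical to the original; at
#' fidelity 0 it is pure spontaneous noise.
#'
#' @param original A [video_au_table()] (from this generator or parsed).
#' @param config A [synthetic_config()].
#' @param donor_performer Integer id of the face donor.
#' @return A [video_au_table()] named by the Celeb-DF fake convention.
#' @export
derive_fake <- function(original, config, donor_performer) {
  seq <- parse_video_name(original$video_id)$sequence_number
  target <- original$target_performer
  vid <- sprintf("id%d_id%d_%04d", target, donor_performer, seq)
  with_substream(config$seed, "fake", target, donor_performer, seq,
                 original$model_variant, fn = function() {
    m <- original$presence
    keep <- runif(length(m)) < config$fidelity
    noise <- as.integer(runif(length(m)) < config$q_spont)
    fake <- m
    fake[!keep] <- noise[!keep]
    video_au_table(vid, original$frames, fake,
                   target_performer = target,
                   donor_performer = donor_performer,
                   model_variant = original$model_variant)
  })
}

#' Simulate a full paired original/fake dataset
#'
#' Generates every original of every performer and `fakes_per_original`
#' fakes per original, with donors cycling over the other performers (or
#' over all performers when there is only one). Both model-variant streams
#' are emitted for every video.
#'
#' @param config A [synthetic_config()].
#' @return List of class `synthetic_dataset`: `tables` (flat list of
#'   [video_au_table()], both variants of originals then fakes),
#'   `episode_log` (ground-truth episodes of all originals), and `config`.
#' @export
simulate_dataset <- function(config) {
  tables <- list()
  logs <- list()
  performers <- seq_len(config$n_performers) - 1L
  for (p in performers) {
    donors <- setdiff(performers, p)
    if (length(donors) == 0) donors <- p
    for (s in seq_len(config$originals_per_performer) - 1L) {
      orig <- generate_original(config, p, s)
      tables[[paste0(orig$dynamic$video_id, ".dynamic")]] <- orig$dynamic
      tables[[paste0(orig$static$video_id, ".static")]] <- orig$static
      logs[[length(logs) + 1]] <- orig$episodes
      for (k in seq_len(config$fakes_per_original)) {
        donor <- donors[((s * config$fakes_per_original + k - 1) %% length(donors)) + 1]
        for (variant in c("dynamic", "static")) {
          fake <- derive_fake(orig[[variant]], config, donor)
          tables[[paste0(fake$video_id, ".", variant)]] <- fake
        }
      }
    }
  }
  structure(list(tables = unname(tables),
                 episode_log = dplyr::bind_rows(logs),
                 config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  n_orig <- sum(vapply(x$tables, function(t) is.na(t$donor_performer), logical(1)))
  cat(sprintf("<synthetic_dataset> %d tables (%d original, %d fake), %d episodes\n",
              length(x$tables), n_orig, length(x$tables) - n_orig,
              nrow(x$episode_log)))
  invisible(x)
}

#' Write a synthetic dataset as an OpenFace-dialect CSV tree
#'
#' Lays out `<dir>/static/<video_id>.csv` and `<dir>/dynamic/<video_id>.csv`
#' for every video, plus `episode_log.csv` (ground truth) and `config.txt`
#' (the resolved generator configuration, one `key = value` per line).
#' The tree is directly consumable by [run_analyze()].
#'
#' @param dataset A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  for (v in c("static", "dynamic")) {
    dir.create(file.path(dir, v), recursive = TRUE, showWarnings = FALSE)
  }
  for (tab in dataset$tables) {
    write_au_csv(tab, file.path(dir, tab$model_variant,
                                paste0(tab$video_id, ".csv")))
  }
  readr::write_csv(dataset$episode_log, file.path(dir, "episode_log.csv"),
                   progress = FALSE)
  cfg <- dataset$config
  scalars <- cfg[!(names(cfg) %in% c("rules", "episode_emotion_weights"))]
  lines <- c(
    vapply(names(scalars), function(k) {
      paste0(k, " = ", paste(scalars[[k]], collapse = ",")) }, character(1)),
    paste0("episode_emotion_weights = ",
           paste(sprintf("%s:%g", names(cfg$episode_emotion_weights),
                         cfg$episode_emotion_weights), collapse = ", ")),
    vapply(names(cfg$rules$rules), function(e) {
      paste0("rule.", e, " = ", paste(cfg$rules$rules[[e]], collapse = ", "))
    }, character(1)))
  writeLines(lines, file.path(dir, "config.txt"))
  invisible(dir)
}

#' Moment estimator of the fake channel's copy fidelity
#'
#' For a single-AU emotion probe the per-frame label equals the AU bit, and
#' the copy-or-resample channel gives `P(fake = 1 | orig = 1) = rho +
#' (1 - rho) q` and `P(fake = 1 | orig = 0) = (1 - rho) q`. The difference
#' of the two conditional proportions is therefore exactly `rho`, whatever
#' the spontaneous rate `q`, and reduces to the moment form
#' `rho_hat = (P11 - P1. * P.1) / (P1. (1 - P1.))` — the empirical
#' covariance of the two bit streams over the variance of the original
#' stream. Counts must come from [count_agreement()] with
#' `scope = "both_channels"` over fully aligned frames, so that
#' `epfa = #\{orig = 0, fake = 1\}`.
#'
#' The standard error is the binomial one of the difference of the two
#' conditional proportions. A probe in which the original stream is
#' constant (all zero or all one) has no information about rho: the
#' estimate is flagged undefined.
#'
#' @param epc,epoa,epfa Agreement counts of the probe emotion (both-channels
#'   scope); `epc` may be a one-row tibble carrying all three.
#' @param n_frames Number of aligned frames the counts were taken over.
#' @return One-row tibble: `rho_hat`, `se`, `n_frames`, `defined`.
#' @export
estimate_fidelity <- function(epc, epoa = NULL, epfa = NULL, n_frames) {
  if (is.data.frame(epc)) {
    d <- epc
    epc <- d$epc; epoa <- d$epoa; epfa <- d$epfa
  }
  m1 <- epc + epoa          # frames with the AU on in the original
  m0 <- n_frames - m1       # frames with it off
  if (m1 == 0 || m0 == 0) {
    warn("degenerate probe: original stream is constant, fidelity undefined",
         class = "emotransfer_undefined_estimate")
    return(tibble::tibble(rho_hat = NA_real_, se = NA_real_,
                          n_frames = n_frames, defined = FALSE))
  }
  p1 <- epc / m1            # P(fake on | orig on)
  p0 <- epfa / m0           # P(fake on | orig off)
  tibble::tibble(
    rho_hat = p1 - p0,
    se = sqrt(p1 * (1 - p1) / m1 + p0 * (1 - p0) / m0),
    n_frames = n_frames, defined = TRUE)
}

#' Run a single-AU fidelity-recovery probe end to end
#'
#' Generates one long original with a one-AU probe rule set, derives its
#' fake at the requested fidelity, labels both streams, counts agreement
#' over the aligned frames and feeds the counts to [estimate_fidelity()].
#'
#' @param rho True copy fidelity to simulate.
#' @param n_frames Probe length in frames.
#' @param seed Root seed.
#' @param probe_au AU id carried by the probe emotion (default 12).
#' @param ... Further [synthetic_config()] overrides (e.g. `q_spont`,
#'   `episode_rate`).
#' @return One-row tibble from [estimate_fidelity()], plus the true `rho`.
#' @export
run_fidelity_probe <- function(rho, n_frames = 1e5, seed = 1, probe_au = 12L,
                               ...) {
  rules <- emotion_ruleset(list(Probe = probe_au))
  config <- synthetic_config(
    n_performers = 1, originals_per_performer = 1, fakes_per_original = 1,
    frames_per_video = n_frames, fidelity = rho, stream_flip = 0,
    performer_weight_sd = 0, rules = rules, seed = seed, ...)
  orig <- generate_original(config, 0L, 0L)$dynamic
  fake <- derive_fake(orig, config, 1L)
  lo <- label_video(orig, rules)
  lf <- label_video(fake, rules)
  pair <- align_frames(orig, fake)
  counts <- count_agreement(pair, lo, lf, emotion = "Probe",
                            scope = "both_channels")
  dplyr::mutate(estimate_fidelity(counts, n_frames = nrow(pair$aligned_indices)),
                rho = rho, .before = 1)
}
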