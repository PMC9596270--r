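#' Frame-agreement counts for one recording pair
#'
#' For every emotion label, counts photograms that are emotional in both
#' channels (`epc`, "emotional photograms in common"), in the original alone
#' (`epoa`) and in the fake alone (`epfa`). Under the default
#' `scope = "per_channel"`, a frame that exists in only one channel (the
#' counterpart was dropped by validity filtering) still contributes to that
#' channel's one-sided count, so `epc + epoa` equals the total number of
#' emotional original photograms in the pair. With `scope = "both_channels"`
#' only aligned frames are counted at all.
#'
#' Besides the six emotions and `Neutral`, a derived `AnyEmotion` label
#' (at least one basic-emotion flag, Neutral excluded) is counted, which
#' feeds the distinct-frame variant of the per-performer totals.
#'
#' @param pair An [align_frames()] result.
#' @param labels_orig,labels_fake Label matrices from [label_video()] for the
#'   pair's original and fake tables (same row counts).
#' @param emotion Optional character vector restricting the output rows.
#' @param scope `"per_channel"` (default) or `"both_channels"`.
#' @return Tibble with columns `emotion`, `epc`, `epoa`, `epfa`.
#' @export
count_agreement <- function(pair, labels_orig, labels_fake, emotion = NULL,
                            scope = c("per_channel", "both_channels")) {
  scope <- match.arg(scope)
  if (nrow(labels_orig) != nrow(pair$original$frames)) {
    stop_contract("labels_orig row count does not match the original table")
  }
  if (nrow(labels_fake) != nrow(pair$fake$frames)) {
    stop_contract("labels_fake row count does not match the fake table")
  }
  basic <- intersect(emotions(), colnames(labels_orig))
  add_any <- function(m) {
    cbind(m, AnyEmotion = rowSums(m[, basic, drop = FALSE]) > 0)
  }
  labels_orig <- add_any(labels_orig)
  labels_fake <- add_any(labels_fake)
  emo <- emotion %||% colnames(labels_orig)

  ai <- pair$aligned_indices
  lo <- labels_orig[ai$orig_row, emo, drop = FALSE]
  lf <- labels_fake[ai$fake_row, emo, drop = FALSE]
  epc <- colSums(lo & lf)
  if (scope == "per_channel") {
    epoa <- colSums(labels_orig[, emo, drop = FALSE]) - epc
    epfa <- colSums(labels_fake[, emo, drop = FALSE]) - epc
  } else {
    epoa <- colSums(lo & !lf)
    epfa <- colSums(!lo & lf)
  }
  tibble::tibble(emotion = emo, epc = as.integer(epc),
                 epoa = as.integer(epoa), epfa = as.integer(epfa))
}

#' Percentage normalisation of agreement counts
#'
#' The study tables normalise each emotion's counts to the emotional
#' photograms of the *original* channel: `%C = 100 * epc / (epc + epoa)` and
#' `%O = 100 * epoa / (epc + epoa)` sum to 100, and the fake-alone percentage
#' `%F = 100 * epfa / (epc + epoa)` shares that denominator — it can exceed
#' 100 when fakes outnumber originals. When `epc + epoa = 0` the triple is
#' undefined: `defined` is `FALSE` and the percentages are `NA` (never 0 or
#' `NaN`); such rows are the input of [zero_baseline_exclusions()].
#'
#' Values are returned at full precision; the published tables display them
#' rounded half-up to 2 decimals (see [round_half_up()]).
#'
#' @param epc,epoa,epfa Integer count vectors (recycled together), or `epc`
#'   may be a tibble holding all three columns.
#' @return Tibble with `pct_common`, `pct_original_alone`, `pct_fake_alone`,
#'   `defined`.
#' @examples
#' percent_triple(6047, 15099, 11827)  # 28.60 / 71.40 / 55.93 once rounded
#' @export
percent_triple <- function(epc, epoa = NULL, epfa = NULL) {
  if (is.data.frame(epc)) {
    d <- epc
    epc <- d$epc; epoa <- d$epoa; epfa <- d$epfa
  }
  den <- epc + epoa
  defined <- den > 0
  safe <- function(num) ifelse(defined, 100 * num / ifelse(defined, den, NA), NA_real_)
  tibble::tibble(pct_common = safe(epc),
                 pct_original_alone = safe(epoa),
                 pct_fake_alone = safe(epfa),
                 defined = defined)
}

#' Pool agreement counts by emotion
#'
#' Sums per-pair counts over all pairs of one model variant before taking
#' percentages (the global-table convention: percentages of pooled counts,
#' not means of per-pair percentages).
#'
#' @param counts Tibble of per-pair counts with columns `model_variant`,
#'   `emotion`, `epc`, `epoa`, `epfa`.
#' @return Tibble with summed counts and their [percent_triple()] per
#'   (`model_variant`, `emotion`).
#' @export
aggregate_by_emotion <- function(counts) {
  out <- dplyr::summarise(
    dplyr::group_by(counts, .data$model_variant, .data$emotion),
    epc = sum(.data$epc), epoa = sum(.data$epoa), epfa = sum(.data$epfa),
    .groups = "drop")
  dplyr::bind_cols(out, percent_triple(out))
}

#' Per-performer agreement summary
#'
#' Sums counts over all pairs whose target is the performer and over the six
#' basic emotions (Neutral is excluded from the all-emotions totals). Under
#' the default `totals = "multiple"` a photogram flagged with several
#' emotions counts once per flag; `totals = "distinct"` counts each
#' photogram at most once (via the derived `AnyEmotion` label). Sample
#' columns (`n_originals`, `n_donor_performers`, `n_fake_recordings`) come
#' from the dataset index; performers with no fake recordings are omitted.
#'
#' @param counts Per-pair counts with columns `model_variant`,
#'   `target_performer`, `emotion`, `epc`, `epoa`, `epfa`.
#' @param index A [index_dataset()] result.
#' @param totals `"multiple"` (default) or `"distinct"`.
#' @return Tibble, one row per (performer, model variant), with sample
#'   counts, summed `epc`/`epoa`/`epfa` and their [percent_triple()].
#' @export
aggregate_by_performer <- function(counts, index,
                                   totals = c("multiple", "distinct")) {
  totals <- match.arg(totals)
  keep <- if (totals == "multiple") emotions() else "AnyEmotion"
  out <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(counts, .data$emotion %in% keep),
                    .data$model_variant, performer = .data$target_performer),
    epc = sum(.data$epc), epoa = sum(.data$epoa), epfa = sum(.data$epfa),
    .groups = "drop")
  out <- dplyr::inner_join(
    dplyr::filter(index$performers, .data$n_fake_recordings > 0),
    out, by = "performer")
  dplyr::arrange(dplyr::bind_cols(out, percent_triple(out)),
                 .data$model_variant, .data$performer)
}

#' Share of fake recordings containing an emotion
#'
#' For each performer, model variant and emotion: the percentage of that
#' performer's fake recordings that contain at least one photogram flagged
#' with the emotion, normalised to the performer's total number of fake
#' recordings (FRP). Performers with no fake recordings are omitted.
#'
#' @param video_flags Tibble, one row per (fake recording, model variant,
#'   emotion) with logical `present` (any flagged frame in the recording),
#'   plus `target_performer`.
#' @param index A [index_dataset()] result.
#' @return Tibble with `performer`, `model_variant`, `emotion`,
#'   `n_recordings`, `pct_recordings`.
#' @export
recording_rates <- function(video_flags, index) {
  frp <- dplyr::filter(index$performers, .data$n_fake_recordings > 0)
  out <- dplyr::summarise(
    dplyr::group_by(video_flags, performer = .data$target_performer,
                    .data$model_variant, .data$emotion),
    n_recordings = sum(.data$present), .groups = "drop")
  out <- dplyr::inner_join(
    dplyr::select(frp, "performer", "n_fake_recordings"), out,
    by = "performer")
  dplyr::select(
    dplyr::mutate(out,
                  pct_recordings = 100 * .data$n_recordings / .data$n_fake_recordings),
    "performer", "model_variant", "emotion", "n_recordings", "pct_recordings")
}

#' Performers excluded by the zero-baseline rule
#'
#' A percentage increase over an original baseline of zero is undefined, so
#' performers all of whose original recordings carry no photogram of an
#' emotion — while their fakes do — are excluded from the per-performer
#' figures for that emotion. This returns those performers per
#' (model variant, emotion), with the per-cell cardinalities.
#'
#' @param performer_emotion_counts Tibble of per-performer per-emotion summed
#'   counts: `model_variant`, `performer`, `emotion`, `epc`, `epoa`, `epfa`.
#' @return List with `excluded` (the qualifying rows) and `summary`
#'   (count of excluded performers per model variant and emotion).
#' @export
zero_baseline_exclusions <- function(performer_emotion_counts) {
  excluded <- dplyr::filter(performer_emotion_counts,
                            .data$epc + .data$epoa == 0, .data$epfa > 0)
  summary <- dplyr::summarise(
    dplyr::group_by(excluded, .data$model_variant, .data$emotion),
    n_performers = dplyr::n_distinct(.data$performer), .groups = "drop")
  list(excluded = excluded, summary = summary)
}
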