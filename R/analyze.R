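#' End-to-end emotion-transfer analysis of a paired dataset
#'
#' Runs the whole pipeline over a set of AU tables: validity filtering,
#' EMFACS labeling, original/fake pairing and frame alignment, and every
#' agreement statistic of the study tables.
#'
#' @param tables Flat list of [video_au_table()] objects (any mix of model
#'   variants; identities must parse from `video_id`), or a
#'   `synthetic_dataset`.
#' @param rules An [emotion_ruleset()].
#' @param min_confidence Passed to [filter_valid_frames()].
#' @param scope Frame-counting scope, see [count_agreement()].
#' @param totals Per-performer totals mode, see [aggregate_by_performer()].
#' @param missing_au See [label_video()].
#' @return List of class `emotion_transfer_analysis`:
#' \describe{
#'   \item{recording_rates}{per (performer, variant, emotion) share of fake
#'     recordings containing the emotion.}
#'   \item{by_emotion}{pooled counts and percentages per (variant, emotion).}
#'   \item{by_performer}{per-performer all-emotions totals with sample
#'     counts.}
#'   \item{figure_data}{per (variant, emotion, performer) counts and
#'     percentages — the per-performer scatter quantities.}
#'   \item{exclusions}{zero-baseline exclusion list and its per-cell
#'     cardinalities.}
#'   \item{pair_counts}{raw per-pair per-emotion counts.}
#'   \item{index}{the [index_dataset()] used.}
#' }
#' @export
analyze_tables <- function(tables, rules = emotion_ruleset(),
                           min_confidence = 0,
                           scope = c("per_channel", "both_channels"),
                           totals = c("multiple", "distinct"),
                           missing_au = c("absent", "drop")) {
  scope <- match.arg(scope)
  totals <- match.arg(totals)
  missing_au <- match.arg(missing_au)
  if (inherits(tables, "synthetic_dataset")) tables <- tables$tables
  if (length(tables) == 0) stop_format("no AU tables to analyze")

  tables <- lapply(tables, filter_valid_frames, min_confidence = min_confidence)
  labels <- lapply(tables, label_video, rules = rules, missing_au = missing_au)
  key <- vapply(tables, function(t) paste0(t$video_id, ".", t$model_variant),
                character(1))
  if (anyDuplicated(key)) {
    stop_identity(paste0("duplicate (video, variant) tables: ",
                         paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  names(tables) <- names(labels) <- key
  variants <- unique(vapply(tables, function(t) t$model_variant, character(1)))

  pair_counts <- list()
  flag_rows <- list()
  index <- NULL
  for (v in variants) {
    vt <- tables[vapply(tables, function(t) t$model_variant == v, logical(1))]
    idx <- index_dataset(vapply(vt, function(t) t$video_id, character(1)))
    index <- idx  # variants carry the same roster; keep the last
    pairs <- match_pairs(idx)
    for (i in seq_len(nrow(pairs))) {
      ok <- paste0(pairs$original_id[i], ".", v)
      fk <- paste0(pairs$fake_id[i], ".", v)
      pr <- align_frames(tables[[ok]], tables[[fk]])
      cnt <- count_agreement(pr, labels[[ok]], labels[[fk]], scope = scope)
      pair_counts[[length(pair_counts) + 1]] <- dplyr::mutate(
        cnt, model_variant = v,
        original_id = pairs$original_id[i], fake_id = pairs$fake_id[i],
        target_performer = pairs$target_performer[i], .before = 1)
    }
    fakes <- dplyr::bind_rows(idx$fakes, idx$orphans)
    for (i in seq_len(nrow(fakes))) {
      lab <- labels[[paste0(fakes$video_id[i], ".", v)]]
      emo <- colnames(lab)
      flag_rows[[length(flag_rows) + 1]] <- tibble::tibble(
        video_id = fakes$video_id[i], model_variant = v,
        target_performer = fakes$target_performer[i],
        emotion = emo,
        present = if (nrow(lab) > 0) apply(lab, 2, any) else rep(FALSE, length(emo)))
    }
  }
  pair_counts <- dplyr::bind_rows(pair_counts)
  video_flags <- dplyr::bind_rows(flag_rows)

  no_any <- dplyr::filter(pair_counts, .data$emotion != "AnyEmotion")
  per_perf_emotion <- dplyr::summarise(
    dplyr::group_by(no_any, .data$model_variant,
                    performer = .data$target_performer, .data$emotion),
    epc = sum(.data$epc), epoa = sum(.data$epoa), epfa = sum(.data$epfa),
    .groups = "drop")

  structure(list(
    recording_rates = recording_rates(video_flags, index),
    by_emotion = aggregate_by_emotion(no_any),
    by_performer = aggregate_by_performer(pair_counts, index, totals = totals),
    figure_data = dplyr::bind_cols(per_perf_emotion,
                                   percent_triple(per_perf_emotion)),
    exclusions = zero_baseline_exclusions(per_perf_emotion),
    pair_counts = pair_counts,
    index = index
  ), class = "emotion_transfer_analysis")
}

#' @export
print.emotion_transfer_analysis <- function(x, ...) {
  cat(sprintf(
    "<emotion_transfer_analysis> %d performers, %d pairs per variant (%s)\n",
    nrow(x$index$performers),
    nrow(dplyr::distinct(x$pair_counts, .data$original_id, .data$fake_id)),
    paste(unique(x$pair_counts$model_variant), collapse = ", ")))
  print(x$by_emotion)
  invisible(x)
}

read_dataset_dir <- function(input_dir, ...) {
  tables <- list()
  for (v in c("static", "dynamic")) {
    d <- file.path(input_dir, v)
    if (!dir.exists(d)) next
    for (f in sort(list.files(d, pattern = "\\.csv$", full.names = TRUE))) {
      tables[[length(tables) + 1]] <- read_au_csv(f, model_variant = v, ...)
    }
  }
  if (length(tables) == 0) {
    stop_format(paste0(
      "no AU tables found under ", input_dir,
      " (expected <dir>/static/*.csv and/or <dir>/dynamic/*.csv)"))
  }
  tables
}

# display formatting: half-up 2-decimal percentages, counts untouched
display_round <- function(d) {
  dplyr::mutate(d, dplyr::across(dplyr::starts_with("pct_"),
                                 ~ round_half_up(.x, 2)))
}

#' Analyze a dataset directory and write all report tables
#'
#' Reads every AU CSV under `<input_dir>/static` and `<input_dir>/dynamic`,
#' runs [analyze_tables()] and writes the full report to `output_dir`:
#' `table2.csv` (recording rates), `table3.csv` (pooled per-emotion counts
#' and percentages), `table4.csv` (per-performer totals with sample counts),
#' one `figure_data_<emotion>.csv` per label, `exclusions.csv`, and
#' `run_config.txt` echoing the resolved options. Percentages are written
#' rounded half-up to 2 decimals; undefined percentages are written empty.
#' Re-running on the same inputs is byte-identical.
#'
#' @param input_dir Dataset directory (layout of [write_dataset()]).
#' @param output_dir Report directory, created if needed.
#' @param rules,min_confidence,scope,totals,missing_au Passed to
#'   [analyze_tables()].
#' @param fake_id_order Passed to [read_au_csv()].
#' @return The [analyze_tables()] result, invisibly.
#' @export
run_analyze <- function(input_dir, output_dir, rules = emotion_ruleset(),
                        min_confidence = 0, scope = "per_channel",
                        totals = "multiple", missing_au = "absent",
                        fake_id_order = "target_first") {
  tables <- read_dataset_dir(input_dir, fake_id_order = fake_id_order)
  res <- analyze_tables(tables, rules = rules, min_confidence = min_confidence,
                        scope = scope, totals = totals, missing_au = missing_au)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(d, name) {
    readr::write_csv(display_round(d), file.path(output_dir, name),
                     na = "", progress = FALSE)
  }
  wr(res$recording_rates, "table2.csv")
  wr(dplyr::rename(res$by_emotion, EPC = "epc", EPOA = "epoa", EPFA = "epfa"),
     "table3.csv")
  wr(dplyr::rename(res$by_performer,
                   OR = "n_originals", PF = "n_donor_performers",
                   FRP = "n_fake_recordings",
                   CO = "epc", OA = "epoa", FA = "epfa"),
     "table4.csv")
  for (e in unique(res$figure_data$emotion)) {
    wr(dplyr::select(
         dplyr::filter(res$figure_data, .data$emotion == e),
         "model_variant", "performer", "pct_original_alone",
         "pct_fake_alone", "pct_common"),
       paste0("figure_data_", tolower(e), ".csv"))
  }
  wr(res$exclusions$excluded, "exclusions.csv")
  writeLines(c(
    paste0("input_dir = ", input_dir),
    paste0("min_confidence = ", min_confidence),
    paste0("scope = ", scope),
    paste0("totals = ", totals),
    paste0("missing_au = ", missing_au),
    paste0("fake_id_order = ", fake_id_order),
    vapply(names(rules$rules), function(e) {
      paste0("rule.", e, " = ", paste(rules$rules[[e]], collapse = ", "))
    }, character(1))
  ), file.path(output_dir, "run_config.txt"))
  invisible(res)
}

#' Simulate a synthetic dataset to disk
#'
#' Convenience wrapper: [simulate_dataset()] then [write_dataset()].
#'
#' @param config A [synthetic_config()].
#' @param output_dir Directory for the CSV tree.
#' @return The `synthetic_dataset`, invisibly.
#' @export
run_simulate <- function(config, output_dir) {
  dataset <- simulate_dataset(config)
  write_dataset(dataset, output_dir)
  invisible(dataset)
}
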