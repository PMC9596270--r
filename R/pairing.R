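#' Index a set of video identities
#'
#' Groups parsed Celeb-DF identities into originals and fakes, matches every
#' fake to the original recording it was made on (same target performer and
#' sequence number), and tallies the per-performer sample counts used by the
#' study tables: `n_originals` (OR), `n_donor_performers` (PF, distinct face
#' donors used on this performer's recordings) and `n_fake_recordings` (FRP).
#' Fakes whose (target, sequence) has no original are collected in an orphan
#' list rather than dropped.
#'
#' @param identities List of [parse_video_name()] results, or a character
#'   vector of file names which will be parsed.
#' @return A list of class `dataset_index` with tibbles `originals`, `fakes`,
#'   `orphans` and `performers`.
#' @export
index_dataset <- function(identities) {
  if (is.character(identities)) {
    identities <- lapply(identities, parse_video_name)
  }
  ids <- dplyr::bind_rows(lapply(identities, function(x) {
    tibble::tibble(video_id = x$video_id, is_fake = x$is_fake,
                   target_performer = x$target_performer,
                   donor_performer = x$donor_performer,
                   sequence_number = x$sequence_number)
  }))
  if (nrow(ids) == 0) {
    ids <- tibble::tibble(video_id = character(), is_fake = logical(),
                          target_performer = integer(),
                          donor_performer = integer(),
                          sequence_number = integer())
  }
  if (anyDuplicated(ids$video_id)) {
    dup <- unique(ids$video_id[duplicated(ids$video_id)])
    stop_identity(paste0("duplicate video identities: ",
                         paste(dup, collapse = ", ")))
  }
  originals <- dplyr::filter(ids, !.data$is_fake)
  fakes <- dplyr::filter(ids, .data$is_fake)
  key <- function(d) paste(d$target_performer, d$sequence_number, sep = "#")
  matched <- key(fakes) %in% key(originals)
  orphans <- fakes[!matched, , drop = FALSE]
  fakes <- fakes[matched, , drop = FALSE]

  per_orig <- dplyr::summarise(
    dplyr::group_by(originals, performer = .data$target_performer),
    n_originals = dplyr::n(), .groups = "drop")
  all_fakes <- dplyr::bind_rows(fakes, orphans)
  per_fake <- dplyr::summarise(
    dplyr::group_by(all_fakes, performer = .data$target_performer),
    n_donor_performers = dplyr::n_distinct(.data$donor_performer),
    n_fake_recordings = dplyr::n(), .groups = "drop")
  performers <- dplyr::arrange(
    tidyr::replace_na(
      dplyr::full_join(per_orig, per_fake, by = "performer"),
      list(n_originals = 0L, n_donor_performers = 0L, n_fake_recordings = 0L)),
    .data$performer)

  structure(list(originals = originals, fakes = fakes, orphans = orphans,
                 performers = performers),
            class = "dataset_index")
}

#' @export
print.dataset_index <- function(x, ...) {
  cat(sprintf(
    "<dataset_index> %d originals, %d matched fakes, %d orphans, %d performers\n",
    nrow(x$originals), nrow(x$fakes), nrow(x$orphans), nrow(x$performers)))
  invisible(x)
}

#' Enumerate original/fake recording pairs
#'
#' One pair per (original, fake) combination sharing target performer and
#' sequence number — every fake made on a given original recording is paired
#' with it. Orphan fakes produce no pair.
#'
#' @param index A [index_dataset()] result.
#' @return Tibble with columns `original_id`, `fake_id`, `target_performer`,
#'   `donor_performer`, `sequence_number`.
#' @export
match_pairs <- function(index) {
  if (nrow(index$fakes) == 0) {
    return(tibble::tibble(original_id = character(), fake_id = character(),
                          target_performer = integer(),
                          donor_performer = integer(),
                          sequence_number = integer()))
  }
  dplyr::select(
    dplyr::inner_join(
      dplyr::select(index$originals, original_id = "video_id",
                    "target_performer", "sequence_number"),
      dplyr::select(index$fakes, fake_id = "video_id", "target_performer",
                    "donor_performer", "sequence_number"),
      by = c("target_performer", "sequence_number"),
      relationship = "one-to-many"),
    "original_id", "fake_id", "target_performer", "donor_performer",
    "sequence_number")
}

#' Align the photogram sequences of a recording pair
#'
#' Celeb-DF fakes are frame-synchronous re-renderings of their originals, so
#' corresponding photograms share a frame number. Alignment is therefore the
#' intersection of the two tables' frame indices; frames present in only one
#' channel (e.g. dropped there by validity filtering) stay available for that
#' channel's one-sided counts.
#'
#' @param original,fake [video_au_table()] objects with a common
#'   `model_variant`, both validity-filtered.
#' @return A list of class `recording_pair`: the two tables plus
#'   `aligned_indices`, a tibble of row positions (`orig_row`, `fake_row`)
#'   into each table for every shared frame index.
#' @export
align_frames <- function(original, fake) {
  if (!identical(original$model_variant, fake$model_variant)) {
    stop_contract("cannot pair tables from different model variants")
  }
  common <- intersect(original$frames$frame_index, fake$frames$frame_index)
  structure(
    list(original = original, fake = fake,
         aligned_indices = tibble::tibble(
           frame_index = sort(common),
           orig_row = match(sort(common), original$frames$frame_index),
           fake_row = match(sort(common), fake$frames$frame_index))),
    class = "recording_pair")
}
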