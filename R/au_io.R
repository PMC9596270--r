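#' Per-video action-unit table
#'
#' Container for one video's per-photogram facial action-unit (AU) record:
#' frame bookkeeping (index, timestamp, face-detection confidence and success
#' flag), a binary AU presence matrix, and an optional AU intensity matrix.
#' This is the in-memory form of one OpenFace output CSV.
#'
#' @param video_id Character scalar, usually the file stem
#'   (e.g. `"id0_0000"` or `"id0_id16_0003"`).
#' @param frames Tibble with columns `frame_index` (strictly increasing,
#'   non-negative integers), `timestamp_s` (seconds, may be `NA`),
#'   `confidence` (in `[0, 1]`) and `success` (logical).
#' @param presence Integer matrix, one row per frame, one column per AU;
#'   column names are AU identifiers (`"1"`, `"2"`, ..., `"45"`); entries 0/1.
#' @param intensity Optional numeric matrix with the same shape conventions,
#'   AU intensities on the 0-5 scale, or `NULL`.
#' @param target_performer Integer id of the performer whose recording this is
#'   (for a fake: the performer of the original recording it was made on).
#' @param donor_performer Integer id of the face-swap donor, or `NA` for an
#'   original recording.
#' @param model_variant `"static"` or `"dynamic"`: which AU prediction stream
#'   of the upstream extractor this table carries.
#'
#' @return An object of class `video_au_table`.
#' @seealso [read_au_csv()], [filter_valid_frames()]
#' @export
video_au_table <- function(video_id, frames, presence, intensity = NULL,
                           target_performer = NA_integer_,
                           donor_performer = NA_integer_,
                           model_variant = c("dynamic", "static")) {
  model_variant <- match.arg(model_variant)
  frames <- tibble::as_tibble(frames)
  needed <- c("frame_index", "timestamp_s", "confidence", "success")
  missing_cols <- setdiff(needed, names(frames))
  if (length(missing_cols) > 0) {
    stop_contract(paste0("frames is missing column(s): ",
                         paste(missing_cols, collapse = ", ")))
  }
  if (nrow(frames) > 1 && any(diff(frames$frame_index) <= 0)) {
    stop_contract("frame_index must be strictly increasing")
  }
  presence <- as.matrix(presence)
  if (nrow(presence) != nrow(frames)) {
    stop_contract("presence matrix and frames row counts differ")
  }
  if (is.null(colnames(presence))) {
    stop_contract("presence matrix must carry AU ids as column names")
  }
  if (!is.null(intensity) && !identical(dim(intensity), dim(presence))) {
    stop_contract("intensity matrix shape must match presence matrix")
  }
  structure(
    list(
      video_id = video_id,
      target_performer = as.integer(target_performer),
      donor_performer = as.integer(donor_performer),
      model_variant = model_variant,
      frames = frames,
      presence = presence,
      intensity = intensity
    ),
    class = "video_au_table"
  )
}

#' @export
print.video_au_table <- function(x, ...) {
  role <- if (is.na(x$donor_performer)) "original" else
    paste0("fake (donor id", x$donor_performer, ")")
  cat(sprintf(
    "<video_au_table> %s [%s, %s]\n  %d frames, AU universe: %s\n",
    x$video_id, role, x$model_variant, nrow(x$frames),
    paste(colnames(x$presence), collapse = " ")
  ))
  invisible(x)
}

#' AU universe of a table
#'
#' AU identifiers declared by a video's header, as integers.
#' @param table A [video_au_table()].
#' @return Integer vector of AU ids.
#' @export
au_universe <- function(table) {
  as.integer(colnames(table$presence))
}

#' Parse a Celeb-DF style video file name
#'
#' Celeb-DF names originals `id<target>_<seq>` and face-swap fakes
#' `id<target>_id<donor>_<seq>` (any file extension is ignored). By default
#' the first id is the target performer — the performer of the original
#' recording the fake was made on — and the second id is the face donor;
#' `fake_id_order = "donor_first"` swaps that reading.
#'
#' @param filename File name or path; only the base name is used.
#' @param fake_id_order `"target_first"` (default) or `"donor_first"`.
#' @return A list of class `video_identity` with fields `video_id`, `is_fake`,
#'   `target_performer`, `donor_performer` (`NA` for originals) and
#'   `sequence_number`.
#' @examples
#' parse_video_name("id0_0000.mp4")
#' parse_video_name("id0_id16_0003.mp4")
#' @export
parse_video_name <- function(filename,
                             fake_id_order = c("target_first", "donor_first")) {
  fake_id_order <- match.arg(fake_id_order)
  stem <- sub("\\.[A-Za-z0-9]+$", "", basename(filename))
  m2 <- regmatches(stem, regexec("^id([0-9]+)_id([0-9]+)_([0-9]+)$", stem))[[1]]
  m1 <- regmatches(stem, regexec("^id([0-9]+)_([0-9]+)$", stem))[[1]]
  if (length(m2) == 4) {
    ids <- as.integer(m2[2:3])
    if (fake_id_order == "donor_first") ids <- rev(ids)
    out <- list(video_id = stem, is_fake = TRUE,
                target_performer = ids[1], donor_performer = ids[2],
                sequence_number = as.integer(m2[4]))
  } else if (length(m1) == 3) {
    out <- list(video_id = stem, is_fake = FALSE,
                target_performer = as.integer(m1[2]),
                donor_performer = NA_integer_,
                sequence_number = as.integer(m1[3]))
  } else {
    stop_identity(paste0(
      "'", stem, "' does not match a Celeb-DF video name; accepted patterns ",
      "are 'id<int>_<seq>' (original) and 'id<int>_id<int>_<seq>' (fake)"))
  }
  structure(out, class = "video_identity")
}

#' Read an OpenFace-dialect AU table
#'
#' Reads one per-frame AU CSV as emitted by OpenFace: mandatory columns
#' `frame`, `confidence` and `success`, AU presence columns `AU##_c` (binary)
#' and optional intensity columns `AU##_r` (0-5 scale), plus an optional
#' `timestamp` column. Header names are whitespace-tolerant (OpenFace pads
#' them inconsistently). When a file carries intensities but no presence
#' columns, presence is derived as `intensity > presence_threshold`.
#'
#' Performer/donor identities are parsed from the file name when it follows
#' the Celeb-DF convention; otherwise they are left `NA`.
#'
#' @param path Path to the CSV file.
#' @param model_variant `"static"` or `"dynamic"` input stream tag.
#' @param presence_threshold Intensity cut-off used only when the file has no
#'   binary presence columns (default 0: any positive intensity counts).
#' @param fake_id_order Passed to [parse_video_name()].
#' @return A [video_au_table()]. A header-only file yields a 0-frame table.
#' @export
read_au_csv <- function(path, model_variant = c("dynamic", "static"),
                        presence_threshold = 0,
                        fake_id_order = "target_first") {
  model_variant <- match.arg(model_variant)
  if (!file.exists(path)) stop_format(paste0("no such file: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  names(raw) <- trimws(names(raw))

  for (col in c("frame", "confidence", "success")) {
    if (!col %in% names(raw)) {
      stop_format(paste0(path, ": mandatory column '", col, "' is missing"))
    }
  }
  pres_cols <- grep("^AU[0-9]+_c$", names(raw), value = TRUE)
  int_cols <- grep("^AU[0-9]+_r$", names(raw), value = TRUE)
  if (length(pres_cols) == 0 && length(int_cols) == 0) {
    stop_format(paste0(path, ": no AU presence (AU##_c) or intensity (AU##_r) columns"))
  }

  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & trimws(raw[[col]]) != "")
    if (length(bad) > 0) {
      stop_format(paste0(path, ": non-numeric value '", raw[[col]][bad[1]],
                         "' in column '", col, "', data row ", bad[1]))
    }
    v
  }

  n <- nrow(raw)
  frames <- tibble::tibble(
    frame_index = as.integer(num("frame")),
    timestamp_s = if ("timestamp" %in% names(raw)) num("timestamp") else rep(NA_real_, n),
    confidence = num("confidence"),
    success = num("success") != 0
  )

  au_num <- function(cols) as.integer(sub("^AU0*([0-9]+)_[cr]$", "\\1", cols))
  intensity <- NULL
  if (length(int_cols) > 0) {
    intensity <- matrix(NA_real_, nrow = n, ncol = length(int_cols),
                        dimnames = list(NULL, au_num(int_cols)))
    for (i in seq_along(int_cols)) intensity[, i] <- num(int_cols[i])
    intensity <- intensity[, order(as.integer(colnames(intensity))), drop = FALSE]
  }
  if (length(pres_cols) > 0) {
    presence <- matrix(0L, nrow = n, ncol = length(pres_cols),
                       dimnames = list(NULL, au_num(pres_cols)))
    for (i in seq_along(pres_cols)) presence[, i] <- as.integer(num(pres_cols[i]) != 0)
    presence <- presence[, order(as.integer(colnames(presence))), drop = FALSE]
  } else {
    presence <- matrix(as.integer(intensity > presence_threshold),
                       nrow = n, dimnames = dimnames(intensity))
  }

  ident <- tryCatch(parse_video_name(path, fake_id_order = fake_id_order),
                    emotransfer_identity_error = function(e) NULL)
  video_au_table(
    video_id = sub("\\.[A-Za-z0-9]+$", "", basename(path)),
    frames = frames, presence = presence, intensity = intensity,
    target_performer = if (is.null(ident)) NA_integer_ else ident$target_performer,
    donor_performer = if (is.null(ident)) NA_integer_ else ident$donor_performer,
    model_variant = model_variant
  )
}

#' Write an AU table in the OpenFace CSV dialect
#'
#' Inverse of [read_au_csv()]: emits `frame`, `timestamp`, `confidence`,
#' `success`, then `AU##_r` intensity columns (if present) and `AU##_c`
#' presence columns, zero-padded to two digits. Reading the file back
#' reproduces frame count, AU universe and all presence bits exactly.
#'
#' @param table A [video_au_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_au_csv <- function(table, path) {
  aus <- colnames(table$presence)
  pad <- sprintf("AU%02d", as.integer(aus))
  out <- tibble::tibble(
    frame = table$frames$frame_index,
    timestamp = table$frames$timestamp_s,
    confidence = table$frames$confidence,
    success = as.integer(table$frames$success)
  )
  if (!is.null(table$intensity)) {
    ints <- tibble::as_tibble(table$intensity, .name_repair = "minimal")
    names(ints) <- paste0(pad, "_r")
    out <- dplyr::bind_cols(out, ints)
  }
  pres <- tibble::as_tibble(table$presence, .name_repair = "minimal")
  names(pres) <- paste0(pad, "_c")
  out <- dplyr::bind_cols(out, pres)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Drop photograms without a usable face
#'
#' Keeps only frames where the face detector succeeded and its confidence is
#' at least `min_confidence`. Original frame indices are retained, so
#' downstream frame alignment still works. Idempotent, and monotone in the
#' threshold: a higher `min_confidence` keeps a subset of the frames.
#'
#' @param table A [video_au_table()].
#' @param min_confidence Confidence threshold in `[0, 1]` (default 0:
#'   only the success flag matters).
#' @return A filtered [video_au_table()]; an empty table is a legal result.
#' @export
filter_valid_frames <- function(table, min_confidence = 0) {
  # a threshold above 1 is legal and simply keeps nothing
  keep <- which(table$frames$success & table$frames$confidence >= min_confidence)
  table$frames <- table$frames[keep, , drop = FALSE]
  table$presence <- table$presence[keep, , drop = FALSE]
  if (!is.null(table$intensity)) {
    table$intensity <- table$intensity[keep, , drop = FALSE]
  }
  table
}
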