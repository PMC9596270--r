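#' The six Ekman basic emotions
#'
#' @return Character vector in the fixed order used throughout the package.
#' @export
emotions <- function() {
  c("Sadness", "Fear", "Happiness", "Anger", "Surprise", "Disgust")
}

#' EMFACS emotion rule set
#'
#' A mapping from each Ekman basic emotion to the set of facial action units
#' (AUs) involved in its prototypical expression, in the EMFACS tradition.
#' The default is:
#'
#' | Emotion   | AUs                   |
#' |-----------|-----------------------|
#' | Sadness   | 1, 4                  |
#' | Fear      | 1, 2, 4, 5, 7, 20, 26 |
#' | Happiness | 6, 12                 |
#' | Anger     | 4, 5, 7, 23           |
#' | Surprise  | 1, 2, 5, 26           |
#' | Disgust   | 9, 15, 16             |
#'
#' An emotion fires on a photogram when *all* of its AUs are present
#' (conjunction rule; see [classify_frame()]). The rule universe — the union
#' of all six AU sets — additionally defines Neutral: a photogram whose AU
#' set contains no emotion-related AU at all.
#'
#' @param rules Optional named list replacing the default mapping: names are
#'   emotions, values integer vectors of AU ids. All six emotions must be
#'   present and every AU set non-empty.
#' @return An object of class `emotion_ruleset` with elements `rules` (named
#'   list of integer vectors) and `universe` (sorted union of all AU ids).
#' @examples
#' rs <- emotion_ruleset()
#' rs$rules$Happiness  # 6, 12
#' rs$universe
#' @export
emotion_ruleset <- function(rules = NULL) {
  if (is.null(rules)) {
    rules <- list(
      Sadness   = c(1L, 4L),
      Fear      = c(1L, 2L, 4L, 5L, 7L, 20L, 26L),
      Happiness = c(6L, 12L),
      Anger     = c(4L, 5L, 7L, 23L),
      Surprise  = c(1L, 2L, 5L, 26L),
      Disgust   = c(9L, 15L, 16L)
    )
  }
  if (!is.list(rules) || is.null(names(rules)) || anyDuplicated(names(rules)) ||
      any(names(rules) == "") || "Neutral" %in% names(rules)) {
    stop_config(paste0("rules must be a uniquely named list keyed by emotion; ",
                       "Neutral is derived, never a rule"))
  }
  rules <- lapply(rules, function(x) sort(unique(as.integer(x))))
  empty <- names(rules)[vapply(rules, length, 1L) == 0]
  if (length(empty) > 0) {
    stop_config(paste0("empty AU set for: ", paste(empty, collapse = ", ")))
  }
  structure(
    list(rules = rules, universe = sort(unique(unlist(rules, use.names = FALSE)))),
    class = "emotion_ruleset"
  )
}

#' @export
print.emotion_ruleset <- function(x, ...) {
  cat("<emotion_ruleset>\n")
  for (e in names(x$rules)) {
    cat(sprintf("  %-10s AU %s\n", e, paste(x$rules[[e]], collapse = ", ")))
  }
  cat("  universe:  ", paste(x$universe, collapse = ", "), "\n")
  invisible(x)
}

#' Read an emotion rule set from a plain-text config
#'
#' One rule per line, `Emotion: au, au, ...`; blank lines and `#` comments
#' are ignored. Emotions not mentioned keep their default AU sets.
#'
#' @param path Path to the config file.
#' @return An [emotion_ruleset()].
#' @export
read_ruleset <- function(path) {
  if (!file.exists(path)) stop_format(paste0("no such file: ", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  rules <- emotion_ruleset()$rules
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) {
      stop_format(paste0("cannot parse rule line: '", ln, "'"))
    }
    emo <- trimws(parts[1])
    aus <- suppressWarnings(as.integer(strsplit(trimws(parts[2]), "[ ,]+")[[1]]))
    if (anyNA(aus) || length(aus) == 0) {
      stop_format(paste0("cannot parse AU list in line: '", ln, "'"))
    }
    rules[[emo]] <- aus
  }
  emotion_ruleset(rules)
}

#' Classify one photogram from its AU presence set
#'
#' Applies the conjunction rule: emotion `E` is flagged exactly when every AU
#' in its rule set is present. Several emotions may fire at once (the rule
#' sets overlap; e.g. the full Fear set also satisfies Sadness and Surprise).
#' Neutral fires exactly when the presence set shares no AU with the rule
#' universe. A frame can also be entirely unflagged: emotion-related AUs are
#' present but no complete rule is satisfied.
#'
#' @param presence Integer vector of AU ids present on the frame. Ids outside
#'   the rule universe are ignored.
#' @param rules An [emotion_ruleset()].
#' @return Named logical vector over the six emotions plus `Neutral`.
#' @examples
#' rs <- emotion_ruleset()
#' classify_frame(c(6, 12), rs)   # Happiness
#' classify_frame(integer(0), rs) # Neutral
#' classify_frame(9, rs)          # nothing: incomplete Disgust, not Neutral
#' @export
classify_frame <- function(presence, rules = emotion_ruleset()) {
  presence <- as.integer(presence)
  flags <- vapply(rules$rules, function(aus) all(aus %in% presence), logical(1))
  c(flags, Neutral = !any(presence %in% rules$universe))
}

#' Label every photogram of a video
#'
#' Vectorised per-frame classification of a whole [video_au_table()]. AUs
#' that an emotion rule requires but the file's AU universe does not declare
#' are, by default, treated as never present, so the affected emotion can
#' never fire (`missing_au = "absent"`, the conservative reading for
#' extractors that do not emit e.g. AU16). With `missing_au = "drop"` the
#' undeclared AUs are removed from the rule instead, and the remaining AUs
#' must all be present; a rule losing all its AUs never fires.
#'
#' @param table A [video_au_table()], already validity-filtered.
#' @param rules An [emotion_ruleset()].
#' @param missing_au `"absent"` (default) or `"drop"`; see Details.
#' @return Logical matrix, one row per frame, columns the six emotions plus
#'   `Neutral`, in the order of [emotions()].
#' @export
label_video <- function(table, rules = emotion_ruleset(),
                        missing_au = c("absent", "drop")) {
  missing_au <- match.arg(missing_au)
  mat <- table$presence
  have <- as.integer(colnames(mat))
  n <- nrow(mat)
  emo_names <- names(rules$rules)
  out <- matrix(FALSE, nrow = n, ncol = length(emo_names) + 1,
                dimnames = list(NULL, c(emo_names, "Neutral")))
  for (e in emo_names) {
    aus <- rules$rules[[e]]
    declared <- intersect(aus, have)
    if (missing_au == "absent" && length(declared) < length(aus)) next
    if (length(declared) == 0) next  # vacuous rule after drop: never fires
    cols <- match(as.character(declared), colnames(mat))
    if (n > 0) {
      out[, e] <- rowSums(mat[, cols, drop = FALSE]) == length(declared)
    }
  }
  uni <- intersect(rules$universe, have)
  if (n > 0) {
    out[, "Neutral"] <- if (length(uni) == 0) TRUE else
      rowSums(mat[, match(as.character(uni), colnames(mat)), drop = FALSE]) == 0
  }
  out
}
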