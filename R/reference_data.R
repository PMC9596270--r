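#' Published Celeb-DF emotion-transfer reference tables
#'
#' The agreement tables published for the Celeb-DF corpus (59 performers,
#' 590 originals, 5639 face-swap fakes, AU streams from both the static and
#' the dynamic extractor model), shipped as plain-text CSV:
#'
#' * `celebdf_emotion_counts()` — pooled per-emotion counts (EPC/EPOA/EPFA)
#'   with the printed `%C`/`%O`/`%F` percentages, per model variant.
#' * `celebdf_performer_counts()` — per-performer sample counts (OR, PF,
#'   FRP) and all-emotions totals (CO/OR/FA) with printed percentages.
#' * `celebdf_recording_rates()` — per-performer share of fake recordings
#'   containing each emotion.
#'
#' These are used to validate the package's percentage normalisation against
#' the published cells: every printed percentage reproduces bit-exactly from
#' its printed counts under half-up rounding at the printed precision.
#'
#' @return A tibble.
#' @name celebdf_reference
NULL

ref_csv <- function(name) {
  readr::read_csv(system.file("extdata", name, package = "emotransfer",
                              mustWork = TRUE),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname celebdf_reference
#' @export
celebdf_emotion_counts <- function() ref_csv("celebdf_emotion_counts.csv")

#' @rdname celebdf_reference
#' @export
celebdf_performer_counts <- function() ref_csv("celebdf_performer_counts.csv")

#' @rdname celebdf_reference
#' @export
celebdf_recording_rates <- function() ref_csv("celebdf_recording_rates.csv")
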