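Package: emotransfer
Title: Frame-Level Emotion Agreement Between Original and Face-Swap
    Deepfake Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study how well face-swap deepfakes preserve facial
    emotional expression. Reads per-frame facial action-unit (AU) tables in
    the OpenFace CSV dialect, labels every photogram with Ekman basic
    emotions (and Neutral) using EMFACS-style AU combination rules, pairs
    original recordings with the deepfakes derived from them under the
    Celeb-DF naming convention, and computes frame-agreement statistics:
    emotional photograms in common, in the original alone, and in the fake
    alone, with the percentage normalisation used in the published Celeb-DF
    emotion-transfer tables. Ships a synthetic paired-AU generator with
    controllable transfer fidelity so the whole pipeline is testable without
    any video data, plus a moment estimator that recovers the fidelity
    parameter from agreement counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
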