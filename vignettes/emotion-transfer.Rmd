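---
title: "Frame-level emotion agreement between originals and face-swap fakes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frame-level emotion agreement between originals and face-swap fakes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emotransfer)
```

`emotransfer` measures how well face-swap deepfakes reproduce the facial
emotional expression of the recordings they were made from. This vignette
explains the underlying model and procedure, the parameters that matter,
what the synthetic generator does and does not emulate, and the numerical
and design choices behind the implementation.

## From action units to emotions

The pipeline never sees pixels. Its input is the per-frame output of a
facial action-unit (AU) extractor such as OpenFace: one CSV per video with
a face-detection `success` flag and `confidence`, binary AU presence
columns (`AU##_c`) and optionally AU intensities (`AU##_r`). Two extractor
streams exist per video — `static` (each frame estimated alone) and
`dynamic` (person-normalised over the video) — and the pipeline treats
them as parallel inputs throughout.

Frames without a detected face are removed first (`filter_valid_frames()`,
default confidence threshold 0, so only the success flag decides; the
threshold is exposed because extractor confidence calibration varies).

Each remaining frame is labeled with Ekman's six basic emotions using
EMFACS-style AU combinations:

| Emotion   | AUs                   |
|-----------|-----------------------|
| Sadness   | 1, 4                  |
| Fear      | 1, 2, 4, 5, 7, 20, 26 |
| Happiness | 6, 12                 |
| Anger     | 4, 5, 7, 23           |
| Surprise  | 1, 2, 5, 26           |
| Disgust   | 9, 15, 16             |

An emotion fires only when **all** its AUs are present (conjunction). The
EMFACS literature lists "involved" AUs without fixing the combination
logic; we adopt the conjunction because it is the strictest reading and it
produces the qualitative signature seen in practice — Fear, with seven
required AUs, is vastly rarer than Happiness with two. Rule sets are
configurable (`emotion_ruleset()`, `read_ruleset()`) so partial-prototype
variants can be swapped in.

The labeling is deliberately multi-label: the rule sets overlap (a complete
Fear set contains complete Sadness and Surprise sets), and all downstream
counts treat emotions independently. `Neutral` is defined as the absence of
*any* of the 13 emotion-related AUs — so a frame can be neither emotional
nor Neutral (some emotion-related AUs present, no rule completed).

Two degenerate-input policies deserve note. AU ids outside the rule
universe are always ignored. An AU that a rule requires but the input file
never declares (common for AU16, which several extractors do not emit) is
by default treated as never present, so the affected emotion simply cannot
fire — the conservative choice; `missing_au = "drop"` instead removes the
undeclared AU from the rule, and a rule that loses all its AUs never fires
rather than firing vacuously.

## Pairing and agreement accounting

Originals are named `id<target>_<seq>`, fakes `id<target>_id<donor>_<seq>`;
the first id is read as the performer of the underlying original recording
(a config switch accepts the opposite convention). Every fake is paired
with the original sharing its (target, sequence); fakes without such an
original are kept on an explicit orphan list — they cannot enter pair
statistics but still count toward the performer's fake-recording total
(FRP) used by the recording rates.

Face swaps are frame-synchronous re-renderings, so "corresponding
photogram" means "same frame number": alignment is the intersection of
frame indices, with no time warping. For each pair and emotion we count
EPC (emotional in both), EPOA (original alone) and EPFA (fake alone).
Frames surviving validity filtering in only one channel contribute to that
channel's one-sided count by default (`scope = "per_channel"`), keeping the
invariant EPC + EPOA = all emotional original photograms in the pair;
`scope = "both_channels"` restricts everything to aligned frames. Counts
are summed across pairs *before* percentages are taken.

Percentages follow the published convention: %C and %O are shares of the
original-channel emotional photograms (they sum to 100), and %F uses the
same denominator, so it exceeds 100 whenever a performer's many fakes
jointly show more emotional frames than the originals. When the
denominator is zero the triple is flagged undefined (`defined = FALSE`,
`NA` values — never silently 0), and such performer/emotion cells are
routed to the zero-baseline exclusion list instead of being imputed.

Per-performer totals sum the six emotions with Neutral excluded and count
a multi-flagged frame once per flag (the totals then exceed any single
emotion, matching the published per-performer table); `totals = "distinct"`
switches to counting each frame at most once via the derived `AnyEmotion`
label. Display rounding is half-up to two decimals — the published tables
round 109.735… to 109.74 — applied only at write time; all internal sums
are exact integers. (`round_half_up()` adds a 1e-9 guard so decimal ties
are not lost to binary floating point.) The bundled reference tables
(`celebdf_emotion_counts()` etc.) let `analysis/04_reference_checks.R`
verify these conventions: all 390 published percentage cells reproduce
exactly at their printed precision from the printed counts.

## The synthetic generator

Real paired AU corpora are large, restricted and expensive to re-extract,
so the package ships a generator whose output exercises every pipeline
stage. Per original video a latent binary AU process is drawn: outside
episodes each universe AU activates independently at the spontaneous rate
`q_spont` per frame; an emotion episode starts from idle with probability
`episode_rate` per frame, lasts Uniform(`episode_length`) frames, and
while it runs each AU required by its emotion is on with probability
`p_on`. Episode emotions are drawn from per-performer weights — the base
weights tilted by a log-normal factor (`performer_weight_sd`) per
performer — to emulate the strong between-performer variation in
expressiveness that real corpora show.

The fake channel is a per-frame, per-AU copy-or-resample process: with
probability ρ (`fidelity`) the original's bit is copied, otherwise it is
replaced by fresh Bernoulli(`q_spont`) noise. Perturbing *AU states* rather
than emotion labels is the essential modelling choice: partial rule
breakage then emerges naturally, and emotions with larger AU sets degrade
faster — with per-AU survival ρ, an all-AU conjunction survives roughly as
ρ^k — which is exactly the behaviour worth testing in an emotion-transfer
analysis. The static and dynamic streams are two independent
observation-noise realisations of the one latent state, each bit flipped
with probability `stream_flip`; the package does not model the real
calibration differences between the two extractor modes, only their
divergence.

Defaults, chosen once as a plausible small interview-like corpus:
5 performers × 2 originals × 3 fakes (donors cycling), 300 frames per
video (10 s at 30 fps), `episode_rate` 0.02 and lengths 10–30 frames
(episodes occupy roughly a quarter of a video), `p_on` 0.9, `q_spont`
0.02, `fidelity` 0.7, `stream_flip` 0.02, `performer_weight_sd` 0.5.

Determinism: one root seed; every video derives an RNG substream by
hashing (role, performer, donor, sequence) onto a 31-bit seed, so a
dataset can be extended without perturbing existing videos, and equal
seeds give bit-identical output on any platform.

What the generator does **not** emulate: realistic AU co-activation
covariance beyond the episode structure, intensity dynamics
(onset–apex–offset ramps), face-detection dropouts (all frames are valid
by default), and any pixel-level artefact of face swapping. Tests passing
on synthetic data therefore validate the *accounting* — labeling, pairing,
counting, normalisation — not the behaviour of any AU extractor on real
deepfakes.

## Fidelity recovery

For a probe rule with a single AU the frame label equals the AU bit, and
the copy-or-resample channel gives

P(fake = 1 | orig = 1) = ρ + (1 − ρ)q,  P(fake = 1 | orig = 0) = (1 − ρ)q,

so the difference of the two conditional proportions estimates ρ without
knowing q; algebraically this equals the moment form
cov(orig, fake) / var(orig). `estimate_fidelity()` implements it with the
binomial standard error of the proportion difference; it requires
both-channels-scope counts, is exact at ρ = 1 (the fake is a bit-exact
copy), and is flagged undefined when the original stream is constant. The
estimator is conditionally unbiased given the original stream, so episode
autocorrelation does not bias it. `analysis/03_fidelity.R` shows recovery
within a few standard errors over the whole (0, 1) range at 10⁵ frames
(|z| < 3), and the monotone dose response of %C in ρ.

## Problem sizes and limitations

The bundled experiments use modest sizes chosen for tight feedback loops:
50 videos × 300 frames for pipeline-level checks, 10⁵ frames for probe
estimation, 20 written videos for the independent recount; all scale
linearly if increased. Known limitations: the conjunction rule is one of
several defensible EMFACS readings (the partial-prototype variants are
configuration, not default); Disgust depends on AU16, which common
extractors omit — with the default missing-AU policy Disgust then never
fires, mirroring how such frames would be counted from real extractor
output; and agreement is computed strictly frame-by-frame, so a fake whose
emotion episode is shifted by even a few frames scores poorly — a
deliberate choice matching the frame-synchronous construction of face-swap
corpora, not a claim about perceived emotion.
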