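flag_tables <- function(orig_bits, fake_bits) {
  as_sets <- function(bits) lapply(bits, function(b) if (b) c(6, 12) else integer(0))
  orig <- make_table(as_sets(orig_bits))
  fake <- make_table(as_sets(fake_bits), video_id = "id0_id1_0000", donor = 1L)
  rs <- emotion_ruleset()
  list(pair = align_frames(orig, fake),
       lo = label_video(orig, rs), lf = label_video(fake, rs))
}

test_that("per-pair counts enumerate common and one-sided emotional frames", {
  x <- flag_tables(c(1, 1, 0, 1, 0), c(1, 1, 0, 1, 0))
  cnt <- count_agreement(x$pair, x$lo, x$lf, emotion = "Happiness")
  expect_equal(c(cnt$epc, cnt$epoa, cnt$epfa), c(3L, 0L, 0L))

  x <- flag_tables(c(1, 1, 0, 1, 0), c(1, 0, 0, 1, 1))
  cnt <- count_agreement(x$pair, x$lo, x$lf, emotion = "Happiness")
  expect_equal(c(cnt$epc, cnt$epoa, cnt$epfa), c(2L, 1L, 1L))

  x <- flag_tables(c(0, 0, 0), c(0, 0, 0))
  cnt <- count_agreement(x$pair, x$lo, x$lf, emotion = "Happiness")
  expect_equal(c(cnt$epc, cnt$epoa, cnt$epfa), c(0L, 0L, 0L))

  expect_error(count_agreement(x$pair, x$lo[-1, , drop = FALSE], x$lf),
               class = "emotransfer_contract_error")
})

test_that("frames present in one channel only feed that channel's one-sided count", {
  orig <- make_table(lapply(1:5, function(i) c(6, 12)), frame_index = 1:5)
  fake <- make_table(list(c(6, 12), integer(0), c(6, 12)), frame_index = c(1, 2, 7),
                     video_id = "id0_id1_0000", donor = 1L)
  rs <- emotion_ruleset()
  pr <- align_frames(orig, fake)
  lo <- label_video(orig, rs); lf <- label_video(fake, rs)
  # aligned: frames 1, 2 -> epc=1; unaligned orig 3,4,5 all flagged; fake 7 flagged
  per_channel <- count_agreement(pr, lo, lf, emotion = "Happiness")
  expect_equal(c(per_channel$epc, per_channel$epoa, per_channel$epfa), c(1L, 4L, 1L))
  both_only <- count_agreement(pr, lo, lf, emotion = "Happiness",
                               scope = "both_channels")
  expect_equal(c(both_only$epc, both_only$epoa, both_only$epfa), c(1L, 1L, 0L))
  # invariant: epc + epoa = all emotional original frames in pairing scope
  expect_equal(per_channel$epc + per_channel$epoa, sum(lo[, "Happiness"]))
})

test_that("percent triples use the original-channel denominator", {
  # published global Sadness row, dynamic stream
  pt <- percent_triple(6047, 15099, 11827)
  expect_equal(round_half_up(pt$pct_common), 28.60)
  expect_equal(round_half_up(pt$pct_original_alone), 71.40)
  expect_equal(round_half_up(pt$pct_fake_alone), 55.93)
  # published per-performer row where fakes exceed the original baseline
  pt2 <- percent_triple(1652, 1871, 3866)
  expect_equal(round_half_up(pt2$pct_fake_alone), 109.74)
  expect_true(pt2$pct_fake_alone > 100)
  # perfect transfer
  pt3 <- percent_triple(7, 0, 0)
  expect_equal(c(pt3$pct_common, pt3$pct_original_alone, pt3$pct_fake_alone),
               c(100, 0, 0))
  # undefined denominator is a marker, not a number
  pt4 <- percent_triple(0, 0, 5)
  expect_false(pt4$defined)
  expect_true(is.na(pt4$pct_common) && is.na(pt4$pct_fake_alone))
})

test_that("half-up display rounding differs from round-half-even where it must", {
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(2.675, 2), 2.68)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(round_half_up(46.885, 2), 46.89)
})

test_that("aggregation is additive over disjoint pair sets", {
  counts <- tibble::tibble(
    model_variant = "dynamic", emotion = "Happiness",
    epc = c(1L, 4L), epoa = c(2L, 5L), epfa = c(3L, 6L))
  agg <- aggregate_by_emotion(counts)
  expect_equal(c(agg$epc, agg$epoa, agg$epfa), c(5L, 7L, 9L))
  # singleton aggregation is the identity on counts
  one <- aggregate_by_emotion(counts[1, ])
  expect_equal(c(one$epc, one$epoa, one$epfa), c(1L, 2L, 3L))
  # union of the parts equals the whole
  split_sum <- aggregate_by_emotion(counts[1, ])[, c("epc", "epoa", "epfa")] +
    aggregate_by_emotion(counts[2, ])[, c("epc", "epoa", "epfa")]
  expect_equal(as.integer(split_sum), as.integer(agg[, c("epc", "epoa", "epfa")]))
})

test_that("rounded common and original-alone percentages sum to 100 within 0.01", {
  set.seed(21)
  epc <- sample(0:5000, 300); epoa <- sample(0:5000, 300)
  keep <- epc + epoa > 0
  pt <- percent_triple(epc[keep], epoa[keep], 0)
  sums <- round_half_up(pt$pct_common) + round_half_up(pt$pct_original_alone)
  expect_true(all(abs(sums - 100) <= 0.01 + 1e-9))
})

test_that("per-performer totals sum the six emotions and exclude Neutral", {
  counts <- tibble::tibble(
    model_variant = "dynamic",
    target_performer = 0L,
    emotion = c(emotions(), "Neutral", "AnyEmotion"),
    epc = c(5L, 0L, 3L, 0L, 2L, 0L, 99L, 8L),
    epoa = c(2L, 0L, 2L, 0L, 1L, 0L, 99L, 4L),
    epfa = c(1L, 0L, 1L, 0L, 1L, 0L, 99L, 2L))
  idx <- index_dataset(c("id0_0000", "id0_id1_0000", "id1_0005"))
  perf <- aggregate_by_performer(counts, idx)
  expect_equal(nrow(perf), 1)  # performer 1 has no fakes: omitted
  expect_equal(c(perf$epc, perf$epoa, perf$epfa), c(10L, 5L, 3L))
  expect_equal(round_half_up(perf$pct_common), 66.67)
  # distinct mode counts multi-flagged frames once, via AnyEmotion
  dist <- aggregate_by_performer(counts, idx, totals = "distinct")
  expect_equal(c(dist$epc, dist$epoa, dist$epfa), c(8L, 4L, 2L))
})

test_that("recording rates normalise to the performer's fake-recording count", {
  # 114 fake recordings on one performer's originals, 16 containing sadness
  fakes <- sprintf("id0_id1_%04d", 0:113)
  idx <- index_dataset(c(sprintf("id0_%04d", 0:9), fakes))
  expect_equal(idx$performers$n_fake_recordings, 114L)
  flags <- tibble::tibble(video_id = fakes, model_variant = "dynamic",
                          target_performer = 0L, emotion = "Sadness",
                          present = c(rep(TRUE, 16), rep(FALSE, 98)))
  rt <- recording_rates(flags, idx)
  expect_equal(round_half_up(rt$pct_recordings), 14.04)
  # limiting cases
  flags$present <- FALSE
  expect_equal(recording_rates(flags, idx)$pct_recordings, 0)
  flags$present <- TRUE
  expect_equal(recording_rates(flags, idx)$pct_recordings, 100)
})

test_that("zero-baseline exclusions list exactly the undefined performers", {
  counts <- tibble::tibble(
    model_variant = "dynamic",
    performer = c(0L, 1L, 2L),
    emotion = "Anger",
    epc = c(0L, 3L, 0L), epoa = c(0L, 1L, 0L), epfa = c(7L, 2L, 0L))
  ex <- zero_baseline_exclusions(counts)
  expect_equal(ex$excluded$performer, 0L)  # performer 2 has no fake frames either
  expect_equal(ex$summary$n_performers, 1L)
  expect_equal(ex$summary$emotion, "Anger")
})
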