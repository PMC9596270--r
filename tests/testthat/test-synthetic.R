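test_that("config validation rejects impossible parameters", {
  expect_error(synthetic_config(fidelity = 1.2), class = "emotransfer_config_error")
  expect_error(synthetic_config(q_spont = -0.1), class = "emotransfer_config_error")
  expect_error(synthetic_config(n_performers = 0), class = "emotransfer_config_error")
  expect_error(synthetic_config(episode_length = c(5, 2)),
               class = "emotransfer_config_error")
  expect_error(synthetic_config(episode_emotion_weights = c(Happiness = 1)),
               class = "emotransfer_config_error")
})

test_that("a silent baseline produces only Neutral frames", {
  cfg <- synthetic_config(q_spont = 0, episode_rate = 0, stream_flip = 0,
                          frames_per_video = 50, seed = 5)
  orig <- generate_original(cfg, 0L, 0L)
  lab <- label_video(orig$dynamic, cfg$rules)
  expect_true(all(lab[, "Neutral"]))
  expect_equal(nrow(orig$episodes), 0)
})

test_that("a forced clean episode is labeled on exactly its frames", {
  cfg <- synthetic_config(p_on = 1, q_spont = 0, stream_flip = 0,
                          frames_per_video = 40, seed = 5)
  eps <- tibble::tibble(start_frame = 11L, end_frame = 20L,
                        emotion = "Happiness")
  orig <- generate_original(cfg, 0L, 0L, episodes = eps)
  lab <- label_video(orig$dynamic, cfg$rules)
  expect_equal(which(lab[, "Happiness"]), 11:20)
  expect_equal(sum(lab[, "Happiness"]), 10)
  expect_true(all(lab[-(11:20), "Neutral"]))
})

test_that("generation is bit-identical under a fixed seed and extensible", {
  cfg <- synthetic_config(seed = 9, frames_per_video = 60)
  a <- generate_original(cfg, 1L, 0L)
  b <- generate_original(cfg, 1L, 0L)
  expect_identical(a$dynamic$presence, b$dynamic$presence)
  expect_identical(a$static$presence, b$static$presence)
  expect_identical(a$episodes, b$episodes)
  # per-video substreams: other videos do not perturb this one
  big <- synthetic_config(seed = 9, frames_per_video = 60,
                          originals_per_performer = 3)
  c <- generate_original(big, 1L, 0L)
  expect_identical(a$dynamic$presence, c$dynamic$presence)
  # the two model-variant streams are distinct noise realisations
  expect_false(identical(a$dynamic$presence, a$static$presence))
})

test_that("fidelity limits behave as perfect copy and pure noise", {
  cfg1 <- synthetic_config(fidelity = 1, seed = 13, frames_per_video = 80)
  orig <- generate_original(cfg1, 0L, 0L)$dynamic
  fake <- derive_fake(orig, cfg1, 1L)
  expect_identical(fake$presence, orig$presence)
  expect_equal(fake$video_id, "id0_id1_0000")
  expect_equal(fake$donor_performer, 1L)

  cfg0 <- synthetic_config(fidelity = 0, q_spont = 0, seed = 13,
                           frames_per_video = 80)
  zero <- derive_fake(generate_original(cfg0, 0L, 0L)$dynamic, cfg0, 1L)
  expect_true(all(zero$presence == 0L))
})

test_that("simulated datasets follow the naming convention and ground truth log", {
  cfg <- synthetic_config(n_performers = 3, originals_per_performer = 2,
                          fakes_per_original = 2, frames_per_video = 40,
                          seed = 2)
  ds <- simulate_dataset(cfg)
  # 6 originals + 12 fakes, both variants each
  expect_length(ds$tables, 36)
  ids <- vapply(ds$tables, function(t) t$video_id, character(1))
  expect_true(all(grepl("^id[0-9]+(_id[0-9]+)?_[0-9]{4}$", ids)))
  # every identity parses and indexes cleanly per variant
  idx <- index_dataset(unique(ids))
  expect_equal(sum(idx$performers$n_originals), 6L)
  expect_equal(sum(idx$performers$n_fake_recordings), 12L)
  expect_equal(nrow(idx$orphans), 0)
  # fakes never use their own performer as donor
  donors <- vapply(ds$tables, function(t) t$donor_performer, integer(1))
  targets <- vapply(ds$tables, function(t) t$target_performer, integer(1))
  expect_true(all(is.na(donors) | donors != targets))
  # ground-truth log covers originals only
  expect_true(all(ds$episode_log$video_id %in% ids[is.na(donors)]))
})

test_that("written dataset trees round-trip through the reader", {
  cfg <- synthetic_config(n_performers = 2, originals_per_performer = 1,
                          fakes_per_original = 1, frames_per_video = 25,
                          seed = 4)
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "episode_log.csv")))
  expect_true(file.exists(file.path(dir, "config.txt")))
  back <- read_au_csv(file.path(dir, "dynamic", "id0_0000.csv"))
  orig <- ds$tables[[which(vapply(
    ds$tables, function(t) t$video_id == "id0_0000" &&
      t$model_variant == "dynamic", logical(1)))]]
  expect_equal(unname(back$presence), unname(orig$presence))
  expect_equal(au_universe(back), cfg$rules$universe)
})

test_that("the fidelity estimator recovers the copy probability", {
  # exact limit: perfect copy, no spontaneous noise
  exact <- run_fidelity_probe(1, n_frames = 3000, seed = 8, q_spont = 0)
  expect_equal(exact$rho_hat, 1)
  # consistency at moderate n
  est <- run_fidelity_probe(0.5, n_frames = 3e4, seed = 8)
  expect_true(abs(est$rho_hat - 0.5) < 4 * est$se)
  # degenerate probe: constant original stream carries no information
  expect_warning(
    deg <- estimate_fidelity(0, 0, 3, n_frames = 100),
    class = "emotransfer_undefined_estimate")
  expect_false(deg$defined)
})

test_that("the estimator is monotone in the common count at fixed marginals", {
  n <- 1000L
  m1 <- 300L  # original-on frames; fake marginal fixed via epfa = k_total - epc
  k_total <- 200L
  grid <- 60:140
  rho <- vapply(grid, function(epc) {
    estimate_fidelity(epc, m1 - epc, k_total - epc, n_frames = n)$rho_hat
  }, numeric(1))
  expect_true(all(diff(rho) > 0))
})
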