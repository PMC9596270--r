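test_that("a hand-counted single-pair dataset reproduces manual enumeration", {
  dir <- withr::local_tempdir()
  dir.create(file.path(dir, "dynamic"))
  orig <- make_table(list(c(6, 12), c(6, 12), integer(0), c(1, 4), 9))
  fake <- make_table(list(c(6, 12), integer(0), integer(0), c(1, 4), c(6, 12)),
                     video_id = "id0_id1_0000", donor = 1L)
  write_au_csv(orig, file.path(dir, "dynamic", "id0_0000.csv"))
  write_au_csv(fake, file.path(dir, "dynamic", "id0_id1_0000.csv"))
  out <- file.path(dir, "report")
  res <- run_analyze(dir, out)

  t3 <- readr::read_csv(file.path(out, "table3.csv"), show_col_types = FALSE)
  row <- function(e) t3[t3$emotion == e, ]
  expect_equal(unlist(row("Happiness")[, c("EPC", "EPOA", "EPFA")],
                      use.names = FALSE), c(1, 1, 1))
  expect_equal(row("Happiness")$pct_common, 50)
  expect_equal(unlist(row("Sadness")[, c("EPC", "EPOA", "EPFA")],
                      use.names = FALSE), c(1, 0, 0))
  expect_equal(row("Sadness")$pct_common, 100)
  expect_equal(unlist(row("Neutral")[, c("EPC", "EPOA", "EPFA")],
                      use.names = FALSE), c(1, 0, 1))
  expect_equal(row("Neutral")$pct_fake_alone, 100)
  # frame 5 of the original ({9} alone) completes no rule and is not Neutral
  expect_equal(unlist(row("Disgust")[, c("EPC", "EPOA", "EPFA")],
                      use.names = FALSE), c(0, 0, 0))
  expect_false(row("Disgust")$defined)

  t4 <- readr::read_csv(file.path(out, "table4.csv"), show_col_types = FALSE)
  expect_equal(unlist(t4[, c("OR", "PF", "FRP", "CO", "OA", "FA")],
                      use.names = FALSE), c(1, 1, 1, 2, 1, 1))

  t2 <- readr::read_csv(file.path(out, "table2.csv"), show_col_types = FALSE)
  expect_equal(t2$pct_recordings[t2$emotion == "Happiness"], 100)
  expect_equal(t2$pct_recordings[t2$emotion == "Anger"], 0)
})

test_that("analyzing an empty input directory is a format error", {
  dir <- withr::local_tempdir()
  expect_error(run_analyze(dir, file.path(dir, "out")),
               class = "emotransfer_format_error")
  expect_error(analyze_tables(list()), class = "emotransfer_format_error")
})

test_that("re-running the analysis writes byte-identical reports", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_performers = 2, originals_per_performer = 1,
                          fakes_per_original = 1, frames_per_video = 60,
                          seed = 31)
  run_simulate(cfg, file.path(dir, "data"))
  run_analyze(file.path(dir, "data"), file.path(dir, "r1"))
  run_analyze(file.path(dir, "data"), file.path(dir, "r2"))
  for (f in list.files(file.path(dir, "r1"))) {
    expect_identical(readLines(file.path(dir, "r1", f)),
                     readLines(file.path(dir, "r2", f)), label = f)
  }
})

test_that("pooled Fear agreement never exceeds Sadness or Surprise agreement", {
  # Fear's AU set contains both the Sadness and the Surprise sets, so on any
  # aligned frame a joint Fear flag implies joint Sadness and Surprise flags
  cfg <- synthetic_config(n_performers = 3, originals_per_performer = 2,
                          fakes_per_original = 2, frames_per_video = 150,
                          episode_rate = 0.05, fidelity = 0.8, seed = 17)
  res <- analyze_tables(simulate_dataset(cfg))
  wide <- res$pair_counts
  for (v in unique(wide$model_variant)) {
    for (pid in unique(wide$fake_id)) {
      sel <- wide[wide$model_variant == v & wide$fake_id == pid, ]
      expect_lte(sel$epc[sel$emotion == "Fear"],
                 min(sel$epc[sel$emotion == "Sadness"],
                     sel$epc[sel$emotion == "Surprise"]))
    }
  }
})

test_that("forcing every emotion into every original empties the exclusion lists", {
  cfg <- synthetic_config(n_performers = 2, originals_per_performer = 1,
                          fakes_per_original = 1, frames_per_video = 130,
                          p_on = 1, q_spont = 0, stream_flip = 0,
                          fidelity = 1, seed = 23)
  eps <- tibble::tibble(start_frame = seq(1L, 121L, by = 20L),
                        end_frame = seq(10L, 130L, by = 20L),
                        emotion = c(emotions(), "Happiness"))
  tables <- list()
  for (p in 0:1) {
    orig <- generate_original(cfg, p, 0L, episodes = eps)
    fake_d <- derive_fake(orig$dynamic, cfg, 1L - p)
    tables <- c(tables, list(orig$dynamic, fake_d))
  }
  res <- analyze_tables(tables)
  expect_equal(nrow(res$exclusions$excluded), 0)
  expect_equal(nrow(res$exclusions$summary), 0)
})

test_that("duplicate (video, variant) tables are rejected", {
  tab <- make_table(list(c(6, 12)))
  expect_error(analyze_tables(list(tab, tab)),
               class = "emotransfer_identity_error")
})
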