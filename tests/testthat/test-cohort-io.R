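test_that("EDF write/read round-trips within one quantization step", {
  set.seed(1)
  x <- matrix(rnorm(3 * 128 * 4, sd = 20), ncol = 4)
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(x, fs = 128, channels = c("F3", "F4", "C3", "C4"), path = f)
  rec <- read_edf(f)
  expect_equal(rec$fs, 128)
  expect_equal(rec$channels, c("F3", "F4", "C3", "C4"))
  # one 16-bit step per channel, plus slack for the ASCII-rounded range
  tol <- max(rec$quant_step) * 1.5
  expect_lt(max(abs(rec$signals - x)), tol)
})

test_that("a synthetic cohort survives a disk round trip", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  manifest <- write_cohort(co, dir)
  eeg <- manifest$path[manifest$kind == "eeg"]
  co2 <- read_cohort(eeg, file.path(dir, "labels.csv"),
                     file.path(dir, "montage.yaml"),
                     trial_duration = co$trial_sets[[1]]$trial_duration)
  expect_equal(subject_ids(co2), subject_ids(co))
  for (s in subject_ids(co)) {
    a <- co$trial_sets[[s]]; b <- co2$trial_sets[[s]]
    expect_equal(b$labels$valence, a$labels$valence)
    expect_equal(b$labels$arousal, a$labels$arousal)
    # EDF stores 16-bit integers over the per-channel range
    rel_tol <- max(abs(a$signals)) * 2.2 / 65534
    expect_lt(max(abs(b$signals - a$signals)), rel_tol * 2)
  }
})

test_that("label-table problems are hard errors naming the culprit", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  manifest <- write_cohort(co, dir)
  eeg <- manifest$path[manifest$kind == "eeg"]
  lab <- readr::read_csv(file.path(dir, "labels.csv"), show_col_types = FALSE)

  bad <- lab
  bad$valence_label[3] <- 2
  f <- file.path(dir, "bad.csv"); readr::write_csv(bad, f)
  expect_error(read_cohort(eeg, f, file.path(dir, "montage.yaml"), 10),
               "non-binary label")

  missing <- lab[lab$subject_id != "S02", ]
  f2 <- file.path(dir, "missing.csv"); readr::write_csv(missing, f2)
  expect_error(read_cohort(eeg, f2, file.path(dir, "montage.yaml"), 10),
               "S02 missing")
})

test_that("a montage/channel-count mismatch is a hard error", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  manifest <- write_cohort(co, dir)
  eeg <- manifest$path[manifest$kind == "eeg"]
  small_m <- montage_1020(c("F3", "F4"))
  f <- file.path(dir, "montage2.yaml")
  write_montage(small_m, f)
  expect_error(read_cohort(eeg, file.path(dir, "labels.csv"), f, 10),
               "channels")
})

test_that("a full-size cohort has the canonical shape", {
  spec <- cohort_spec(n_subjects = 26, fs = 100, seed = 5)
  co <- generate_cohort(spec)
  expect_length(co$trial_sets, 26L)
  for (ts in co$trial_sets) {
    expect_equal(dim(ts$signals), c(16L, 30L, 30L * 100L))
    expect_equal(sum(ts$labels$valence), 8L)
    expect_equal(sum(ts$labels$arousal), 8L)
  }
})
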