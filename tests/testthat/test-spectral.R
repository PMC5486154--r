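one_channel_trial_set <- function(x, fs, n_trials = 1, duration = length(x) / fs) {
  sig <- array(rep(x, each = n_trials), dim = c(n_trials, 1L, length(x)))
  trial_set("X01", sig, fs,
            tibble::tibble(trial_index = seq_len(n_trials),
                           valence = rep_len(0:1, n_trials),
                           arousal = rep_len(0:1, n_trials)),
            trial_duration = duration)
}

test_that("frame count follows the 50%-overlap window grid", {
  fs <- 128
  ts <- one_channel_trial_set(rnorm(30 * fs), fs)
  bp <- stft_band_power(ts)
  expect_equal(dim(bp$power)[4L], 59L)  # starts 0, 0.5, ..., 29.0 s
  expect_equal(bp$frame_starts[1:3], c(0, 0.5, 1.0))
  short <- one_channel_trial_set(rnorm(64), fs, duration = 0.5)
  expect_error(stft_band_power(short), "shorter than one")
})

test_that("zero input gives zero power; a 10 Hz tone lands in alpha", {
  fs <- 128
  bp0 <- stft_band_power(one_channel_trial_set(numeric(4 * fs), fs))
  expect_true(all(bp0$power == 0))

  tone <- sin(2 * pi * 10 * (0:(6 * fs - 1)) / fs)
  bp <- stft_band_power(one_channel_trial_set(tone, fs))
  alpha <- bp$power[1, 1, 3, ]
  for (b in c(1, 2, 4, 5)) {
    expect_true(all(alpha > bp$power[1, 1, b, ]))
  }
})

test_that("band powers match a direct DFT oracle on short signals", {
  fs <- 128
  set.seed(3)
  x <- rnorm(2 * fs)
  bp <- stft_band_power(one_channel_trial_set(x, fs))
  oracle <- dft_band_power_oracle(x, fs)
  expect_equal(bp$power[1, 1, , ], oracle, tolerance = 1e-6)
})

test_that("gain calibration is a baseline-relative ratio", {
  fs <- 128
  ts <- one_channel_trial_set(rnorm(8 * fs), fs)
  bp <- stft_band_power(ts)

  # constant series -> identically 1
  bpc <- bp
  bpc$power[] <- 3.7
  expect_true(all(abs(gain_calibrate(bpc)$power - 1) < 1e-12))

  # scale invariance: doubling all power cancels in the ratio
  bp2 <- bp
  bp2$power <- bp$power * 2
  expect_equal(gain_calibrate(bp2)$power, gain_calibrate(bp)$power)

  # plain arithmetic: baseline mean 2, later value 3 -> 1.5
  bpa <- bp
  bpa$power[] <- 2
  bpa$power[, , , dim(bp$power)[4L]] <- 3
  cal <- gain_calibrate(bpa)
  expect_equal(unique(as.vector(cal$power[, , , dim(bp$power)[4L]])), 1.5)

  # degenerate zero baseline is a hard error
  bpz <- bp
  bpz$power[] <- 0
  expect_error(gain_calibrate(bpz), "zero baseline")
})

make_band_power <- function(power, fs = 128, frame_step = 0.5,
                            channels = c("C3", "C4")) {
  n_frames <- dim(power)[4L]
  starts <- (seq_len(n_frames) - 1L) * frame_step
  n_trials <- dim(power)[1L]
  structure(
    list(power = power, frame_starts = starts, window = 1,
         frame_step = frame_step, fs = fs, bands = band_scheme()$band,
         subject_id = "M01",
         labels = tibble::tibble(trial_index = seq_len(n_trials),
                                 valence = rep_len(0:1, n_trials),
                                 arousal = rep_len(0:1, n_trials)),
         trial_duration = starts[n_frames] + 1, calibrated = TRUE,
         baseline_frames = which(starts + 1 <= 5)),
    class = "ctl_band_power"
  )
}

test_that("DLAT is the left-minus-right pooled difference with 60 default columns", {
  # left power = right power + 1 on one band -> that feature is exactly 1
  p <- array(1, dim = c(2, 2, 5, 15))
  p[, 1, 2, ] <- 2
  bp <- make_band_power(p)
  m <- montage_1020(c("C3", "C4"))
  f <- dlat_features(bp, m)
  expect_equal(feature_cols(f), paste0("C3C4_", band_scheme()$band))
  expect_equal(f$C3C4_theta, c(1, 1))
  expect_true(all(as.matrix(f[setdiff(feature_cols(f), "C3C4_theta")]) == 0))

  # full chain, default montage: 12 pairs x 5 bands = 60 features
  feats <- small_features()
  expect_length(feature_cols(feats), 60L)

  # mirrored signals on every pair -> all features 0
  fs <- 128
  x <- rnorm(8 * fs)
  sig <- array(0, dim = c(1, 2, length(x)))
  sig[1, 1, ] <- x; sig[1, 2, ] <- x
  ts <- trial_set("Y01", sig, fs,
                  tibble::tibble(trial_index = 1, valence = 0, arousal = 0),
                  trial_duration = 8)
  mirr <- stft_band_power(ts) |> gain_calibrate() |> dlat_features(m)
  expect_true(all(abs(as.matrix(mirr[feature_cols(mirr)])) < 1e-12))

  # an uncalibrated series and a pairless montage are refused
  expect_error(dlat_features(stft_band_power(ts), m), "calibrated")
  expect_error(dlat_features(bp, montage_1020(c("Cz", "Fz"))), "no symmetric pairs")
})

test_that("swapping every pair's left/right negates all features", {
  set.seed(9)
  p <- array(rexp(2 * 2 * 5 * 15), dim = c(2, 2, 5, 15))
  bp <- make_band_power(p)
  m <- montage_1020(c("C3", "C4"))
  m_swapped <- montage_1020(c("C3", "C4"),
                            pairs = data.frame(left = "C4", right = "C3"))
  a <- dlat_features(bp, m)
  b <- dlat_features(bp, m_swapped)
  expect_equal(as.matrix(b[feature_cols(b)]),
               -as.matrix(a[feature_cols(a)]), ignore_attr = TRUE)
})

test_that("within-subject z-scoring standardizes with the n denominator and is idempotent", {
  feats <- small_features()
  for (s in unique(feats$subject_id)) {
    sub <- feats[feats$subject_id == s, ]
    fm <- as.matrix(sub[feature_cols(sub)])
    expect_lt(max(abs(colMeans(fm))), 1e-9)
    expect_lt(max(abs(colMeans(fm^2) - 1)), 1e-9)
  }
  expect_equal(zscore_within_subject(feats), feats, tolerance = 1e-12)

  # hand check: column [1, 3] -> [-1, 1]
  df <- tibble::tibble(subject_id = "a", trial_index = 1:2,
                       valence = 0:1, arousal = 0:1, f = c(1, 3))
  expect_equal(zscore_within_subject(df)$f, c(-1, 1))

  # constant column -> 0 with a warning
  dfc <- dplyr::mutate(df, f = 2)
  expect_warning(z <- zscore_within_subject(dfc), "constant")
  expect_equal(z$f, c(0, 0))
})

test_that("permuting trial order permutes feature rows identically", {
  co <- small_cohort()
  ts <- co$trial_sets[[1]]
  perm <- c(3L, 1L, 4L, 2L, 8L, 6L, 5L, 7L)
  ts_p <- trial_set(ts$subject_id, ts$signals[perm, , , drop = FALSE], ts$fs,
                    tibble::tibble(trial_index = seq_along(perm),
                                   valence = ts$labels$valence[perm],
                                   arousal = ts$labels$arousal[perm]),
                    ts$trial_duration)
  chain <- function(t) {
    stft_band_power(t) |> gain_calibrate() |> dlat_features(co$montage)
  }
  a <- chain(ts); b <- chain(ts_p)
  expect_equal(as.matrix(b[feature_cols(b)]),
               as.matrix(a[feature_cols(a)])[perm, ], ignore_attr = TRUE)
})
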