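#' The five stereotyped EEG frequency bands
#'
#' delta 1-3 Hz, theta 4-7 Hz, alpha 8-13 Hz, beta 14-30 Hz, gamma 31-50 Hz.
#' Band edges are inclusive at the periodogram's native 1 Hz resolution (1-s
#' analysis window); bins outside 1-50 Hz are discarded, which realizes the
#' broadband band-pass.
#'
#' @return Tibble with columns `band`, `low`, `high` (Hz), ordered by `low`.
#' @export
band_scheme <- function() {
  tibble(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    low  = c(1, 4, 8, 14, 31),
    high = c(3, 7, 13, 30, 50)
  )
}

hamming_window <- function(n) {
  # periodic-symmetric Hamming as in signal::hamming (symmetric form)
  as.numeric(signal::hamming(n))
}

#' Short-time Fourier transform band power of one subject's trials
#'
#' Slides a Hamming-windowed analysis window over each trial and channel,
#' takes the periodogram per frame, and averages the power of the bins whose
#' center frequency falls inside each band (inclusive edges). Band power is a
#' mean (not sum) over bins so bands of different widths are comparable.
#'
#' @param ts A [trial_set()].
#' @param scheme Band definitions, default [band_scheme()].
#' @param window Analysis window length in seconds (default 1).
#' @param overlap Fractional window overlap (default 0.5).
#' @return Object of class `ctl_band_power`: list with `power` array
#'   `[n_trials x n_channels x n_bands x n_frames]`, `frame_starts` (s),
#'   `window` (s), `frame_step` (s), plus subject metadata. Power is in
#'   periodogram PSD units until calibrated.
#' @export
stft_band_power <- function(ts, scheme = band_scheme(), window = 1, overlap = 0.5) {
  stopifnot(inherits(ts, "ctl_trial_set"))
  fs <- ts$fs
  if (fs < 100) abort("sampling rate must be >= 100 Hz so gamma (<= 50 Hz) is below Nyquist")
  stopifnot(all(diff(scheme$low) > 0), all(scheme$low <= scheme$high))
  d <- dim(ts$signals)
  nwin <- round(window * fs)
  if (d[3L] < nwin) abort("trial shorter than one analysis window")
  step <- round(nwin * (1 - overlap))
  starts <- seq(1L, d[3L] - nwin + 1L, by = step)
  n_frames <- length(starts)

  w <- hamming_window(nwin)
  pscale <- 1 / (fs * sum(w^2))
  freqs <- (seq_len(nwin) - 1L) * fs / nwin
  keep <- freqs >= 1 & freqs <= 50 & seq_len(nwin) <= floor(nwin / 2) + 1L
  band_bins <- lapply(seq_len(nrow(scheme)), function(b) {
    which(keep & freqs >= scheme$low[b] & freqs <= scheme$high[b])
  })
  if (any(lengths(band_bins) == 0L)) abort("a band contains no frequency bin")

  power <- array(0, dim = c(d[1L], d[2L], nrow(scheme), n_frames))
  for (tr in seq_len(d[1L])) {
    x <- t(matrix(ts$signals[tr, , ], nrow = d[2L]))  # n_samples x n_channels
    for (f in seq_along(starts)) {
      seg <- x[starts[f]:(starts[f] + nwin - 1L), , drop = FALSE] * w
      spec <- Mod(mvfft(seg))^2 * pscale
      for (b in seq_along(band_bins)) {
        bb <- band_bins[[b]]
        power[tr, , b, f] <- if (length(bb) == 1L) spec[bb, ] else colMeans(spec[bb, , drop = FALSE])
      }
    }
  }
  structure(
    list(power = power, frame_starts = (starts - 1L) / fs, window = window,
         frame_step = step / fs, fs = fs, bands = scheme$band,
         subject_id = ts$subject_id, labels = ts$labels,
         trial_duration = ts$trial_duration, calibrated = FALSE),
    class = "ctl_band_power"
  )
}

#' Gain-model baseline calibration of band-power series
#'
#' Divides each (trial, channel, band) power time series by the mean power of
#' the frames lying fully inside the trial's first `baseline` seconds,
#' yielding a dimensionless gain ratio relative to the pre-stimulus interval.
#'
#' @param bp A `ctl_band_power` from [stft_band_power()].
#' @param baseline Baseline length in seconds (default 5).
#' @return The calibrated `ctl_band_power` (`calibrated = TRUE`, with the
#'   baseline frame indices recorded in `baseline_frames`).
#' @export
gain_calibrate <- function(bp, baseline = 5) {
  stopifnot(inherits(bp, "ctl_band_power"))
  if (bp$trial_duration <= baseline) abort("trial_duration must exceed the baseline")
  base_idx <- which(bp$frame_starts + bp$window <= baseline)
  if (length(base_idx) == 0L) abort("no frame lies fully inside the baseline")
  d <- dim(bp$power)
  base_mean <- apply(bp$power[, , , base_idx, drop = FALSE], c(1L, 2L, 3L), mean)
  if (any(base_mean == 0)) {
    abort("zero baseline mean power (degenerate input); cannot calibrate")
  }
  bp$power <- bp$power / array(base_mean, dim = d)  # recycles over frames
  bp$calibrated <- TRUE
  bp$baseline_frames <- base_idx
  bp
}

feature_name <- function(left, right, band) paste0(left, right, "_", band)

#' Meta (non-feature) columns of a feature tibble
#' @keywords internal
#' @export
meta_cols <- function() c("subject_id", "trial_index", "valence", "arousal")

#' Names of the feature columns of a DLAT feature tibble
#' @param x A feature tibble as returned by [dlat_features()].
#' @return Character vector of feature column names.
#' @export
feature_cols <- function(x) setdiff(names(x), meta_cols())

#' Differential laterality (DLAT) features
#'
#' For every left-right symmetric channel pair and band, the hemispheric
#' asymmetry feature is the temporal mean (over post-baseline frames) of
#' left-channel minus right-channel calibrated band power. With the default
#' 30-channel montage (12 pairs) and 5 bands this yields 60 features per
#' trial. Column order is pair-major, band-minor; names follow
#' `"<left><right>_<band>"` (e.g. `F3F4_alpha`).
#'
#' @param bp A gain-calibrated `ctl_band_power`.
#' @param montage A [montage_1020()] whose pairs define the features.
#' @param include_baseline If `TRUE`, baseline frames also enter the temporal
#'   pooling (default `FALSE`: the baseline defines the reference, not the
#'   response).
#' @return A tibble with columns `subject_id`, `trial_index`, `valence`,
#'   `arousal`, then one numeric column per (pair, band) feature.
#' @export
dlat_features <- function(bp, montage = montage_1020(), include_baseline = FALSE) {
  stopifnot(inherits(bp, "ctl_band_power"), inherits(montage, "ctl_montage"))
  if (!isTRUE(bp$calibrated)) {
    abort("band power must be gain-calibrated before DLAT extraction")
  }
  if (nrow(montage$pairs) == 0L) abort("montage has no symmetric pairs")
  frames <- seq_along(bp$frame_starts)
  if (!include_baseline) frames <- setdiff(frames, bp$baseline_frames)
  li <- match(montage$pairs$left, montage$channels)
  ri <- match(montage$pairs$right, montage$channels)
  n_trials <- dim(bp$power)[1L]
  n_bands <- dim(bp$power)[3L]
  vals <- matrix(0, nrow = n_trials, ncol = nrow(montage$pairs) * n_bands)
  cn <- character(ncol(vals))
  k <- 0L
  for (p in seq_len(nrow(montage$pairs))) {
    diffp <- bp$power[, li[p], , frames, drop = FALSE] -
      bp$power[, ri[p], , frames, drop = FALSE]
    pooled <- apply(diffp, c(1L, 3L), mean)   # trials x bands
    for (b in seq_len(n_bands)) {
      k <- k + 1L
      vals[, k] <- pooled[, b]
      cn[k] <- feature_name(montage$pairs$left[p], montage$pairs$right[p], bp$bands[b])
    }
  }
  colnames(vals) <- cn
  bind_cols(
    tibble(subject_id = bp$subject_id,
           trial_index = bp$labels$trial_index,
           valence = bp$labels$valence,
           arousal = bp$labels$arousal),
    as_tibble(vals)
  )
}

#' Z-transform features within subject
#'
#' Standardizes every feature column to zero mean and unit variance across
#' each subject's trials, using the population (n) denominator. Columns with
#' zero variance are set to 0 and reported via a warning.
#'
#' @param features Feature tibble from [dlat_features()] (one or more
#'   subjects). Idempotent: applying twice gives the same result.
#' @return The standardized feature tibble.
#' @export
zscore_within_subject <- function(features) {
  fcols <- feature_cols(features)
  flagged <- character(0)
  out <- features |>
    group_by(.data$subject_id) |>
    group_modify(function(df, key) {
      if (nrow(df) < 2L) abort("z-scoring needs at least 2 trials per subject")
      for (f in fcols) {
        v <- df[[f]]
        s <- sqrt(mean((v - mean(v))^2))
        if (s > 0) {
          df[[f]] <- (v - mean(v)) / s
        } else {
          df[[f]] <- rep(0, length(v))
          flagged <<- c(flagged, paste0(key$subject_id, ":", f))
        }
      }
      df
    }) |>
    ungroup()
  if (length(flagged) > 0) {
    warn(paste0("constant feature column(s) set to 0: ",
                paste(head(flagged, 5L), collapse = ", "),
                if (length(flagged) > 5L) " ..."))
  }
  select(out, all_of(names(features)))
}

#' Extract z-scored DLAT features for a whole cohort
#'
#' Runs the full per-subject chain: STFT band power, gain-model baseline
#' calibration, DLAT laterality differencing with temporal pooling, then
#' within-subject z-transform.
#'
#' @param x A `ctl_cohort`.
#' @inheritParams stft_band_power
#' @inheritParams gain_calibrate
#' @inheritParams dlat_features
#' @param zscore Standardize within subject (default `TRUE`).
#' @return Feature tibble (one row per subject-trial; see [dlat_features()]).
#' @export
#' @examples
#' co <- generate_cohort(cohort_spec(n_subjects = 2, duration = 8, seed = 1))
#' feats <- extract_features(co)
#' dim(feats)
extract_features <- function(x, scheme = band_scheme(), window = 1,
                             overlap = 0.5, baseline = 5,
                             include_baseline = FALSE, zscore = TRUE) {
  stopifnot(inherits(x, "ctl_cohort"))
  feats <- bind_rows(lapply(x$trial_sets, function(ts) {
    stft_band_power(ts, scheme = scheme, window = window, overlap = overlap) |>
      gain_calibrate(baseline = baseline) |>
      dlat_features(montage = x$montage, include_baseline = include_baseline)
  }))
  if (zscore) feats <- zscore_within_subject(feats)
  feats
}

#' @importFrom dplyr group_modify bind_cols
NULL
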