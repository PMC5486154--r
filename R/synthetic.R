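#' Default class-discriminative (pair, band) slots
#'
#' The synthetic generator plants the class signal on a distributed set of
#' asymmetry slots: fronto-central alpha plus frontal theta for valence
#' (frontal alpha asymmetry is the classic valence marker) and
#' fronto-parietal beta plus temporal gamma for arousal. Eight slots per
#' task give each subject's discriminative signature enough dimensionality
#' that inter-subject signature similarity is a meaningful quantity:
#' idiosyncratic (random) signatures are then close to orthogonal to the
#' cohort-common one instead of aligning with it by chance.
#'
#' @return Named list of tibbles (`valence`, `arousal`) with columns
#'   `left`, `right`, `band`.
#' @export
default_active_slots <- function() {
  list(
    valence = tibble(
      left = c("Fp1", "F3", "F7", "FC3", "C3", "P3", "F3", "F7"),
      right = c("Fp2", "F4", "F8", "FC4", "C4", "P4", "F4", "F8"),
      band = c(rep("alpha", 6), "theta", "theta")
    ),
    arousal = tibble(
      left = c("F3", "FC3", "C3", "CP3", "P3", "T5", "T3", "T5"),
      right = c("F4", "FC4", "C4", "CP4", "P4", "T6", "T4", "T6"),
      band = c(rep("beta", 6), "gamma", "gamma")
    )
  )
}

#' Specify a synthetic EEG cohort
#'
#' Describes a multi-subject cohort mirroring a music-listening emotion
#' experiment: per subject, `n_trials` balanced-label trials of `duration`
#' seconds over a 30-channel montage. Two generative knobs realize the two
#' transfer-learning hypotheses: `engagement` scales each subject's
#' class-signal amplitude (0 = pure noise, no class information), and
#' `signature_similarity` (rho) mixes a cohort-common discriminative
#' asymmetry pattern with a subject-specific one (1 = identical signatures
#' across subjects, 0 = fully idiosyncratic).
#'
#' @param n_subjects Number of subjects (default 26).
#' @param n_trials Trials per subject (default 16; must be even, labels are
#'   balanced per task).
#' @param fs Sampling rate in Hz (default 250).
#' @param duration Trial length in seconds (default 30).
#' @param montage A [montage_1020()].
#' @param engagement Per-subject signal-to-noise scaling, recycled to
#'   `n_subjects`; must be `>= 0`.
#' @param signature_similarity Per-subject rho in `[0, 1]`, recycled.
#' @param effect_size Amplitude of the planted band-power asymmetry at
#'   engagement 1 (fractional amplitude modulation, default 0.4).
#' @param active_slots Task-wise (pair, band) slots carrying class signal
#'   (default [default_active_slots()]).
#' @param baseline Unmodulated pre-stimulus seconds at the start of every
#'   trial (default 5).
#' @param pink_sd Pink-noise background standard deviation in microvolts.
#' @param band_sd Per-band rhythm standard deviations in microvolts.
#' @param pink_exponent Spectral exponent of the 1/f background (default 1).
#' @param seed Generator seed.
#' @return A `ctl_cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 26, n_trials = 16, fs = 250,
                        duration = 30, montage = montage_1020(),
                        engagement = 1, signature_similarity = 0.7,
                        effect_size = 0.4,
                        active_slots = default_active_slots(),
                        baseline = 5, pink_sd = 10,
                        band_sd = c(delta = 4, theta = 4, alpha = 5,
                                    beta = 4, gamma = 3),
                        pink_exponent = 1, seed = 1) {
  spec <- list(
    n_subjects = as.integer(n_subjects), n_trials = as.integer(n_trials),
    fs = fs, duration = duration, montage = montage,
    engagement = rep_len(engagement, n_subjects),
    signature_similarity = rep_len(signature_similarity, n_subjects),
    effect_size = effect_size, active_slots = active_slots,
    baseline = baseline, pink_sd = pink_sd, band_sd = band_sd,
    pink_exponent = pink_exponent, seed = as.integer(seed)
  )
  validate_cohort_spec(spec)
  structure(spec, class = "ctl_cohort_spec")
}

validate_cohort_spec <- function(spec) {
  if (spec$n_subjects < 1L) abort("n_subjects must be >= 1")
  if (spec$n_trials < 2L || spec$n_trials %% 2L != 0L) {
    abort("n_trials must be even (balanced labels)")
  }
  if (any(spec$engagement < 0)) abort("engagement must be >= 0")
  if (any(spec$signature_similarity < 0 | spec$signature_similarity > 1)) {
    abort("signature_similarity must be in [0, 1]")
  }
  if (spec$duration <= spec$baseline) abort("duration must exceed the baseline")
  if (spec$fs < 100) abort("fs must be >= 100 Hz")
  pair_key <- paste0(spec$montage$pairs$left, spec$montage$pairs$right)
  for (task in names(spec$active_slots)) {
    sl <- spec$active_slots[[task]]
    if (!all(paste0(sl$left, sl$right) %in% pair_key)) {
      abort(paste0("active slot pair not in montage (task ", task, ")"))
    }
    if (!all(sl$band %in% band_scheme()$band)) {
      abort(paste0("unknown band in active slots (task ", task, ")"))
    }
  }
  invisible(TRUE)
}

# Draw the per-subject discriminative pattern vectors (one per task), as
# rho * cohort-common + (1 - rho) * subject-specific, unit-normalized.
# Isolated here with its own derived seed so planted_truth() can replay it
# without regenerating signals.
draw_patterns <- function(spec) {
  set.seed(derive_seed(spec$seed, 101))
  tasks <- names(spec$active_slots)
  common <- lapply(tasks, function(task) rnorm(nrow(spec$active_slots[[task]])))
  names(common) <- tasks
  pats <- lapply(seq_len(spec$n_subjects), function(s) {
    p <- lapply(tasks, function(task) {
      own <- rnorm(nrow(spec$active_slots[[task]]))
      rho <- spec$signature_similarity[s]
      v <- rho * common[[task]] + (1 - rho) * own
      v / sqrt(sum(v^2))
    })
    names(p) <- tasks
    p
  })
  list(common = common, subject = pats)
}

subject_label <- function(i) sprintf("S%02d", i)

# Gaussian series with prescribed spectral amplitude profile, via inverse
# FFT of Hermitian-symmetric complex noise. amp has one entry per positive-
# frequency bin (1 .. n/2 - 1); series variance is 2 * sum(amp^2) / n^2.
spectral_series <- function(n, amp, n_series, scale_to_sd = NULL) {
  half <- n %/% 2L
  stopifnot(length(amp) == half - 1L)
  if (!is.null(scale_to_sd)) {
    amp <- amp * n * scale_to_sd / sqrt(2 * sum(amp^2))
  }
  eps <- matrix(complex(real = rnorm((half - 1L) * n_series),
                        imaginary = rnorm((half - 1L) * n_series)),
                nrow = half - 1L) / sqrt(2)
  X <- matrix(0 + 0i, nrow = n, ncol = n_series)
  X[2:half, ] <- amp * eps
  X[n:(half + 2L), ] <- Conj(X[2:half, , drop = FALSE])
  Re(mvfft(X, inverse = TRUE)) / n
}

#' Generate a synthetic multi-subject EEG cohort
#'
#' Every channel carries a 1/f (pink) background plus band-limited Gaussian
#' rhythms in the five stereotyped bands. On the active (pair, band) slots,
#' the rhythm amplitude after the baseline interval is modulated in
#' opposite directions on the left and right channel of the pair:
#' `1 +/- engagement * effect_size * pattern_slot`, with the sign set by the
#' trial's class label. The baseline seconds are never modulated, so
#' gain-model calibration against them exposes the planted asymmetry, and
#' class information lives purely in the band-power domain (the only domain
#' the feature pipeline observes). Labels are exactly balanced per task and
#' drawn independently for valence and arousal.
#'
#' @param spec A [cohort_spec()].
#' @return A `ctl_cohort` carrying the planted ground truth as attribute
#'   `"planted_truth"` (see [planted_truth()]).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "ctl_cohort_spec"))
  validate_cohort_spec(spec)
  pats <- draw_patterns(spec)
  n <- as.integer(spec$fs * spec$duration)
  half <- n %/% 2L
  freqs <- (1:(half - 1L)) / spec$duration
  scheme <- band_scheme()
  channels <- spec$montage$channels
  nch <- length(channels)

  # relative 1/f amplitude, scaled to pink_sd
  pink_rel <- freqs^(-spec$pink_exponent / 2)
  pink_amp <- pink_rel * n * spec$pink_sd / sqrt(2 * sum(pink_rel^2))
  band_bins <- lapply(seq_len(nrow(scheme)), function(b) {
    which(freqs >= scheme$low[b] & freqs <= scheme$high[b])
  })
  band_amp <- lapply(seq_len(nrow(scheme)), function(b) {
    a <- numeric(half - 1L)
    a[band_bins[[b]]] <- 1
    a * n * spec$band_sd[[b]] / sqrt(2 * length(band_bins[[b]]))
  })

  # active (channel, band) modulation bookkeeping: one row per channel side
  act <- list()
  for (task in names(spec$active_slots)) {
    sl <- spec$active_slots[[task]]
    for (j in seq_len(nrow(sl))) {
      b <- match(sl$band[j], scheme$band)
      act[[length(act) + 1L]] <- tibble(
        task = task, slot = j, band = b,
        channel = c(match(sl$left[j], channels), match(sl$right[j], channels)),
        side = c(1, -1)
      )
    }
  }
  act <- bind_rows(act)
  # channels whose background must exclude an (already separately generated)
  # active band component
  excl <- unique(act[c("channel", "band")])

  # per-channel background amplitude profile
  base_amp2 <- pink_amp^2 + Reduce(`+`, lapply(band_amp, function(a) a^2))
  bg_amp <- lapply(seq_len(nch), function(ch) {
    a2 <- base_amp2
    for (r in which(excl$channel == ch)) a2 <- a2 - band_amp[[excl$band[r]]]^2
    sqrt(pmax(a2, 0))
  })

  set.seed(derive_seed(spec$seed, 202))
  labels <- lapply(seq_len(spec$n_subjects), function(s) {
    tibble(
      trial_index = seq_len(spec$n_trials),
      valence = sample(rep(0:1, each = spec$n_trials / 2L)),
      arousal = sample(rep(0:1, each = spec$n_trials / 2L))
    )
  })

  post <- (seq_len(n) - 1L) / spec$fs >= spec$baseline
  trial_sets <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    set.seed(derive_seed(spec$seed, 303, s))
    sig <- array(0, dim = c(spec$n_trials, nch, n))
    for (tr in seq_len(spec$n_trials)) {
      # backgrounds for all channels in one batch
      eps <- matrix(complex(real = rnorm((half - 1L) * nch),
                            imaginary = rnorm((half - 1L) * nch)),
                    nrow = half - 1L) / sqrt(2)
      X <- matrix(0 + 0i, nrow = n, ncol = nch)
      for (ch in seq_len(nch)) X[2:half, ch] <- bg_amp[[ch]] * eps[, ch]
      X[n:(half + 2L), ] <- Conj(X[2:half, , drop = FALSE])
      bg <- Re(mvfft(X, inverse = TRUE)) / n

      # separately generated active-band rhythms, amplitude-modulated after
      # the baseline according to the trial's class label
      mod <- numeric(nrow(act))
      for (r in seq_len(nrow(act))) {
        lab <- labels[[s]][[act$task[r]]][tr]
        pat <- pats$subject[[s]][[act$task[r]]][act$slot[r]]
        mod[r] <- (2 * lab - 1) * spec$engagement[s] * spec$effect_size *
          pat * act$side[r]
      }
      u <- matrix(0, nrow = n, ncol = nrow(act))
      for (r in seq_len(nrow(act))) {
        u[, r] <- spectral_series(n, band_amp[[act$band[r]]], 1L)
      }
      for (r in seq_len(nrow(act))) {
        a <- ifelse(post, pmax(1 + mod[r], 0.05), 1)
        bg[, act$channel[r]] <- bg[, act$channel[r]] + a * u[, r]
      }
      sig[tr, , ] <- t(bg)
    }
    sid <- subject_label(s)
    trial_sets[[s]] <- trial_set(sid, sig, spec$fs, labels[[s]],
                                 trial_duration = spec$duration)
  }
  out <- cohort(trial_sets, spec$montage)
  attr(out, "planted_truth") <- planted_truth_from_patterns(spec, pats)
  out
}

planted_truth_from_patterns <- function(spec, pats, poor_threshold = 0) {
  ids <- vapply(seq_len(spec$n_subjects), subject_label, character(1))
  tasks <- names(spec$active_slots)
  sim <- lapply(tasks, function(task) {
    P <- vapply(pats$subject, function(p) p[[task]],
                numeric(nrow(spec$active_slots[[task]])))
    colnames(P) <- ids
    suppressWarnings(cor(P))
  })
  names(sim) <- tasks
  list(
    subjects = tibble(
      subject_id = ids,
      engagement = spec$engagement,
      signature_similarity = spec$signature_similarity,
      expected_transferability = ifelse(spec$engagement <= poor_threshold,
                                        "poor", "good")
    ),
    patterns = pats,
    similarity = sim
  )
}

#' Planted ground truth of a synthetic cohort
#'
#' Exposes what the generator planted: per-subject engagement and the
#' engagement-derived expected transferability label (`poor` when a subject
#' carries no class signal), plus the true inter-subject pattern-correlation
#' matrix per task, for parameter-recovery tests.
#'
#' @param x A `ctl_cohort` produced by [generate_cohort()] or a
#'   [cohort_spec()].
#' @param ... Passed on (unused).
#' @return List with `subjects` (tibble), `patterns`, `similarity` (named
#'   list of correlation matrices).
#' @export
planted_truth <- function(x, ...) UseMethod("planted_truth")

#' @export
planted_truth.ctl_cohort <- function(x, ...) {
  pt <- attr(x, "planted_truth")
  if (is.null(pt)) abort("cohort carries no planted truth (not generated by generate_cohort)")
  pt
}

#' @export
planted_truth.ctl_cohort_spec <- function(x, ...) {
  planted_truth_from_patterns(x, draw_patterns(x))
}
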