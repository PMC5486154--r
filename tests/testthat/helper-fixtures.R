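# Shared fixtures (generated once per test run) and independent brute-force
# oracles used by several test files.

.fix <- new.env(parent = emptyenv())

# 5 subjects x 8 trials at a reduced sampling rate: fast but runs the full
# raw-signal -> feature chain.
small_cohort <- function() {
  if (is.null(.fix$cohort)) {
    spec <- cohort_spec(n_subjects = 5, n_trials = 8, fs = 128, duration = 10,
                        seed = 42)
    .fix$cohort <- generate_cohort(spec)
  }
  .fix$cohort
}

small_features <- function() {
  if (is.null(.fix$feats)) .fix$feats <- extract_features(small_cohort())
  .fix$feats
}

# 3 subjects x 16 trials: the canonical trial count, short trials.
features16 <- function() {
  if (is.null(.fix$feats16)) {
    spec <- cohort_spec(n_subjects = 3, n_trials = 16, fs = 128, duration = 8,
                        seed = 7)
    .fix$feats16 <- extract_features(generate_cohort(spec))
  }
  .fix$feats16
}

quick_cfg <- function(...) {
  do.call(pipeline_config,
          utils::modifyList(list(n_balance_reps = 20, seed = 99), list(...)))
}

# ReliefF brute force, k = 1, m = "all": enumerate every instance's nearest
# hit and miss directly (Manhattan on max-min scaled features, distance ties
# by ascending instance index).
relieff_oracle_k1 <- function(X, y) {
  n <- nrow(X); p <- ncol(X)
  Xs <- X
  for (j in seq_len(p)) {
    r <- diff(range(X[, j]))
    Xs[, j] <- if (r > 0) (X[, j] - min(X[, j])) / r else 0
  }
  W <- numeric(p)
  for (i in seq_len(n)) {
    d <- rowSums(abs(Xs - matrix(Xs[i, ], n, p, byrow = TRUE)))
    hits <- setdiff(which(y == y[i]), i)
    misses <- which(y != y[i])
    h <- hits[order(d[hits], hits)][1L]
    m <- misses[order(d[misses], misses)][1L]
    W <- W - abs(Xs[h, ] - Xs[i, ]) / n + abs(Xs[m, ] - Xs[i, ]) / n
  }
  W
}

# Gaussian naive Bayes posterior by direct density multiplication.
gnb_posterior_oracle <- function(model, x) {
  lik <- vapply(1:2, function(ci) {
    model$priors[ci] * prod(stats::dnorm(x, mean = model$means[ci, ],
                                         sd = sqrt(model$variances[ci, ])))
  }, numeric(1))
  lik / sum(lik)
}

# Pearson correlation from first principles.
pearson_oracle <- function(a, b) {
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

pop_sd_oracle <- function(x) sqrt(mean((x - mean(x))^2))

# Direct DFT band power oracle: no fft(), plain complex exponential sums.
dft_band_power_oracle <- function(x, fs, window = 1, overlap = 0.5,
                                  scheme = band_scheme()) {
  nwin <- round(window * fs)
  step <- round(nwin * (1 - overlap))
  starts <- seq(1L, length(x) - nwin + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nwin - 1L)) / (nwin - 1L))
  freqs <- (0:(nwin - 1L)) * fs / nwin
  keep <- freqs >= 1 & freqs <= 50 & seq_len(nwin) <= floor(nwin / 2) + 1L
  out <- matrix(0, nrow = nrow(scheme), ncol = length(starts))
  for (f in seq_along(starts)) {
    seg <- x[starts[f]:(starts[f] + nwin - 1L)] * w
    spec <- vapply(0:(nwin - 1L), function(k) {
      Mod(sum(seg * exp(-2i * pi * k * (0:(nwin - 1L)) / nwin)))^2
    }, numeric(1)) / (fs * sum(w^2))
    for (b in seq_len(nrow(scheme))) {
      bins <- which(keep & freqs >= scheme$low[b] & freqs <= scheme$high[b])
      out[b, f] <- mean(spec[bins])
    }
  }
  out
}

# Minimal hand-built scenario result for comparison tests.
fake_scenario <- function(label, accs, defaults = rep(0.5, length(accs))) {
  structure(
    list(scenario = label, task = "valence", config = pipeline_config(),
         subjects = tibble::tibble(
           subject_id = sprintf("S%02d", seq_along(accs)),
           default_acc = defaults, tl_acc = NA_real_, scenario_acc = accs,
           transferable = "good", O_used = NA_integer_,
           dissimilarity = NA_real_, improvement = accs - defaults
         ),
         folds = tibble::tibble()),
    class = "ctl_scenario"
  )
}

# One-subject feature tibble with controllable separability: feature "sig"
# encodes the label with the given margin, the rest are standard normal noise.
toy_subject_features <- function(n_trials = 16, n_noise = 9, margin = 4,
                                 subject_id = "T01", seed = 1) {
  set.seed(seed)
  lab <- sample(rep(0:1, each = n_trials / 2))
  x <- matrix(rnorm(n_trials * n_noise), n_trials, n_noise,
              dimnames = list(NULL, paste0("noise", seq_len(n_noise))))
  tibble::as_tibble(x) |>
    dplyr::mutate(
      subject_id = subject_id, trial_index = seq_len(n_trials),
      valence = lab, arousal = lab,
      sig = ifelse(lab == 1, margin, -margin) + rnorm(n_trials, sd = 0.1),
      .before = 1
    )
}
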