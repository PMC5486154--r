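test_that("generation is seed-deterministic and validates its spec", {
  spec <- cohort_spec(n_subjects = 2, n_trials = 4, fs = 128, duration = 6,
                      seed = 31)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$trial_sets[["S01"]]$signals, b$trial_sets[["S01"]]$signals)
  expect_identical(a$trial_sets[["S01"]]$labels, b$trial_sets[["S01"]]$labels)
  c2 <- generate_cohort(cohort_spec(n_subjects = 2, n_trials = 4, fs = 128,
                                    duration = 6, seed = 32))
  expect_false(identical(a$trial_sets[["S01"]]$signals,
                         c2$trial_sets[["S01"]]$signals))

  expect_error(cohort_spec(n_trials = 7), "even")
  expect_error(cohort_spec(engagement = -1), "engagement")
  expect_error(cohort_spec(signature_similarity = 2), "similarity")
  expect_error(cohort_spec(duration = 4), "baseline")
})

test_that("planted truth replays from the spec and encodes the knobs", {
  spec <- cohort_spec(n_subjects = 4, n_trials = 4, fs = 128, duration = 6,
                      engagement = c(0, 1, 1, 0),
                      signature_similarity = c(1, 1, 0.3, 0.6), seed = 33)
  co <- generate_cohort(spec)
  pt_cohort <- planted_truth(co)
  pt_spec <- planted_truth(spec)
  expect_equal(pt_spec$patterns, pt_cohort$patterns)
  expect_equal(pt_cohort$subjects$expected_transferability,
               c("poor", "good", "good", "poor"))
  # rho = 1 subjects share the cohort-common pattern exactly
  expect_equal(pt_cohort$similarity$valence["S01", "S02"], 1)
  expect_true(all(abs(pt_cohort$similarity$arousal) <= 1 + 1e-12))
})

test_that("class-conditional DLAT expectation has the planted sign on active slots", {
  spec <- cohort_spec(n_subjects = 1, n_trials = 200, fs = 128, duration = 8,
                      engagement = 2, signature_similarity = 1, seed = 34)
  co <- generate_cohort(spec)
  feats <- extract_features(co, zscore = FALSE)
  pt <- planted_truth(co)
  y <- feats$valence
  slots <- default_active_slots()$valence
  slot_names <- paste0(slots$left, slots$right, "_", slots$band)
  tvals <- vapply(feature_cols(feats), function(f) {
    unname(t.test(feats[[f]][y == 1], feats[[f]][y == 0])$statistic)
  }, numeric(1))
  pat <- pt$patterns$subject[[1]]$valence
  # slots with substantial pattern loading must show the planted sign; a
  # near-zero loading has no detectable (or meaningful) sign
  for (j in which(abs(pat) >= 0.2)) {
    expect_equal(sign(tvals[[slot_names[j]]]), sign(pat[j]))
    expect_gt(abs(tvals[[slot_names[j]]]), 3)
  }
  expect_gte(sum(abs(pat) >= 0.2), 2L)
  # arousal slots are modulated by the (independent) arousal labels only, and
  # all remaining slots carry no class signal at all
  inactive <- setdiff(feature_cols(feats),
                      c(slot_names,
                        with(default_active_slots()$arousal,
                             paste0(left, right, "_", band))))
  expect_lt(max(abs(tvals[inactive])), 4)
})

test_that("engagement drives default accuracy monotonically from chance", {
  accs <- vapply(c(0, 0.5, 2), function(eng) {
    per_seed <- vapply(1:3, function(seed) {
      spec <- cohort_spec(n_subjects = 2, n_trials = 16, fs = 128,
                          duration = 8, engagement = eng,
                          signature_similarity = 1, seed = 40 + seed)
      feats <- extract_features(generate_cohort(spec))
      cfg <- pipeline_config(task = "valence", n_balance_reps = 20,
                             seed = 40 + seed)
      mean(vapply(unique(feats$subject_id), function(s) {
        lto_default_accuracy(feats[feats$subject_id == s, ], cfg)$accuracy
      }, numeric(1)))
    }, numeric(1))
    mean(per_seed)
  }, numeric(1))
  # seed-averaged accuracy never decreases with the planted effect size
  expect_true(all(diff(accs) > -0.02))
  # and the extremes behave as constructed: no signal ~ chance, strong
  # shared signal well above 0.8
  expect_lt(abs(accs[1] - 0.5), 0.12)
  expect_gt(accs[3], 0.8)
})

test_that("signal-carrying subjects are gated 'good' and noise subjects sit at chance", {
  good_labels <- c(); noise_accs <- c()
  for (seed in 1:6) {
    spec <- cohort_spec(n_subjects = 3, n_trials = 16, fs = 128, duration = 8,
                        engagement = c(0, 1.5, 1.5),
                        signature_similarity = 1, seed = 50 + seed)
    co <- generate_cohort(spec)
    feats <- extract_features(co)
    cfg <- pipeline_config(task = "valence", n_balance_reps = 20,
                           seed = 50 + seed)
    accs <- vapply(subject_ids(co), function(s) {
      lto_default_accuracy(feats[feats$subject_id == s, ], cfg)$accuracy
    }, numeric(1))
    gates <- classify_transferability(accs)
    good_labels <- c(good_labels, gates[c("S02", "S03")])
    noise_accs <- c(noise_accs, accs[["S01"]])
  }
  # engagement-positive subjects recovered as good in >= 90% of cases
  expect_gte(mean(good_labels == "good"), 0.9)
  # a zero-engagement subject's accuracy is statistically at chance: its gate
  # label is a coin toss, not a recoverable parameter
  expect_lt(abs(mean(noise_accs) - 0.5), 0.15)
})

test_that("ReliefF weight spaces recover the planted similarity ordering", {
  rhos <- c()
  for (seed in 1:3) {
    spec <- cohort_spec(n_subjects = 5, n_trials = 16, fs = 128, duration = 8,
                        engagement = 2,
                        signature_similarity = c(1, 1, 0.5, 0.25, 0),
                        seed = 60 + seed)
    co <- generate_cohort(spec)
    feats <- extract_features(co)
    pt <- planted_truth(co)
    ws <- lapply(subject_ids(co), function(s) {
      df <- feats[feats$subject_id == s, ]
      relieff_weights(df, df$valence)
    })
    names(ws) <- subject_ids(co)
    prof <- similarity_profile(ws[["S01"]], ws[-1])
    true_r <- pt$similarity$valence["S01", prof$ss_id]
    rhos <- c(rhos, cor(prof$r, true_r, method = "spearman"))
  }
  expect_gte(mean(rhos), 0.6)
})
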