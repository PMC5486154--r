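#' Pipeline configuration
#'
#' Bundles the knobs of the leave-trial-out transfer pipeline.
#'
#' @param task Classification task: `"valence"` or `"arousal"`.
#' @param O Number of source subjects to borrow from (default `NULL`: all
#'   available sources).
#' @param source_mode Rank sources by `"similar"` (descending correlation,
#'   default) or `"dissimilar"`.
#' @param n_balance_reps Class-balanced subsampling repetitions in the
#'   feature-count optimization (default 500).
#' @param n_cv_folds Cross-validation folds inside the optimization
#'   (default 5).
#' @param chance_level Transferability gate threshold (default 0.5, the
#'   two-class chance level).
#' @param gate_source `"outer_default"` (default): good/poor from the
#'   subject's own full leave-trial-out default accuracy. `"nested"`: the gate
#'   is re-estimated inside each fold from the 15 training trials only, for
#'   strictly prospective use.
#' @param relieff_k ReliefF neighbor count (default `NULL`: 10, clipped to
#'   the smallest class size minus 1).
#' @param seed Master seed; every random draw in the pipeline flows from it
#'   through a documented per-(subject, fold, repetition) derivation.
#' @param audit Record the training-row identities of every fold for the
#'   leakage audit (default `TRUE`).
#' @return A `ctl_config` list.
#' @export
pipeline_config <- function(task = c("valence", "arousal"), O = NULL,
                            source_mode = c("similar", "dissimilar"),
                            n_balance_reps = 500, n_cv_folds = 5,
                            chance_level = 0.5,
                            gate_source = c("outer_default", "nested"),
                            relieff_k = NULL, seed = 1, audit = TRUE) {
  cfg <- list(
    task = match.arg(task), O = O, source_mode = match.arg(source_mode),
    n_balance_reps = as.integer(n_balance_reps),
    n_cv_folds = as.integer(n_cv_folds), chance_level = chance_level,
    gate_source = match.arg(gate_source), relieff_k = relieff_k,
    seed = as.integer(seed), audit = isTRUE(audit)
  )
  stopifnot(cfg$n_balance_reps >= 1L, cfg$n_cv_folds >= 2L)
  structure(cfg, class = "ctl_config")
}

# Deterministic seed stream: fold master seed with each id through a
# Lehmer-style step, staying below 2^31 - 1.
derive_seed <- function(master, ...) {
  s <- as.double(master) %% 2147483647
  for (id in c(...)) {
    s <- (s * 69069 + as.double(id) + 1) %% 2147483647
  }
  as.integer(s)
}

id_hash <- function(id) {
  h <- 0
  for (c in utf8ToInt(as.character(id))) h <- (h * 31 + c) %% 1048573
  h
}

#' Label a subject's transferability from default accuracy
#'
#' A target subject is `"poor"` (and hence a transfer candidate) when the
#' default model trained solely on the subject's own data performs at or
#' below chance; `"good"` otherwise. The boundary is inclusive on the poor
#' side: exactly chance-level accuracy means poor.
#'
#' @param default_acc Default leave-trial-out accuracy in `[0, 1]`.
#' @param chance Chance level (default 0.5 for two classes).
#' @return `"good"` or `"poor"` (vectorized).
#' @export
#' @examples
#' classify_transferability(c(0.50, 0.5001, 0.2179))
classify_transferability <- function(default_acc, chance = 0.5) {
  stopifnot(all(default_acc >= 0 & default_acc <= 1))
  ifelse(default_acc <= chance, "poor", "good")
}

#' Augment a target subject's training trials with source-subject trials
#'
#' Row-concatenates the target's training feature rows with every trial of
#' each selected source subject, keeping the source labels unchanged. With
#' `O` sources of 16 trials each and 15 target training trials the augmented
#' set has `15 + O * 16` rows. Row provenance is retained in `subject_id`.
#'
#' @param ts_train Target subject's training feature tibble.
#' @param sources List of full source-subject feature tibbles.
#' @return The pooled feature tibble.
#' @export
augment_training_set <- function(ts_train, sources) {
  fc <- feature_cols(ts_train)
  for (s in sources) {
    if (!identical(feature_cols(s), fc)) {
      abort("feature descriptor mismatch between target and source feature sets")
    }
  }
  bind_rows(c(list(ts_train), sources))
}

#' Optimize the feature count on a training set
#'
#' Computes the ReliefF ranking on the full training set, then repeatedly
#' (`n_balance_reps` times) subsamples the majority class without replacement
#' down to the minority size, runs stratified k-fold cross-validation, and
#' scores a Gaussian naive Bayes classifier on the top-`d` ranked features
#' for every `d` ("add one feature in"). The selected `d` maximizes the mean
#' CV accuracy pooled over repetitions and folds; ties go to the smallest
#' `d`. If the minority class has fewer instances than `n_cv_folds`, each
#' repetition uses leave-one-out CV instead (with a message).
#'
#' @param x Training features (matrix or feature tibble).
#' @param y Binary labels.
#' @param cfg A [pipeline_config()].
#' @param rw Optional precomputed [relieff_weights()] for `x`.
#' @param seed Seed for the subsample/fold draws (default derived from
#'   `cfg$seed`).
#' @return List with `d` (selected count), `curve` (mean CV accuracy per
#'   feature count), `rw` (the ReliefF weights used).
#' @export
optimize_feature_count <- function(x, y, cfg = pipeline_config(), rw = NULL,
                                   seed = derive_seed(cfg$seed, 0)) {
  xm <- features_as_matrix(x)
  y <- as_binary_labels(y)
  if (is.null(rw)) rw <- relieff_weights(xm, y, k = cfg$relieff_k)
  idx0 <- which(y == 0); idx1 <- which(y == 1)
  mn <- min(length(idx0), length(idx1))
  if (mn < 1L) abort("both classes must be present")
  loo <- mn < cfg$n_cv_folds
  if (loo) message("minority class < ", cfg$n_cv_folds,
                   " instances; using leave-one-out CV in each repetition")
  ns <- 2L * mn
  K <- if (loo) ns else cfg$n_cv_folds
  R <- cfg$n_balance_reps
  balanced <- length(idx0) == length(idx1)

  sub_idx <- matrix(0L, ns, R)
  fold_id <- matrix(0L, ns, R)
  set.seed(seed)
  for (r in seq_len(R)) {
    sub <- if (balanced) {
      c(idx0, idx1)   # identity: no subsampling needed
    } else if (length(idx0) > length(idx1)) {
      c(sample(idx0, mn), idx1)
    } else {
      c(idx0, sample(idx1, mn))
    }
    sub_idx[, r] <- sub
    if (loo) {
      fold_id[, r] <- seq_len(ns)
    } else {
      # stratified: each class spread evenly over folds
      fold_id[, r] <- c(sample(rep_len(seq_len(K), mn)),
                        sample(rep_len(seq_len(K), mn)))
    }
  }
  curve <- cpp_cv_curve(xm, as.integer(y), as.integer(rw$ranking),
                        sub_idx, fold_id, as.integer(K))
  list(d = which.max(curve), curve = curve, rw = rw)
}

# Train the final GNB on one seeded class-balanced subsample of the training
# set, restricted to the top-d ranked features.
fit_final_gnb <- function(xm, y, feat_idx, seed) {
  idx0 <- which(y == 0); idx1 <- which(y == 1)
  mn <- min(length(idx0), length(idx1))
  set.seed(seed)
  rows <- c(if (length(idx0) > mn) sample(idx0, mn) else idx0,
            if (length(idx1) > mn) sample(idx1, mn) else idx1)
  gnb_fit(xm[rows, feat_idx, drop = FALSE], y[rows])
}

# One subject's leave-trial-out evaluation; ss_features/ss_weights == NULL
# gives the default (no-transfer) pipeline, otherwise each fold runs the
# transfer chain: similarity profile from the fold's training trials, source
# selection, augmentation, re-ranking, feature-count optimization, final fit.
# transfer_gate, if given, is called on each fold's training tibble and may
# veto the transfer branch for that fold (prospective "nested" gating).
lto_run <- function(ts_features, cfg, ss_features = NULL, ss_weights = NULL,
                    transfer_gate = NULL) {
  ts_features <- arrange(ts_features, .data$trial_index)
  sid <- ts_features$subject_id[1L]
  shash <- id_hash(sid)
  y <- as_binary_labels(ts_features[[cfg$task]])
  n <- nrow(ts_features)
  if (n < 4L) abort("leave-trial-out needs at least 4 trials")
  xm_all <- features_as_matrix(ts_features)
  transfer <- !is.null(ss_features) && length(ss_features) > 0L

  fold_rows <- vector("list", n)
  train_keys <- vector("list", n)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L) {
      warn(paste0("subject ", sid, ", fold ", i,
                  ": training trials contain one class only; fold skipped"))
      fold_rows[[i]] <- tibble(
        subject_id = sid, fold = i, trial_index = ts_features$trial_index[i],
        d = NA_integer_, predicted = NA_real_, actual = y[i],
        correct = NA, dissimilarity = NA_real_, n_train = NA_integer_
      )
      next
    }
    train_tbl <- ts_features[-i, , drop = FALSE]
    rw_ts <- relieff_weights(xm_all[-i, , drop = FALSE], ytr, k = cfg$relieff_k)
    dissim <- NA_real_
    transfer_i <- transfer &&
      (is.null(transfer_gate) || isTRUE(transfer_gate(train_tbl)))
    if (transfer_i) {
      prof <- similarity_profile(rw_ts, ss_weights)
      O <- cfg$O %||% length(ss_features)
      sel <- select_sources(prof, O, cfg$source_mode)
      if (O >= 2L) dissim <- ts_ss_dissimilarity(prof, sel)
      # augmentation order is canonical (sorted ids): only the selected set,
      # not the selection rank, may influence the downstream model
      aug <- augment_training_set(train_tbl, ss_features[sort(sel)])
      xa <- features_as_matrix(aug)
      ya <- as_binary_labels(aug[[cfg$task]])
      opt <- optimize_feature_count(xa, ya, cfg,
                                    seed = derive_seed(cfg$seed, shash, i, 1))
      fit <- fit_final_gnb(xa, ya, top_features(opt$rw, opt$d),
                           seed = derive_seed(cfg$seed, shash, i, 2))
      keys <- paste0(aug$subject_id, ":", aug$trial_index)
    } else {
      opt <- optimize_feature_count(xm_all[-i, , drop = FALSE], ytr, cfg,
                                    rw = rw_ts,
                                    seed = derive_seed(cfg$seed, shash, i, 1))
      fit <- fit_final_gnb(xm_all[-i, , drop = FALSE], ytr,
                           top_features(opt$rw, opt$d),
                           seed = derive_seed(cfg$seed, shash, i, 2))
      keys <- paste0(sid, ":", ts_features$trial_index[-i])
    }
    feat_idx <- top_features(opt$rw, opt$d)
    pred <- predict(fit, xm_all[i, feat_idx, drop = FALSE], type = "class")
    fold_rows[[i]] <- tibble(
      subject_id = sid, fold = i, trial_index = ts_features$trial_index[i],
      d = opt$d, predicted = pred, actual = y[i], correct = pred == y[i],
      dissimilarity = dissim, n_train = length(keys)
    )
    if (cfg$audit) train_keys[[i]] <- keys
  }
  folds <- bind_rows(fold_rows)
  if (cfg$audit) folds$train_keys <- train_keys
  list(subject_id = sid,
       accuracy = mean(folds$correct, na.rm = TRUE),
       folds = folds)
}

#' Default (no-transfer) leave-trial-out accuracy of one subject
#'
#' Each trial is held out once; the remaining trials drive ReliefF ranking,
#' feature-count optimization, and the final Gaussian naive Bayes fit. The
#' held-out trial never enters any training computation.
#'
#' @param ts_features One subject's feature tibble (see [extract_features()]).
#' @param cfg A [pipeline_config()].
#' @return List with `subject_id`, `accuracy`, and a per-fold tibble `folds`
#'   (selected feature count, prediction, truth, training-row audit keys).
#' @export
lto_default_accuracy <- function(ts_features, cfg = pipeline_config()) {
  stopifnot(length(unique(ts_features$subject_id)) == 1L)
  lto_run(ts_features, cfg)
}

# Nested transferability gate: inner leave-trial-out on the fold's training
# trials only (no information from the held-out trial).
nested_gate_poor <- function(train_tbl, cfg) {
  inner <- lto_run(train_tbl, cfg)
  classify_transferability(inner$accuracy, cfg$chance_level) == "poor"
}

#' Run a transfer-learning scenario over a cohort
#'
#' Each subject is in turn the target subject (TS) and the rest act as source
#' subjects (SSs). Per leave-trial-out fold the transfer chain is: (i)
#' ReliefF on the training trials and similarity profile against each SS's
#' weight space (SS weights come from their full trial sets), (ii) selection
#' of the `O` most similar (or dissimilar) SSs and row-augmentation with all
#' their trials, (iii) ReliefF re-ranking and class-balanced feature-count
#' optimization on the augmented set, (iv) final Gaussian naive Bayes fit and
#' prediction of the held-out trial.
#'
#' Scenario composition: `"default"` never transfers; `"rTL"` (routine)
#' always transfers; `"cTL"` (conditional) transfers only for subjects whose
#' default accuracy is at or below chance; `"oTL"` (oracle) takes the
#' per-subject maximum of default and transferred accuracy.
#'
#' @param features Cohort feature tibble (see [extract_features()]).
#' @param scenario `"default"`, `"rTL"`, `"cTL"`, or `"oTL"`.
#' @param cfg A [pipeline_config()].
#' @return Object of class `ctl_scenario`; see [tidy.ctl_scenario()] /
#'   [glance.ctl_scenario()].
#' @export
run_scenario <- function(features, scenario = c("cTL", "default", "rTL", "oTL"),
                         cfg = pipeline_config()) {
  scenario <- match.arg(scenario)
  subjects <- unique(features$subject_id)
  if (length(subjects) < 3L) abort("a scenario run needs at least 3 subjects")
  feats_by <- split(features, factor(features$subject_id, levels = subjects))
  need_tl <- scenario %in% c("rTL", "cTL", "oTL")

  ss_weights <- NULL
  if (need_tl) {
    ss_weights <- lapply(feats_by, function(df) {
      relieff_weights(features_as_matrix(df), as_binary_labels(df[[cfg$task]]),
                      k = cfg$relieff_k)
    })
  }

  subj_rows <- vector("list", length(subjects))
  fold_tbls <- list()
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    default_res <- lto_run(feats_by[[s]], cfg)
    transferable <- classify_transferability(default_res$accuracy, cfg$chance_level)
    tl_acc <- NA_real_
    dissim <- NA_real_
    O_used <- NA_integer_
    run_tl <- need_tl &&
      (scenario != "cTL" ||
         (cfg$gate_source == "outer_default" && transferable == "poor") ||
         cfg$gate_source == "nested")
    tl_res <- NULL
    if (run_tl) {
      others <- setdiff(subjects, s)
      O_used <- as.integer(cfg$O %||% length(others))
      gate_fn <- NULL
      if (scenario == "cTL" && cfg$gate_source == "nested") {
        cfg_inner <- cfg
        cfg_inner$audit <- FALSE
        gate_fn <- function(train_tbl) nested_gate_poor(train_tbl, cfg_inner)
      }
      tl_res <- lto_run(feats_by[[s]], cfg,
                        ss_features = feats_by[others],
                        ss_weights = ss_weights[others],
                        transfer_gate = gate_fn)
      tl_acc <- tl_res$accuracy
      dissim <- mean(tl_res$folds$dissimilarity, na.rm = TRUE)
    }
    scenario_acc <- switch(scenario,
      default = default_res$accuracy,
      rTL = tl_acc,
      cTL = if (cfg$gate_source == "nested") tl_acc
            else if (transferable == "poor") tl_acc else default_res$accuracy,
      oTL = max(default_res$accuracy, tl_acc, na.rm = TRUE)
    )
    subj_rows[[si]] <- tibble(
      subject_id = s,
      default_acc = default_res$accuracy,
      tl_acc = tl_acc,
      scenario_acc = scenario_acc,
      transferable = transferable,
      O_used = O_used,
      dissimilarity = dissim,
      improvement = scenario_acc - default_res$accuracy
    )
    default_res$folds$branch <- "default"
    fold_tbls[[paste0(s, ".default")]] <- default_res$folds
    if (!is.null(tl_res)) {
      tl_res$folds$branch <- "transfer"
      fold_tbls[[paste0(s, ".transfer")]] <- tl_res$folds
    }
  }
  structure(
    list(scenario = scenario, task = cfg$task, config = cfg,
         subjects = bind_rows(subj_rows), folds = bind_rows(fold_tbls)),
    class = "ctl_scenario"
  )
}

#' @export
print.ctl_scenario <- function(x, ...) {
  g <- glance(x)
  cat("<ctl_scenario> ", x$scenario, " / ", x$task, ": ",
      nrow(x$subjects), " subjects, mean accuracy ",
      sprintf("%.1f%% (sd %.1f), mean improvement %+.1f pts", 100 * g$mean_acc,
              100 * g$sd_acc, 100 * g$mean_improvement), "\n", sep = "")
  invisible(x)
}

#' Tidy / summarize a scenario result
#'
#' `tidy()` returns the per-subject table (default, transferred and scenario
#' accuracies, transferability label, source count, target-source
#' dissimilarity, improvement); `glance()` the cohort-level summary.
#'
#' @param x A `ctl_scenario`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ctl_scenario <- function(x, ...) x$subjects

#' @rdname tidy.ctl_scenario
#' @export
glance.ctl_scenario <- function(x, ...) {
  tibble(
    scenario = x$scenario, task = x$task,
    n_subjects = nrow(x$subjects),
    n_poor = sum(x$subjects$transferable == "poor"),
    mean_default = mean(x$subjects$default_acc),
    sd_default = sd(x$subjects$default_acc),
    mean_acc = mean(x$subjects$scenario_acc),
    sd_acc = sd(x$subjects$scenario_acc),
    mean_improvement = mean(x$subjects$improvement)
  )
}

#' Chance-level calibration of the default pipeline
#'
#' Estimates the no-information accuracy of the default (no-transfer)
#' pipeline: synthetic cohorts are generated, each subject's trial labels are
#' permuted uniformly at random (severing the label-signal association while
#' keeping the class balance), and the full leave-trial-out default pipeline
#' is run. For a calibrated two-class pipeline the mean accuracy sits at the
#' 50% chance level.
#'
#' @param seeds Integer vector; one synthetic cohort (and label permutation
#'   and pipeline run) per seed.
#' @param n_subjects Subjects per cohort (default 8).
#' @param spec_args Extra arguments to [cohort_spec()].
#' @param cfg_args Extra arguments to [pipeline_config()].
#' @return Tibble with one row per (seed, subject): `seed`, `subject_id`,
#'   `accuracy`.
#' @export
chance_level_calibration <- function(seeds, n_subjects = 8,
                                     spec_args = list(), cfg_args = list()) {
  rows <- lapply(seeds, function(seed) {
    spec <- do.call(cohort_spec, modifyList(
      list(n_subjects = n_subjects, seed = derive_seed(seed, 1)), spec_args))
    feats <- extract_features(generate_cohort(spec))
    cfg <- do.call(pipeline_config, modifyList(
      list(n_balance_reps = 50, seed = derive_seed(seed, 2)), cfg_args))
    set.seed(derive_seed(seed, 3))
    feats <- feats |>
      group_by(.data$subject_id) |>
      mutate(dplyr::across(all_of(cfg$task), sample)) |>
      ungroup()
    accs <- vapply(unique(feats$subject_id), function(s) {
      lto_run(feats[feats$subject_id == s, , drop = FALSE], cfg)$accuracy
    }, numeric(1))
    tibble(seed = seed, subject_id = names(accs), accuracy = unname(accs))
  })
  bind_rows(rows)
}

#' Sweep the number of transferred source subjects
#'
#' Re-runs the transfer pipeline for every source count `O` in `O_range` and
#' every ranking mode, and reports the accuracy change relative to each
#' subject's default model, grouped by transferability (good / poor / all).
#'
#' @param features Cohort feature tibble.
#' @param cfg A [pipeline_config()]; its `O`/`source_mode` are ignored in
#'   favor of the sweep grid.
#' @param O_range Integer vector of source counts (default `1:(n_subjects-1)`).
#' @param modes Ranking modes to sweep (default both).
#' @return Object of class `ctl_sweep` with per-(subject, mode, O) results;
#'   `tidy()` gives group mean-improvement curves, `glance()` the argmax per
#'   curve (smallest `O` on ties).
#' @export
sweep_source_count <- function(features, cfg = pipeline_config(),
                               O_range = NULL,
                               modes = c("similar", "dissimilar")) {
  subjects <- unique(features$subject_id)
  n_ss <- length(subjects) - 1L
  if (is.null(O_range)) O_range <- seq_len(n_ss)
  stopifnot(all(O_range >= 1L), all(O_range <= n_ss))
  feats_by <- split(features, factor(features$subject_id, levels = subjects))
  ss_weights <- lapply(feats_by, function(df) {
    relieff_weights(features_as_matrix(df), as_binary_labels(df[[cfg$task]]),
                    k = cfg$relieff_k)
  })
  cfg_quiet <- cfg
  cfg_quiet$audit <- FALSE

  rows <- list()
  for (s in subjects) {
    default_res <- lto_run(feats_by[[s]], cfg_quiet)
    group <- classify_transferability(default_res$accuracy, cfg$chance_level)
    others <- setdiff(subjects, s)
    ts <- arrange(feats_by[[s]], .data$trial_index)
    xm_all <- features_as_matrix(ts)
    y <- as_binary_labels(ts[[cfg$task]])
    shash <- id_hash(s)
    n <- nrow(ts)

    # per-fold pieces shared across (mode, O)
    profs <- vector("list", n)
    for (i in seq_len(n)) {
      ytr <- y[-i]
      if (length(unique(ytr)) < 2L) next
      rw_ts <- relieff_weights(xm_all[-i, , drop = FALSE], ytr, k = cfg$relieff_k)
      profs[[i]] <- similarity_profile(rw_ts, ss_weights[others])
    }
    for (mode in modes) {
      for (O in O_range) {
        correct <- logical(0)
        for (i in seq_len(n)) {
          if (is.null(profs[[i]])) next
          sel <- select_sources(profs[[i]], O, mode)
          aug <- augment_training_set(ts[-i, , drop = FALSE],
                                      feats_by[sort(sel)])
          xa <- features_as_matrix(aug)
          ya <- as_binary_labels(aug[[cfg$task]])
          opt <- optimize_feature_count(xa, ya, cfg,
                                        seed = derive_seed(cfg$seed, shash, i, 1))
          fit <- fit_final_gnb(xa, ya, top_features(opt$rw, opt$d),
                               seed = derive_seed(cfg$seed, shash, i, 2))
          feat_idx <- top_features(opt$rw, opt$d)
          pred <- predict(fit, xm_all[i, feat_idx, drop = FALSE], type = "class")
          correct <- c(correct, pred == y[i])
        }
        rows[[length(rows) + 1L]] <- tibble(
          subject_id = s, group = group, mode = mode, O = O,
          default_acc = default_res$accuracy,
          tl_acc = mean(correct),
          improvement = mean(correct) - default_res$accuracy
        )
      }
    }
  }
  structure(list(results = bind_rows(rows), task = cfg$task, config = cfg),
            class = "ctl_sweep")
}

#' @export
print.ctl_sweep <- function(x, ...) {
  cat("<ctl_sweep> ", x$task, ": ", length(unique(x$results$subject_id)),
      " subjects, O in ", min(x$results$O), "..", max(x$results$O), ", modes ",
      paste(unique(x$results$mode), collapse = "/"), "\n", sep = "")
  print(glance(x))
  invisible(x)
}

sweep_groups <- function(results) {
  bind_rows(
    mutate(results, grp = .data$group),
    mutate(results, grp = "all")
  )
}

#' Tidy / summarize a source-count sweep
#'
#' `tidy()` returns the mean accuracy-change curves per (mode, subject group,
#' O) with a one-sample t-test of the per-subject improvements against zero;
#' `glance()` the maximal-improvement point of each curve (smallest `O` on
#' ties).
#'
#' @param x A `ctl_sweep`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ctl_sweep <- function(x, ...) {
  sweep_groups(x$results) |>
    group_by(.data$mode, .data$grp, .data$O) |>
    summarise(
      n = n(),
      mean_improvement = mean(.data$improvement),
      sd_improvement = sd(.data$improvement),
      p_value = tryCatch(t.test(.data$improvement)$p.value,
                         error = function(e) NA_real_),
      .groups = "drop"
    ) |>
    rename(group = "grp")
}

#' @rdname tidy.ctl_sweep
#' @export
glance.ctl_sweep <- function(x, ...) {
  tidy(x) |>
    group_by(.data$mode, .data$group) |>
    arrange(desc(.data$mean_improvement), .data$O, .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    select("mode", "group", O_best = "O", max_improvement = "mean_improvement")
}

#' Compare scenario results with paired t-tests
#'
#' Pairs per-subject scenario accuracies for every pair of scenario runs, and
#' additionally tests each scenario's per-subject improvement over default
#' against zero. Zero-variance difference vectors are reported as degenerate
#' (a scenario compared to itself gives `t = 0, p = 1`).
#'
#' @param results List of `ctl_scenario` objects over the same subjects.
#' @return Object of class `ctl_comparison` with tibbles `pairwise` and
#'   `improvement`; `tidy()` returns `pairwise`.
#' @export
compare_scenarios <- function(results) {
  stopifnot(length(results) >= 1L)
  labs <- vapply(results, function(r) r$scenario, character(1))
  if (anyDuplicated(labs)) labs <- make.unique(labs)
  ids <- lapply(results, function(r) r$subjects$subject_id)
  for (i in seq_along(ids)) {
    if (!identical(ids[[i]], ids[[1L]])) {
      abort("all scenario results must cover the same subjects in the same order")
    }
  }
  paired_row <- function(a, b, la, lb) {
    d <- a - b
    if (sd(d) == 0) {
      if (all(d == 0)) {
        tibble(scenario_a = la, scenario_b = lb, mean_diff = 0, t = 0,
               df = length(d) - 1, p_value = 1,
               note = "degenerate: identical accuracies")
      } else {
        tibble(scenario_a = la, scenario_b = lb, mean_diff = mean(d),
               t = NA_real_, df = length(d) - 1, p_value = NA_real_,
               note = "degenerate: constant nonzero difference")
      }
    } else {
      tt <- t.test(a, b, paired = TRUE)
      tibble(scenario_a = la, scenario_b = lb, mean_diff = mean(d),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value, note = NA_character_)
    }
  }
  pw <- list()
  for (i in seq_along(results)) {
    for (j in seq_along(results)) {
      if (j <= i) next
      pw[[length(pw) + 1L]] <- paired_row(
        results[[i]]$subjects$scenario_acc, results[[j]]$subjects$scenario_acc,
        labs[i], labs[j]
      )
    }
  }
  if (length(results) == 1L) {
    pw[[1L]] <- paired_row(results[[1L]]$subjects$scenario_acc,
                           results[[1L]]$subjects$scenario_acc,
                           labs[1L], labs[1L])
  }
  impr <- bind_rows(lapply(seq_along(results), function(i) {
    paired_row(results[[i]]$subjects$scenario_acc,
               results[[i]]$subjects$default_acc, labs[i], "default") |>
      rename(scenario = "scenario_a", mean_improvement = "mean_diff") |>
      select(-"scenario_b")
  }))
  structure(list(pairwise = bind_rows(pw), improvement = impr),
            class = "ctl_comparison")
}

#' @export
print.ctl_comparison <- function(x, ...) {
  cat("<ctl_comparison>\n")
  print(x$pairwise)
  invisible(x)
}

#' @export
tidy.ctl_comparison <- function(x, ...) x$pairwise
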