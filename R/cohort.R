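#' Construct one subject's labeled trial set
#'
#' @param subject_id Subject identifier (character scalar).
#' @param signals Numeric array `[n_trials x n_channels x n_samples]`,
#'   microvolts.
#' @param fs Sampling rate in Hz.
#' @param labels Data frame with columns `trial_index` (1..n_trials),
#'   `valence` and `arousal`, each label in `{0, 1}`.
#' @param trial_duration Trial length in seconds; `n_samples` must equal
#'   `fs * trial_duration`.
#' @return Object of class `ctl_trial_set`.
#' @export
trial_set <- function(subject_id, signals, fs, labels, trial_duration = 30) {
  stopifnot(is.array(signals), length(dim(signals)) == 3L)
  labels <- as_tibble(labels)
  if (!all(c("trial_index", "valence", "arousal") %in% names(labels))) {
    abort("labels need columns trial_index, valence, arousal")
  }
  n_trials <- dim(signals)[1L]
  if (nrow(labels) != n_trials) {
    abort(paste0("subject ", subject_id, ": ", nrow(labels),
                 " label rows for ", n_trials, " trials"))
  }
  labels <- arrange(labels, .data$trial_index)
  for (task in c("valence", "arousal")) {
    if (!all(labels[[task]] %in% c(0, 1))) {
      abort(paste0("non-binary label in task '", task, "' for subject ", subject_id))
    }
  }
  if (abs(dim(signals)[3L] - fs * trial_duration) > 1e-9) {
    abort(paste0("subject ", subject_id, ": n_samples (", dim(signals)[3L],
                 ") != fs * trial_duration (", fs * trial_duration, ")"))
  }
  structure(
    list(subject_id = as.character(subject_id), signals = signals, fs = fs,
         labels = labels, trial_duration = trial_duration),
    class = "ctl_trial_set"
  )
}

#' @export
print.ctl_trial_set <- function(x, ...) {
  d <- dim(x$signals)
  cat("<ctl_trial_set> subject ", x$subject_id, ": ", d[1L], " trials x ",
      d[2L], " channels x ", d[3L], " samples (", x$trial_duration,
      " s @ ", x$fs, " Hz)\n", sep = "")
  invisible(x)
}

#' Bundle trial sets from several subjects into a cohort
#'
#' @param trial_sets List of [trial_set()] objects, all sharing the montage's
#'   channel count and a common sampling rate.
#' @param montage A [montage_1020()] object.
#' @return Object of class `ctl_cohort`.
#' @export
cohort <- function(trial_sets, montage = montage_1020()) {
  stopifnot(inherits(montage, "ctl_montage"), length(trial_sets) >= 1L)
  ids <- vapply(trial_sets, function(ts) ts$subject_id, character(1))
  if (anyDuplicated(ids)) abort("duplicated subject ids in cohort")
  fss <- vapply(trial_sets, function(ts) ts$fs, numeric(1))
  if (length(unique(fss)) != 1L) abort("all subjects must share one sampling rate")
  for (ts in trial_sets) {
    if (dim(ts$signals)[2L] != length(montage$channels)) {
      abort(paste0("subject ", ts$subject_id, ": ", dim(ts$signals)[2L],
                   " channels but montage has ", length(montage$channels)))
    }
  }
  structure(list(trial_sets = setNames(trial_sets, ids), montage = montage),
            class = "ctl_cohort")
}

#' @export
print.ctl_cohort <- function(x, ...) {
  cat("<ctl_cohort> ", length(x$trial_sets), " subjects, montage of ",
      length(x$montage$channels), " channels / ", nrow(x$montage$pairs),
      " pairs\n", sep = "")
  invisible(x)
}

#' Subject ids of a cohort
#' @param x A `ctl_cohort`.
#' @return Character vector.
#' @export
subject_ids <- function(x) {
  stopifnot(inherits(x, "ctl_cohort"))
  names(x$trial_sets)
}

#' Write a cohort to disk (EDF + label CSV + montage YAML)
#'
#' One EDF file per subject (trials concatenated in time), a label table
#' `labels.csv` with columns `subject_id, trial_index, valence_label,
#' arousal_label`, and `montage.yaml`.
#'
#' @param x A `ctl_cohort`.
#' @param dir Output directory (created if missing).
#' @return Tibble manifest of written files, invisibly.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "ctl_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  eeg_paths <- character(0)
  lab <- list()
  for (ts in x$trial_sets) {
    d <- dim(ts$signals)
    flat <- matrix(aperm(ts$signals, c(3L, 1L, 2L)), nrow = d[1L] * d[3L], ncol = d[2L])
    p <- file.path(dir, paste0(ts$subject_id, ".edf"))
    write_edf(flat, ts$fs, x$montage$channels, p, recording_id = ts$subject_id)
    eeg_paths <- c(eeg_paths, p)
    lab[[ts$subject_id]] <- tibble(
      subject_id = ts$subject_id,
      trial_index = ts$labels$trial_index,
      valence_label = ts$labels$valence,
      arousal_label = ts$labels$arousal
    )
  }
  label_path <- file.path(dir, "labels.csv")
  readr::write_csv(bind_rows(lab), label_path)
  montage_path <- file.path(dir, "montage.yaml")
  write_montage(x$montage, montage_path)
  invisible(tibble(
    kind = c(rep("eeg", length(eeg_paths)), "labels", "montage"),
    path = c(eeg_paths, label_path, montage_path)
  ))
}

#' Read a multi-subject EEG cohort from disk
#'
#' Reads one EDF file per subject plus a label table and montage definition
#' (the layout written by [write_cohort()]). Subject ids are taken from EDF
#' file names (basename without extension) and must appear in the label
#' table; trial order follows the label table's `trial_index`.
#'
#' @param eeg_paths Character vector of per-subject EDF paths.
#' @param label_table_path CSV with columns `subject_id, trial_index,
#'   valence_label, arousal_label`.
#' @param montage_path Montage YAML (see [read_montage()]).
#' @param trial_duration Trial length in seconds used to split each
#'   recording into trials.
#' @return A `ctl_cohort`.
#' @export
read_cohort <- function(eeg_paths, label_table_path, montage_path,
                        trial_duration = 30) {
  montage <- read_montage(montage_path)
  labels <- readr::read_csv(label_table_path, show_col_types = FALSE)
  need <- c("subject_id", "trial_index", "valence_label", "arousal_label")
  if (!all(need %in% names(labels))) {
    abort(paste0("label table must have columns ", paste(need, collapse = ", ")))
  }
  bad <- !(labels$valence_label %in% c(0, 1)) | !(labels$arousal_label %in% c(0, 1))
  if (any(bad)) {
    abort(paste0("non-binary label for subject(s): ",
                 paste(unique(labels$subject_id[bad]), collapse = ", ")))
  }
  trial_sets <- list()
  for (p in eeg_paths) {
    sid <- sub("\\.edf$", "", basename(p), ignore.case = TRUE)
    sub_lab <- filter(labels, .data$subject_id == sid)
    if (nrow(sub_lab) == 0L) {
      abort(paste0("subject ", sid, " missing from label table"))
    }
    rec <- read_edf(p)
    if (ncol(rec$signals) != length(montage$channels)) {
      abort(paste0("subject ", sid, ": ", ncol(rec$signals),
                   " channels in EDF but montage has ",
                   length(montage$channels)))
    }
    n_trials <- nrow(sub_lab)
    spt <- as.integer(rec$fs * trial_duration)
    if (nrow(rec$signals) < n_trials * spt) {
      abort(paste0("subject ", sid, ": recording shorter than ", n_trials,
                   " trials of ", trial_duration, " s"))
    }
    sig <- array(0, dim = c(n_trials, ncol(rec$signals), spt))
    for (t in seq_len(n_trials)) {
      rows <- ((t - 1L) * spt + 1L):(t * spt)
      sig[t, , ] <- t(rec$signals[rows, , drop = FALSE])
    }
    trial_sets[[sid]] <- trial_set(
      sid, sig, rec$fs,
      tibble(trial_index = sub_lab$trial_index,
             valence = sub_lab$valence_label,
             arousal = sub_lab$arousal_label),
      trial_duration = trial_duration
    )
  }
  cohort(trial_sets, montage)
}
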