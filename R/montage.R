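#' Standard 30-channel 10-20 electrode labels
#'
#' The default montage used throughout the package: a 30-channel extension of
#' the international 10-20 system. Odd final digits denote left-hemisphere
#' electrodes, even digits right-hemisphere, and a trailing `z` the midline.
#'
#' @return Character vector of 30 channel labels.
#' @export
#' @examples
#' channels_1020_30()
channels_1020_30 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FT7", "FC3", "FCz", "FC4", "FT8",
    "T3", "C3", "Cz", "C4", "T4",
    "TP7", "CP3", "CPz", "CP4", "TP8",
    "T5", "P3", "Pz", "P4", "T6",
    "O1", "Oz", "O2")
}

# Old 10-20 names and their modern equivalents; normalized on read so pair
# derivation works on either spelling.
.channel_aliases <- c(T3 = "T7", T4 = "T8", T5 = "P7", T6 = "P8")

#' Normalize 10-20 channel labels
#'
#' Maps legacy temporal labels (T3, T4, T5, T6) to their modern equivalents
#' (T7, T8, P7, P8). Other labels pass through unchanged.
#'
#' @param channels Character vector of channel labels.
#' @return Character vector of normalized labels.
#' @export
normalize_channels <- function(channels) {
  hit <- channels %in% names(.channel_aliases)
  channels[hit] <- .channel_aliases[channels[hit]]
  channels
}

#' Derive left-right symmetric channel pairs from 10-20 labels
#'
#' Under 10-20 nomenclature a left-hemisphere electrode ends in an odd digit
#' and its mirror electrode carries the next even digit (F3/F4, T7/T8, ...).
#' Every channel whose mirror is present forms a pair; midline channels
#' (trailing `z`) and unpartnered channels are excluded. Legacy labels are
#' normalized (T3 is matched with T4 via T7/T8) but reported in their original
#' spelling.
#'
#' @param channels Character vector of channel labels.
#' @return A tibble with columns `left` and `right`, ordered by the position
#'   of the left channel in `channels`.
#' @export
#' @examples
#' derive_symmetric_pairs(channels_1020_30())  # 12 pairs
#' derive_symmetric_pairs(c("C3", "C4", "F3")) # F3 has no partner here
derive_symmetric_pairs <- function(channels) {
  stopifnot(is.character(channels))
  if (anyDuplicated(channels)) {
    abort("duplicated channel labels in montage")
  }
  norm <- normalize_channels(channels)
  last <- substr(norm, nchar(norm), nchar(norm))
  digit <- suppressWarnings(as.integer(last))
  is_left <- !is.na(digit) & digit %% 2L == 1L
  left_idx <- which(is_left)
  lefts <- character(0)
  rights <- character(0)
  for (i in left_idx) {
    mirror <- paste0(substr(norm[i], 1L, nchar(norm[i]) - 1L), digit[i] + 1L)
    j <- match(mirror, norm)
    if (!is.na(j)) {
      lefts <- c(lefts, channels[i])
      rights <- c(rights, channels[j])
    }
  }
  n_dropped <- sum(is_left) - length(lefts)
  if (n_dropped > 0) {
    message(n_dropped, " left channel(s) without a right-hemisphere partner excluded")
  }
  tibble(left = lefts, right = rights)
}

#' Construct an EEG montage
#'
#' A montage bundles the ordered channel labels with the list of left-right
#' symmetric channel pairs used to compute hemispheric-asymmetry (DLAT)
#' features. Pairs are derived automatically from 10-20 nomenclature unless
#' supplied explicitly.
#'
#' @param channels Character vector of channel labels
#'   (default [channels_1020_30()]).
#' @param pairs Optional two-column data frame / tibble (`left`, `right`)
#'   overriding automatic pair derivation.
#' @return An object of class `ctl_montage`: a list with elements `channels`
#'   (character) and `pairs` (tibble with columns `left`, `right`).
#' @export
#' @examples
#' m <- montage_1020()
#' nrow(m$pairs)  # 12
montage_1020 <- function(channels = channels_1020_30(), pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- derive_symmetric_pairs(channels)
  } else {
    pairs <- tibble(left = as.character(pairs[[1]]), right = as.character(pairs[[2]]))
  }
  validate_montage(channels, pairs)
  structure(list(channels = channels, pairs = pairs), class = "ctl_montage")
}

validate_montage <- function(channels, pairs) {
  members <- c(pairs$left, pairs$right)
  if (!all(members %in% channels)) {
    abort(paste0("pair channel(s) not in montage: ",
                 paste(setdiff(members, channels), collapse = ", ")))
  }
  if (anyDuplicated(members)) {
    abort("a channel appears in more than one symmetric pair")
  }
  midline <- grepl("z$", members)
  if (any(midline)) {
    abort(paste0("midline channel(s) cannot form a symmetric pair: ",
                 paste(unique(members[midline]), collapse = ", ")))
  }
  invisible(TRUE)
}

#' @export
print.ctl_montage <- function(x, ...) {
  cat("<ctl_montage> ", length(x$channels), " channels, ",
      nrow(x$pairs), " symmetric pairs\n", sep = "")
  cat("  channels: ", paste(x$channels, collapse = " "), "\n", sep = "")
  cat("  pairs:    ",
      paste(paste0(x$pairs$left, "/", x$pairs$right), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Read / write a montage definition in YAML
#'
#' The file holds `channels:` (list of labels) and optionally `pairs:` (list
#' of two-element lists) overriding automatic derivation.
#'
#' @param path File path.
#' @return `read_montage()` returns a `ctl_montage`; `write_montage()`
#'   returns `path` invisibly.
#' @export
read_montage <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$channels)) abort("montage file lacks a 'channels' entry")
  pairs <- NULL
  if (!is.null(y$pairs)) {
    pairs <- tibble(
      left = vapply(y$pairs, function(p) as.character(p[[1]]), character(1)),
      right = vapply(y$pairs, function(p) as.character(p[[2]]), character(1))
    )
  }
  montage_1020(channels = as.character(unlist(y$channels)), pairs = pairs)
}

#' @param montage A `ctl_montage` object.
#' @rdname read_montage
#' @export
write_montage <- function(montage, path) {
  stopifnot(inherits(montage, "ctl_montage"))
  yaml::write_yaml(
    list(channels = as.list(montage$channels),
         pairs = unname(apply(montage$pairs, 1L, as.list, simplify = FALSE))),
    path
  )
  invisible(path)
}
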