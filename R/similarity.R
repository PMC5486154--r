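#' Inter-subject similarity profile from ReliefF weight spaces
#'
#' Quantifies how similar each source subject's emotion-relevant feature
#' space is to the target subject's, as the Pearson correlation between their
#' ReliefF weight vectors (same feature order). A Spearman option correlates
#' rank orders instead. A zero-variance weight vector gets `r = 0` and is
#' flagged as degenerate.
#'
#' @param w_ts The target subject's [relieff_weights()].
#' @param w_ss Named list of source subjects' `relief_weights` (names are
#'   subject ids).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Object of class `ctl_similarity`: a tibble with columns `ss_id`,
#'   `r`, `degenerate`, plus attribute `ts_id` when `w_ts` carries one.
#' @export
similarity_profile <- function(w_ts, w_ss, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(w_ts, "relief_weights"), length(w_ss) >= 1L)
  if (is.null(names(w_ss)) || any(names(w_ss) == "")) {
    abort("w_ss must be a named list (subject ids)")
  }
  wt <- w_ts$weights
  rows <- imap(w_ss, function(w, id) {
    stopifnot(inherits(w, "relief_weights"))
    if (length(w$weights) != length(wt)) {
      abort("weight vectors must have equal length (same feature order)")
    }
    deg <- sd(w$weights) == 0 || sd(wt) == 0
    r <- if (deg) 0 else cor(wt, w$weights, method = method)
    tibble(ss_id = id, r = r, degenerate = deg)
  })
  out <- bind_rows(rows)
  class(out) <- c("ctl_similarity", class(out))
  out
}

#' Select source subjects by similarity rank
#'
#' `"similar"` ranks source subjects by descending signed correlation (the
#' larger the coefficient, the more similar); `"dissimilar"` by ascending.
#' Rank ties break by ascending subject id.
#'
#' @param profile A [similarity_profile()].
#' @param O Number of source subjects to select (1..n).
#' @param mode `"similar"` or `"dissimilar"`.
#' @return Character vector of `O` subject ids.
#' @export
select_sources <- function(profile, O, mode = c("similar", "dissimilar")) {
  mode <- match.arg(mode)
  n <- nrow(profile)
  if (O < 1L || O > n) abort(paste0("O must be in 1..", n))
  ord <- if (mode == "similar") {
    order(-profile$r, profile$ss_id)
  } else {
    order(profile$r, profile$ss_id)
  }
  profile$ss_id[ord][seq_len(O)]
}

#' Target-source dissimilarity statistic
#'
#' The population standard deviation of the absolute correlation coefficients
#' of the selected target-source pairs: larger values mean a more
#' heterogeneous (dissimilar) set of sources was pooled.
#'
#' @param profile A [similarity_profile()].
#' @param selected Character vector of at least two selected source ids.
#' @return Non-negative scalar.
#' @export
ts_ss_dissimilarity <- function(profile, selected) {
  if (length(selected) < 2L) abort("need at least 2 selected source subjects")
  if (!all(selected %in% profile$ss_id)) abort("unknown source id in 'selected'")
  a <- abs(profile$r[match(selected, profile$ss_id)])
  sqrt(mean((a - mean(a))^2))
}
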