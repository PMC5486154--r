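#' Two-class ReliefF feature relevance weights
#'
#' Neighbor-based relevance weighting: a feature is rewarded when it differs
#' between an instance and its nearest misses (other class) and penalized when
#' it differs from its nearest hits (same class). Features are max-min scaled
#' to `[0, 1]` internally so `diff()` is comparable across features and all
#' weights lie in `[-1, 1]`. Neighbors are found under Manhattan distance on
#' the scaled features; distance ties break by ascending instance index. With
#' `m = "all"` the procedure is fully deterministic.
#'
#' @param x Numeric matrix or feature tibble (feature columns only are used
#'   when meta columns are present).
#' @param y Binary labels (0/1, logical, or 2-level factor), one per row.
#' @param k Number of nearest hits/misses. Default `NULL` uses 10 clipped to
#'   (smallest class size - 1). An explicit `k` must leave every class with
#'   more than `k` members.
#' @param m `"all"` (every instance is used, deterministic; default) or an
#'   integer count of randomly sampled instances.
#' @return Object of class `relief_weights`: list with `weights` (named
#'   numeric), `ranking` (feature indices by descending weight, ties by
#'   ascending index), `k`, `n_sampled`, `feature_names`.
#' @export
#' @examples
#' x <- cbind(f1 = c(0, 0, 1, 1), f2 = rep(0.5, 4))
#' relieff_weights(x, c(0, 0, 1, 1), k = 1)$weights
relieff_weights <- function(x, y, k = NULL, m = "all") {
  x <- features_as_matrix(x)
  y <- as_binary_labels(y)
  n <- nrow(x); p <- ncol(x)
  stopifnot(length(y) == n, n >= 2L)
  if (anyNA(x)) abort("missing values are not supported")
  counts <- table(factor(y, levels = c(0, 1)))
  min_class <- min(counts)
  if (is.null(k)) {
    k <- max(1L, min(10L, min_class - 1L))
  }
  bad <- names(counts)[counts <= k]
  if (length(bad) > 0) {
    abort(paste0("class ", paste(bad, collapse = ", "),
                 " has <= k = ", k, " members"))
  }

  rng <- apply(x, 2L, function(v) diff(range(v)))
  xs <- x
  for (j in seq_len(p)) {
    xs[, j] <- if (rng[j] > 0) (x[, j] - min(x[, j])) / rng[j] else 0
  }

  idx <- if (identical(m, "all")) seq_len(n) else sample.int(n, size = m)
  m_used <- length(idx)
  D <- as.matrix(stats::dist(xs, method = "manhattan"))
  w <- numeric(p)
  for (i in idx) {
    same <- which(y == y[i]); same <- same[same != i]
    diffc <- which(y != y[i])
    hits <- same[order(D[i, same], same)][seq_len(k)]
    misses <- diffc[order(D[i, diffc], diffc)][seq_len(k)]
    w <- w - colSums(abs(xs[hits, , drop = FALSE] -
                           matrix(xs[i, ], k, p, byrow = TRUE))) / (m_used * k) +
      colSums(abs(xs[misses, , drop = FALSE] -
                    matrix(xs[i, ], k, p, byrow = TRUE))) / (m_used * k)
  }
  names(w) <- colnames(x)
  structure(
    list(weights = w, ranking = order(-w, seq_len(p)), k = k,
         n_sampled = m_used, feature_names = colnames(x)),
    class = "relief_weights"
  )
}

#' @export
print.relief_weights <- function(x, ...) {
  cat("<relief_weights> ", length(x$weights), " features, k = ", x$k,
      ", m = ", x$n_sampled, "\n", sep = "")
  top <- head(x$ranking, 5L)
  cat("  top: ", paste0(x$feature_names[top], " (",
                        signif(x$weights[top], 3), ")", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.relief_weights <- function(x, ...) {
  tibble(
    feature = x$feature_names %||% as.character(seq_along(x$weights)),
    weight = unname(x$weights),
    rank = match(seq_along(x$weights), x$ranking)
  )
}

#' Top-ranked feature indices
#'
#' @param rw A [relieff_weights()] result.
#' @param d How many features (1..n_features).
#' @return Integer vector: the first `d` entries of the descending-weight
#'   ranking (ties by ascending feature index).
#' @export
top_features <- function(rw, d) {
  stopifnot(inherits(rw, "relief_weights"))
  p <- length(rw$weights)
  if (d < 1L || d > p) abort(paste0("d must be in 1..", p))
  rw$ranking[seq_len(d)]
}

# --- shared label / matrix coercion helpers -------------------------------

features_as_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
    return(x)
  }
  if (is.data.frame(x)) {
    fc <- setdiff(names(x), meta_cols())
    return(as.matrix(x[fc]))
  }
  abort("x must be a matrix or data frame")
}

as_binary_labels <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) abort("labels must be binary (0/1)")
  y
}
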