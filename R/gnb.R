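#' Fit a Gaussian naive Bayes classifier
#'
#' Models each class-conditional feature distribution as an independent
#' Gaussian: priors are empirical class frequencies, means and variances are
#' per-class per-feature sample moments with the population (n) denominator.
#' Variances are floored at `1e-9` times the largest overall feature variance
#' so constant-within-class features never produce a division error.
#'
#' @param x Numeric matrix or feature tibble (rows = instances).
#' @param y Binary labels (0/1); both classes must be present.
#' @param var_floor Optional explicit variance floor.
#' @return Object of class `gnb_model` with elements `classes`, `priors`,
#'   `means` and `variances` (class x feature matrices), `var_floor`.
#' @export
#' @examples
#' m <- gnb_fit(matrix(c(0, 2), ncol = 1), c(0, 1))
#' m$means
gnb_fit <- function(x, y, var_floor = NULL) {
  x <- features_as_matrix(x)
  y <- as_binary_labels(y)
  stopifnot(nrow(x) == length(y))
  classes <- sort(unique(y))
  if (length(classes) < 2L) abort("both classes must be present in the training data")
  p <- ncol(x)
  if (is.null(var_floor)) {
    overall <- apply(x, 2L, function(v) mean((v - mean(v))^2))
    var_floor <- 1e-9 * max(overall)
    if (var_floor <= 0) var_floor <- 1e-12
  }
  means <- vars <- matrix(0, nrow = 2L, ncol = p,
                          dimnames = list(c("0", "1"), colnames(x)))
  priors <- numeric(2L)
  for (ci in 1:2) {
    rows <- which(y == classes[ci])
    priors[ci] <- length(rows) / length(y)
    xc <- x[rows, , drop = FALSE]
    means[ci, ] <- colMeans(xc)
    vars[ci, ] <- pmax(colMeans(xc^2) - colMeans(xc)^2, var_floor)
  }
  structure(
    list(classes = classes, priors = priors, means = means, variances = vars,
         var_floor = var_floor, n = length(y)),
    class = "gnb_model"
  )
}

#' Predict with a Gaussian naive Bayes model
#'
#' Posteriors are computed in log space (`log prior + sum of log normal
#' densities`) and normalized per instance; the hard label is the posterior
#' argmax with ties resolved to class 0.
#'
#' @param object A [gnb_fit()] model.
#' @param newdata Matrix or feature tibble with the model's feature count.
#' @param type `"class"`, `"posterior"`, or `"both"` (default).
#' @param ... Unused.
#' @return For `"both"`, a tibble with `.pred_class`, `.pred_0`, `.pred_1`;
#'   otherwise the labels vector or posterior matrix.
#' @export
predict.gnb_model <- function(object, newdata, type = c("both", "class", "posterior"), ...) {
  type <- match.arg(type)
  x <- features_as_matrix(newdata)
  if (ncol(x) != ncol(object$means)) {
    abort(paste0("newdata has ", ncol(x), " features; model expects ",
                 ncol(object$means)))
  }
  if (any(!is.finite(x))) abort("non-finite values in newdata")
  ll <- matrix(0, nrow = nrow(x), ncol = 2L)
  for (ci in 1:2) {
    mu <- matrix(object$means[ci, ], nrow(x), ncol(x), byrow = TRUE)
    s2 <- matrix(object$variances[ci, ], nrow(x), ncol(x), byrow = TRUE)
    ll[, ci] <- log(object$priors[ci]) +
      rowSums(-0.5 * log(2 * pi * s2) - (x - mu)^2 / (2 * s2))
  }
  mx <- pmax(ll[, 1L], ll[, 2L])
  post <- exp(ll - mx)
  post <- post / rowSums(post)
  colnames(post) <- as.character(object$classes)
  # tie -> class 0 (strict inequality required to pick class 1)
  cls <- object$classes[ifelse(ll[, 2L] > ll[, 1L], 2L, 1L)]
  switch(type,
    class = cls,
    posterior = post,
    both = tibble(.pred_class = cls, .pred_0 = unname(post[, 1L]),
                  .pred_1 = unname(post[, 2L]))
  )
}

#' @export
print.gnb_model <- function(x, ...) {
  cat("<gnb_model> ", ncol(x$means), " features, priors ",
      paste(signif(x$priors, 3), collapse = "/"), ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.gnb_model <- function(x, ...) {
  p <- ncol(x$means)
  fn <- colnames(x$means) %||% paste0("f", seq_len(p))
  tibble(
    class = rep(x$classes, each = p),
    feature = rep(fn, 2L),
    mean = c(x$means[1L, ], x$means[2L, ]),
    variance = c(x$variances[1L, ], x$variances[2L, ])
  )
}

#' @export
glance.gnb_model <- function(x, ...) {
  tibble(n = x$n, n_features = ncol(x$means),
         prior_0 = x$priors[1L], prior_1 = x$priors[2L],
         var_floor = x$var_floor)
}
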