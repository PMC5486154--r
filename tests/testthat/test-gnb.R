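test_that("fit recovers empirical moments (n denominator) and priors", {
  m <- gnb_fit(matrix(c(0, 2), ncol = 1), c(0, 1))
  expect_equal(unname(m$means[, 1]), c(0, 2))
  expect_equal(m$priors, c(0.5, 0.5))

  # hand-computed moments on a 6-instance set
  x <- cbind(a = c(1, 2, 3, 10, 12, 14), b = c(0, 0, 1, 1, 1, 0))
  y <- c(0, 0, 0, 1, 1, 1)
  m2 <- gnb_fit(x, y)
  expect_equal(unname(m2$means["0", ]), c(2, 1 / 3))
  expect_equal(unname(m2$means["1", ]), c(12, 2 / 3))
  expect_equal(unname(m2$variances["0", "a"]), mean((c(1, 2, 3) - 2)^2))
  expect_equal(unname(m2$variances["1", "a"]), mean((c(10, 12, 14) - 12)^2))

  # constant-within-class feature takes the floor instead of dividing by zero
  x3 <- cbind(c(5, 5, 1, 2), c(0, 1, 0, 1))
  m3 <- gnb_fit(x3, c(0, 0, 1, 1))
  expect_equal(unname(m3$variances["0", 1]), m3$var_floor)
  expect_true(all(is.finite(predict(m3, x3, type = "posterior"))))

  expect_error(gnb_fit(matrix(rnorm(4), 2), c(0, 0)), "both classes")
})

test_that("posteriors are normalized, log-space stable, and tie to class 0", {
  # symmetric means, equal priors, x at the midpoint
  m <- gnb_fit(matrix(c(-1, -1, 1, 1), ncol = 1), c(0, 0, 1, 1))
  pr <- predict(m, matrix(0, 1, 1))
  expect_equal(pr$.pred_0, 0.5, tolerance = 1e-12)
  expect_equal(pr$.pred_class, 0)

  # x at a class mean of well-separated classes
  set.seed(2)
  x <- rbind(matrix(rnorm(30, 0), ncol = 3), matrix(rnorm(30, 8), ncol = 3))
  y <- rep(0:1, each = 10)
  mm <- gnb_fit(x, y)
  expect_equal(predict(mm, matrix(mm$means["0", ], 1), type = "class"), 0)

  # posteriors sum to one and match the density-product oracle
  xt <- matrix(rnorm(15), 5, 3)
  post <- predict(mm, xt, type = "posterior")
  expect_equal(rowSums(post), rep(1, 5), tolerance = 1e-12)
  for (i in 1:5) {
    expect_equal(unname(post[i, ]), unname(gnb_posterior_oracle(mm, xt[i, ])),
                 tolerance = 1e-12)
  }

  expect_error(predict(mm, matrix(c(1, Inf, 0), 1)), "non-finite")
  expect_error(predict(mm, matrix(0, 1, 2)), "expects")
})

test_that("hard labels agree with an independent naive Bayes on separable data", {
  set.seed(4)
  x <- rbind(matrix(rnorm(120, 0), ncol = 4), matrix(rnorm(120, 3), ncol = 4))
  colnames(x) <- paste0("f", 1:4)
  y <- rep(0:1, each = 30)
  ours <- predict(gnb_fit(x, y), x, type = "class")
  ref <- e1071::naiveBayes(x, factor(y))
  theirs <- as.integer(as.character(predict(ref, x)))
  expect_gte(mean(ours == theirs), 0.97)
})

test_that("decision boundary approaches the class-mean midpoint as n grows", {
  set.seed(5)
  boundary <- function(n) {
    x <- matrix(c(rnorm(n, -1), rnorm(n, 1)), ncol = 1)
    m <- gnb_fit(x, rep(0:1, each = n))
    grid <- matrix(seq(-1, 1, by = 0.001), ncol = 1)
    cls <- predict(m, grid, type = "class")
    grid[which(cls == 1)[1]]
  }
  expect_lt(abs(boundary(4000)), 0.08)
})

test_that("tidy and glance expose the fitted parameters", {
  m <- gnb_fit(cbind(a = rnorm(6), b = rnorm(6)), rep(0:1, 3))
  td <- tidy(m)
  expect_equal(nrow(td), 4L)
  expect_named(td, c("class", "feature", "mean", "variance"))
  g <- glance(m)
  expect_equal(g$n, 6L)
  expect_equal(g$prior_0 + g$prior_1, 1)
})
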