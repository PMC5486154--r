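fake_weights <- function(w) {
  structure(list(weights = w, ranking = order(-w, seq_along(w)), k = 1,
                 n_sampled = length(w),
                 feature_names = paste0("f", seq_along(w))),
            class = "relief_weights")
}

test_that("identical and negated weight spaces bracket the correlation range", {
  set.seed(21)
  w <- fake_weights(rnorm(60))
  prof <- similarity_profile(w, list(same = w,
                                     neg = fake_weights(-w$weights),
                                     other = fake_weights(rnorm(60))))
  expect_equal(prof$r[prof$ss_id == "same"], 1)
  expect_equal(prof$r[prof$ss_id == "neg"], -1)
  expect_equal(select_sources(prof, 1, "similar"), "same")
  expect_equal(select_sources(prof, 1, "dissimilar"), "neg")
})

test_that("correlations match the covariance/sigma oracle to 1e-12", {
  set.seed(22)
  w <- fake_weights(rnorm(60))
  ss <- list(a = fake_weights(rnorm(60)), b = fake_weights(rnorm(60)),
             c = fake_weights(rnorm(60)))
  prof <- similarity_profile(w, ss)
  for (id in names(ss)) {
    expect_equal(prof$r[prof$ss_id == id],
                 pearson_oracle(w$weights, ss[[id]]$weights),
                 tolerance = 1e-12)
  }
})

test_that("r is invariant under positive affine rescaling of a weight vector", {
  set.seed(23)
  w <- fake_weights(rnorm(30))
  v <- rnorm(30)
  prof1 <- similarity_profile(w, list(s = fake_weights(v)))
  prof2 <- similarity_profile(w, list(s = fake_weights(3.2 * v + 0.7)))
  expect_equal(prof1$r, prof2$r, tolerance = 1e-12)
})

test_that("zero-variance weight vectors are flagged with r = 0", {
  w <- fake_weights(rnorm(10))
  prof <- similarity_profile(w, list(flat = fake_weights(rep(0.3, 10))))
  expect_true(prof$degenerate)
  expect_equal(prof$r, 0)
})

test_that("similar and dissimilar selection agree when O = n; ties by id", {
  set.seed(24)
  w <- fake_weights(rnorm(20))
  ss <- lapply(1:5, function(i) fake_weights(rnorm(20)))
  names(ss) <- sprintf("S%02d", 5:1)
  prof <- similarity_profile(w, ss)
  expect_setequal(select_sources(prof, 5, "similar"),
                  select_sources(prof, 5, "dissimilar"))
  expect_error(select_sources(prof, 6, "similar"), "must be in")
  expect_error(select_sources(prof, 0, "similar"), "must be in")

  tied <- prof
  tied$r <- rep(0.5, 5)
  expect_equal(select_sources(tied, 2, "similar"), c("S01", "S02"))
})

test_that("dissimilarity is the population sd of absolute correlations", {
  w <- fake_weights(rnorm(10))
  prof <- similarity_profile(w, list(a = fake_weights(rnorm(10)),
                                     b = fake_weights(rnorm(10)),
                                     c = fake_weights(rnorm(10))))
  expect_equal(ts_ss_dissimilarity(prof, prof$ss_id),
               pop_sd_oracle(abs(prof$r)), tolerance = 1e-12)

  equal_prof <- prof
  equal_prof$r <- c(0.3, -0.3, 0.3)
  expect_equal(ts_ss_dissimilarity(equal_prof, prof$ss_id), 0)
  two <- prof
  two$r <- c(0.2, -0.4, 0.9)
  expect_equal(ts_ss_dissimilarity(two, c("a", "b")), 0.1)
  expect_error(ts_ss_dissimilarity(prof, "a"), "at least 2")
})

test_that("a spearman profile ranks by weight order, not magnitude", {
  w <- fake_weights(c(1, 2, 3, 4))
  monotone <- fake_weights(c(10, 20, 40, 80))
  prof <- similarity_profile(w, list(s = monotone), method = "spearman")
  expect_equal(prof$r, 1)
})
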