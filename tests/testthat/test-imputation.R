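test_that("default_metric_params uses twice the population variance and a = 1", {
  m <- cbind(c(0, 2, NA), c(1, 5, 3))
  p <- default_metric_params(m)
  expect_equal(p$scales[1], 2)       # observed {0, 2}: pop variance 1
  expect_equal(p$penalty, 1)
  expect_error(default_metric_params(cbind(c(0, 1), c(3, 3))), "zero variance")
  expect_error(default_metric_params(cbind(c(0, 1), c(3, NA))), "fewer than 2")
  # sample-variance convention available
  expect_equal(default_metric_params(cbind(c(0, 2), c(0, 4)),
                                     var_type = "sample")$scales[1], 4)
})

test_that("pair_dissimilarity follows the coordinate rule", {
  p1 <- list(scales = 2, penalty = 1)
  expect_equal(pair_dissimilarity(c(0), c(0), p1), 0)
  expect_equal(pair_dissimilarity(c(NA), c(5), p1), 1)
  expect_equal(pair_dissimilarity(c(0), c(1), p1), 1 / 3)
  p2 <- list(scales = c(2, 1), penalty = 1)
  expect_equal(pair_dissimilarity(c(0, NA), c(1, 0), p2), 1 / 3 + 1)
  expect_error(pair_dissimilarity(c(0, 1), c(1), p2), "same features")
  # bounded by n, observed coordinates strictly below 1
  set.seed(1)
  for (i in 1:50) {
    x <- stats::rnorm(4, sd = 100); y <- stats::rnorm(4, sd = 100)
    d <- pair_dissimilarity(x, y, list(scales = rep(1, 4), penalty = 1))
    expect_lt(d, 4)
  }
})

test_that("tree_metric is the root of D and symmetric", {
  p <- list(scales = 1, penalty = 0.25)
  expect_equal(tree_metric(c(1), c(1), p), 0)
  expect_equal(tree_metric(c(NA), c(1), p), 0.5)  # sqrt(1/4)
  p2 <- list(scales = c(2, 1), penalty = 1)
  expect_equal(tree_metric(c(0, NA), c(1, 3), p2), sqrt(4 / 3))
  expect_equal(tree_metric(c(0, NA), c(1, 3), p2),
               tree_metric(c(1, 3), c(0, NA), p2))
})

test_that("compiled pairwise dissimilarity agrees with the scalar rule", {
  set.seed(11)
  m <- matrix(stats::rnorm(60), 10, 6)
  m[stats::runif(60) < 0.3] <- NA
  params <- list(scales = stats::runif(6, 0.5, 3), penalty = 0.6)
  d <- dissimilarity_matrix(m, params, squared = TRUE)
  for (i in 1:9) for (j in (i + 1):10)
    expect_equal(d[i, j], pair_dissimilarity(m[i, ], m[j, ], params),
                 tolerance = 1e-12)
  expect_equal(d, t(d))
})

test_that("tree_metric satisfies the triangle inequality for a >= 1/4", {
  set.seed(5)
  for (a in c(0.25, 0.5, 1)) {
    params <- list(scales = rep(1, 3), penalty = a)
    for (i in 1:400) {
      v <- matrix(stats::rcauchy(9), 3, 3)
      v[matrix(stats::runif(9) < 0.3, 3, 3)] <- NA
      d12 <- tree_metric(v[1, ], v[2, ], params)
      d23 <- tree_metric(v[2, ], v[3, ], params)
      d13 <- tree_metric(v[1, ], v[3, ], params)
      expect_lte(d13, d12 + d23 + 1e-12)
    }
  }
})

test_that("triangle_threshold_search finds the 1/4 boundary", {
  res <- triangle_threshold_search(c(0.1, 0.2, 0.25, 0.5, 1),
                                   n_random = 2000, seed = 3)
  expect_equal(res$threshold, 0.25)
  expect_true(all(res$violations[res$a_grid < 0.25]))
  expect_false(any(res$violations[res$a_grid >= 0.25]))
  expect_error(triangle_threshold_search(numeric(0)), "non-empty")
})

test_that("knn_impute fills every hole and never touches observed entries", {
  # hand-traced 1-NN: row 3 is closest to row 1 on the observed feature
  m <- rbind(c(0, 10), c(5, 50), c(0.1, NA))
  filled <- knn_impute(m, k = 1, params = list(scales = c(1, 1), penalty = 1))
  expect_equal(filled[3, 2], 10)
  expect_equal(filled[-3, ], m[-3, ])
  # identical rows share their value
  m2 <- rbind(c(1, 2), c(1, 2), c(1, NA))
  filled2 <- knn_impute(m2, k = 2, params = list(scales = c(1, 1), penalty = 1))
  expect_equal(filled2[3, 2], 2)
  # no missing -> unchanged
  m3 <- matrix(stats::rnorm(20), 5, 4)
  expect_identical(knn_impute(m3, k = 2,
                              params = list(scales = rep(1, 4), penalty = 1)),
                   m3)
  expect_error(knn_impute(m, k = 3), "k must satisfy")
  # larger random case: completion total, observed untouched
  set.seed(9)
  m4 <- matrix(stats::rnorm(200), 40, 5)
  holes <- matrix(stats::runif(200) < 0.3, 40, 5)
  m4na <- m4; m4na[holes] <- NA
  out <- knn_impute(m4na, k = 5)
  expect_false(anyNA(out))
  expect_equal(out[!holes], m4[!holes])
})

test_that("mean_impute and rsse behave as documented", {
  m <- rbind(c(1, NA), c(3, 4), c(NA, 6))
  f <- mean_impute(m)
  expect_equal(f[1, 2], 5)
  expect_equal(f[3, 1], 2)
  expect_identical(mean_impute(matrix(1:4, 2)), matrix(1:4, 2))
  truth <- rbind(c(1, 2), c(3, 4), c(5, 6))
  mask <- is.na(m)
  expect_equal(rsse(truth, truth, mask), 0)
  comp <- truth; comp[1, 2] <- 5; comp[3, 1] <- 1
  expect_equal(rsse(comp, truth, mask), 5)  # errors 3 and 4
  expect_error(rsse(truth, truth[1:2, ], mask), "shapes")
})

test_that("drop_high_missing applies the 90% rule", {
  m <- cbind(a = c(1, NA, NA, NA, NA, NA, NA, NA, NA, NA), b = 1:10)
  kept <- drop_high_missing(m, threshold = 0.8)
  expect_equal(colnames(kept), "b")
  expect_equal(attr(kept, "dropped"), c(a = 1L))
  expect_equal(ncol(drop_high_missing(m, threshold = 0.9)), 2)
})

test_that("swiss-roll embedding is orthonormal and masking hits its rate", {
  set.seed(2)
  q <- random_orthonormal_map(3, 25)
  expect_equal(crossprod(q), diag(3), tolerance = 1e-10)
  res <- swiss_roll_benchmark(n_points = 600, dims = c(6, 10),
                              missing_frac = 0.7, seed = 4)
  expect_true(all(abs(res$masked_frac - 0.7) < 0.02))
  expect_true(all(res$rsse_knn < res$rsse_mean))
})
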