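test_that("dissimilarity ratio is the ratio of mean norms", {
  A <- matrix(rnorm(20), ncol = 2)
  expect_equal(dissimilarity_ratio(A, A), 1)
  expect_equal(dissimilarity_ratio(matrix(0, 3, 2), A), 0)
  T1 <- matrix(c(3, 4), nrow = 1)
  T2 <- rbind(c(6, 8), c(0, 2))
  expect_equal(dissimilarity_ratio(T1, T2), 5 / 6)
  expect_error(dissimilarity_ratio(A, matrix(0, 2, 2)), "mean norm of T2")
  expect_error(dissimilarity_ratio(A[0, , drop = FALSE], A), "non-empty")
})

test_that("class scaling applies (r, max(tau, 1 - r)) and preserves shape", {
  res <- scale_task_spaces(matrix(c(0.8, 0), 1), matrix(c(1, 0), 1))
  expect_equal(res$scaling$factor_T1, 0.8)
  expect_equal(res$scaling$factor_T2, 0.5)

  res2 <- scale_task_spaces(matrix(c(0.3, 0), 1), matrix(c(1, 0), 1))
  expect_equal(res2$scaling$factor_T2, 0.7)

  A <- matrix(rnorm(12), ncol = 3)
  res3 <- scale_task_spaces(A, A)
  expect_equal(res3$scaling$r, 1)
  expect_equal(res3$T1, A)          # factor r = 1
  expect_equal(res3$T2, A * 0.5)    # max(0.5, 0)

  # within-class pairwise distance ratios preserved exactly
  set.seed(7)
  T1 <- matrix(rnorm(15), ncol = 3)
  T2 <- matrix(rnorm(15, 2), ncol = 3)
  sc <- scale_task_spaces(T1, T2)
  d_before <- as.numeric(dist(T1))
  d_after <- as.numeric(dist(sc$T1))
  expect_equal(d_after / d_before, rep(sc$scaling$factor_T1, length(d_before)),
               tolerance = 1e-12)
  expect_error(scale_task_spaces(T1, T2, tau = 1.5), "tau")
})

test_that("scaling broadens the cross-class norm ratio when r < 0.5", {
  set.seed(8)
  for (i in 1:20) {
    T1 <- matrix(rnorm(9, sd = 0.3), ncol = 3)
    T2 <- matrix(rnorm(9, mean = 3), ncol = 3)
    r <- dissimilarity_ratio(T1, T2)
    if (r >= 0.5) next
    sc <- scale_task_spaces(T1, T2)
    r_after <- dissimilarity_ratio(sc$T1, sc$T2)
    expect_lte(r_after, r)  # T1/T2 norm ratio shrinks: classes pushed apart
  }
})

test_that("geometric median handles canonical configurations", {
  expect_equal(geometric_median(c(2, 3)), c(2, 3))
  expect_equal(geometric_median(matrix(c(0, 1, 10), ncol = 1)), 1,
               tolerance = 1e-6)
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_equal(geometric_median(tri), colMeans(tri), tolerance = 1e-6)

  X <- rbind(c(0, 0), c(4, 0), c(0, 4), c(10, 10))
  oracle <- gm_grid_oracle(X)
  got <- geometric_median(X)
  expect_lt(abs(sum_dist(got, X) - oracle$objective), 1e-3)
})

test_that("Weiszfeld objective decreases monotonically", {
  set.seed(9)
  for (i in 1:10) {
    X <- matrix(rnorm(3 * sample(3:6, 1)), ncol = 3)
    y <- geometric_median(X, trace = TRUE)
    tr <- attr(y, "objective_trace")
    expect_true(all(diff(tr) <= 1e-10))
  }
})

test_that("the median sides with the cluster, not the outliers", {
  # cluster-vs-outlier contract, and the cumulative-distance optimality of
  # the returned point over all input points and the centroid
  set.seed(10)
  for (i in 1:10) {
    cluster <- matrix(rnorm(2 * 12, sd = 0.5), ncol = 2)
    outliers <- rbind(c(20, 20), c(-25, 15))[seq_len(sample(1:2, 1)), ,
                                             drop = FALSE]
    X <- rbind(cluster, outliers)
    gm <- geometric_median(X)
    d_centroid <- sqrt(sum((gm - colMeans(cluster))^2))
    d_out <- sqrt(rowSums((outliers - rep(gm, each = nrow(outliers)))^2))
    expect_true(all(d_centroid < d_out))
    obj <- sum_dist(gm, X)
    expect_lte(obj, min(apply(X, 1, sum_dist, pts = X)) + 1e-6)
    expect_lte(obj, sum_dist(colMeans(X), X) + 1e-6)
  }
})

test_that("normal-equation weights solve least squares, min-norm when singular", {
  expect_equal(fit_weights(diag(2), c(0, 1)), c(0, 1))
  expect_equal(fit_weights(matrix(c(1, 2), ncol = 1), c(0, 1)), 0.4)

  set.seed(11)
  X <- matrix(rnorm(30), ncol = 3)
  X <- cbind(X, X[, 1])  # duplicated column -> singular normal matrix
  y <- rnorm(10)
  W <- fit_weights(X, y)
  fitted_oracle <- stats::lm.fit(X, y)$fitted.values
  expect_equal(as.numeric(X %*% W), as.numeric(fitted_oracle),
               tolerance = 1e-9)
})

test_that("midpoint and sigmoid boundary follow their closed forms", {
  expect_equal(snc_midpoint(c(0, 0), c(2, 4)), c(1, 2))
  m <- c(0.3, -1)
  expect_equal(snc_midpoint(m, m), m)
  expect_error(snc_midpoint(c(1, 2), c(1, 2, 3)), "mismatch")

  expect_equal(snc_boundary(c(0, 0), c(5, 5)), 0.5)
  expect_equal(snc_boundary(c(log(3)), c(1)), 0.75)
  vals <- vapply(c(1, 2, 5, 20), function(k) snc_boundary(k, 1), numeric(1))
  expect_true(all(diff(vals) > 0) && all(vals < 1))
})

test_that("polynomial expansion appends element-wise powers only", {
  X <- matrix(rnorm(20), ncol = 4)
  expect_identical(polynomial_expand(X, 0), X)
  expect_identical(polynomial_expand(X, 1), X)
  X2 <- polynomial_expand(X, 2)
  expect_identical(ncol(X2), 8L)
  expect_equal(X2[, 5:8], X^2)
  expect_identical(ncol(polynomial_expand(X, 5)), 20L)
})

test_that("fitting rejects degenerate task spaces and is deterministic", {
  expect_error(snc_fit(rbind(c(0, 0), c(2, 2)), c(0, 0)), "single-class")
  expect_error(snc_fit(rbind(c(0, 0), c(2, 2)), c(0, 1)), "r = 0")

  cl <- separated_clusters(seed = 12)
  m1 <- snc_fit(cl$X, cl$y)
  m2 <- snc_fit(cl$X, cl$y)
  expect_identical(m1, m2)
  expect_gt(m1$beta, 0); expect_lt(m1$beta, 1)
  expect_equal(m1$midpoint, (m1$median_T1 + m1$median_T2) / 2)
})

test_that("well-separated clusters are classified perfectly in training", {
  cl <- separated_clusters(gap = 6, sd = 1, seed = 13)
  model <- snc_fit(cl$X, cl$y)
  expect_equal(mean(predict(model, cl$X) == cl$y), 1)

  # the raw pre-image of the midpoint scores exactly beta -> ties fire 1
  expect_identical(predict(model, model$midpoint), 1L)
  # extreme points follow the sigmoid limits
  big <- sign(model$W)
  expect_identical(predict(model, matrix(big * 1e6, nrow = 1)), 1L)
  expect_identical(predict(model, matrix(-big * 1e6, nrow = 1)), 0L)
  expect_error(predict(model, matrix(1, 1, 7)), "expected 3 raw features")
})

test_that("degree selection prefers the smallest degree among ties", {
  cl <- separated_clusters(seed = 14)
  expect_identical(select_degree(cl$X, cl$y, degrees = 4L), 4L)
  expect_identical(select_degree(cl$X, cl$y), 0L)  # separable at degree 0

  calls <- 0L
  counting <- function(d) { calls <<- calls + 1L; 0.5 }
  select_degree(cl$X, cl$y, degrees = c(0L, 2:12), eval_fn = counting)
  expect_identical(calls, 12L)
})

test_that("models serialize to JSON and back without behavioral change", {
  cl <- separated_clusters(seed = 15)
  model <- snc_fit(cl$X, cl$y, degree = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_snc_model(model, path, feature_family = "DE", channel = "Left1")
  back <- read_snc_model(path)
  expect_equal(back$W, model$W, tolerance = 1e-12)
  expect_equal(back$beta, model$beta, tolerance = 1e-12)
  expect_identical(back$degree, model$degree)
  expect_identical(predict(back, cl$X), predict(model, cl$X))
  expect_identical(back$feature_family, "DE")
})
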