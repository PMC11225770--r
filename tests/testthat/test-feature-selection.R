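# PCA / LDA / RFE reducers and the lion wrapper selector.

# brute-force population covariance: the double loop the fast path must match
cov_bruteforce <- function(X) {
  n <- nrow(X); d <- ncol(X)
  mu <- colMeans(X)
  S <- matrix(0, d, d)
  for (j in seq_len(d)) {
    for (k in seq_len(d)) {
      S[j, k] <- sum((X[, j] - mu[j]) * (X[, k] - mu[k])) / n
    }
  }
  S
}

test_that("PCA covariance uses the 1/n normalization", {
  # 1-D: values 1,2,3 have mean 2 and population variance 2/3
  m <- pca_reduce(matrix(c(1, 2, 3), 3, 1), 1)
  expect_equal(m$covariance[1, 1], 2 / 3)

  set.seed(21)
  for (dims in list(c(5, 4), c(20, 8))) {
    X <- matrix(rnorm(dims[1] * dims[2]), dims[1], dims[2])
    m <- pca_reduce(X, dims[2])
    expect_lt(max(abs(m$covariance - cov_bruteforce(X))), 1e-10)
  }
})

test_that("PCA components are orthonormal and preserve total variance at k=d", {
  set.seed(22)
  X <- matrix(rnorm(40 * 6), 40, 6)
  m <- pca_reduce(X, 6)
  expect_lt(max(abs(crossprod(m$components) - diag(6))), 1e-8)
  expect_true(all(diff(m$explained_variance) <= 1e-12))
  total_var <- sum(apply(m$reduced, 2, function(v) mean((v - mean(v))^2)))
  expect_equal(total_var, sum(diag(m$covariance)), tolerance = 1e-8)
  expect_error(pca_reduce(X, 7), "between 1 and")
})

test_that("LDA finds the Fisher direction for two separated Gaussians", {
  set.seed(23)
  n <- 150
  X <- rbind(cbind(rnorm(n, 0), rnorm(n, 0)), cbind(rnorm(n, 5), rnorm(n, 0)))
  y <- rep(0:1, each = n)
  m <- lda_reduce(X, y, 1)
  w <- m$projection[, 1]
  angle <- acos(abs(w[1]) / sqrt(sum(w^2))) * 180 / pi
  expect_lt(angle, 5)  # within 5 degrees of the x axis

  # independent oracle: the top direction's Fisher ratio beats 100 random ones
  fisher_ratio <- function(v, X, y) {
    p <- drop(X %*% v)
    m0 <- mean(p[y == 0]); m1 <- mean(p[y == 1])
    (m1 - m0)^2 / (stats::var(p[y == 0]) + stats::var(p[y == 1]))
  }
  fw <- fisher_ratio(w, X, y)
  set.seed(24)
  for (r in 1:100) {
    v <- rnorm(2); v <- v / sqrt(sum(v^2))
    expect_gte(fw, fisher_ratio(v, X, y) - 1e-9)
  }
})

test_that("LDA on identical classes and rank limits behaves as degenerate", {
  set.seed(25)
  X <- matrix(rnorm(60 * 4), 60, 4)
  y <- rep(0:1, 30)
  X2 <- X; X2[y == 1, ] <- X[y == 0, ]  # classes share every sample value
  m <- lda_reduce(X2, y, 4)
  expect_lt(max(abs(m$eigenvalues)), 1e-8)
  # two classes carry at most one informative direction
  m2 <- lda_reduce(rbind(X, X + 3), rep(0:1, each = 60), 4)
  expect_lt(m2$eigenvalues[2] / m2$eigenvalues[1], 1e-6)
})

test_that("RFE keeps the planted predictive feature and nests across n_keep", {
  set.seed(26)
  n <- 80
  y <- rep(0:1, n / 2)
  X <- cbind(y + rnorm(n, 0, 0.05), matrix(rnorm(n * 7), n, 7))
  colnames(X) <- paste0("f", 1:8)
  clf <- classifier_spec("logistic_regression", seed = 5)
  m1 <- rfe_select(X, y, clf, n_keep = 1)
  expect_identical(which(m1$mask == 1L), 1L)
  expect_equal(m1$selected_count, 1L)

  m4 <- rfe_select(X, y, clf, n_keep = 4)
  m2 <- rfe_select(X, y, clf, n_keep = 2)
  expect_equal(sum(m4$mask), 4L)
  expect_true(all(which(m2$mask == 1L) %in% which(m4$mask == 1L)))
  expect_true(all(which(m1$mask == 1L) %in% which(m2$mask == 1L)))
  expect_identical(rfe_select(X, y, clf, 4)$mask, m4$mask)  # deterministic

  expect_identical(rfe_select(X, y, clf, 8)$mask, rep(1L, 8))
  expect_error(rfe_select(X, y, classifier_spec("naive_bayes"), 2),
               "no per-feature importance")
})

test_that("mask decoding thresholds at 0.5 with an argmax fallback", {
  expect_identical(decode_mask(c(0.7, 0.2, 0.9)), c(1L, 0L, 1L))
  expect_identical(decode_mask(c(0.1, 0.4, 0.3)), c(0L, 1L, 0L))
  expect_identical(decode_mask(c(0.5, 0.5)), c(1L, 0L))  # strict threshold
})

test_that("loa_select is reproducible and reports a re-evaluable fitness", {
  tab <- small_table()
  cfg <- loa_config(nvar = ncol(tab$X), population_size = 16L, num_prides = 2L,
                    max_iterations = 10L, patience = 5L,
                    lower_bounds = 0, upper_bounds = 1, seed = 5)
  s1 <- loa_select(tab$X, tab$y, config = cfg)
  s2 <- loa_select(tab$X, tab$y, config = cfg)
  expect_identical(s1$mask$mask, s2$mask$mask)
  expect_identical(s1$result$trace, s2$result$trace)
  # reported fitness is exactly the wrapper CV error of the returned mask
  f <- wrapper_cv_error(tab$X, tab$y, s1$mask$mask, classifier_spec("knn"),
                        seed = cfg$seed + 1L)
  expect_equal(s1$best_fitness, f)
  expect_gte(s1$mask$selected_count, 1L)
})

test_that("the selected mask beats random masks of the same size", {
  tab <- small_table()
  cfg <- loa_config(nvar = ncol(tab$X), population_size = 16L, num_prides = 2L,
                    max_iterations = 12L, patience = 6L,
                    lower_bounds = 0, upper_bounds = 1, seed = 5)
  sel <- loa_select(tab$X, tab$y, config = cfg)
  sel_err <- sel$best_fitness
  set.seed(31)
  rand_err <- replicate(5, {
    mask <- integer(ncol(tab$X))
    mask[sample(ncol(tab$X), sel$mask$selected_count)] <- 1L
    wrapper_cv_error(tab$X, tab$y, mask, classifier_spec("knn"), seed = 6)
  })
  expect_lte(sel_err, stats::median(rand_err))
})

test_that("selection masks round-trip through delimited text", {
  tab <- small_table()
  m <- rfe_select(tab$X, tab$y, classifier_spec("logistic_regression"), 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_selection_mask(m, path)
  back <- utils::read.delim(path)
  expect_equal(back$selected, m$mask)
  expect_equal(back$feature_name, m$feature_names)
})
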