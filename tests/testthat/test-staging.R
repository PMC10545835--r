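test_that("pca matches a brute-force covariance eigendecomposition", {
  set.seed(21)
  x <- matrix(rnorm(60), 10, 6)
  pca <- fit_pca(x)
  ev <- eigen(stats::cov(x))
  for (j in seq_len(5)) {
    v <- ev$vectors[, j]
    expect_equal(abs(sum(pca$loadings[j, ] * v)), 1, tolerance = 1e-8)
  }
  # orthonormal loadings, centered scores, full reconstruction
  expect_equal(pca$loadings %*% t(pca$loadings), diag(nrow(pca$loadings)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_lt(max(abs(colMeans(pca$scores))), 1e-10)
  centered <- sweep(x, 2, pca$mean_vector)
  expect_equal(pca$scores %*% pca$loadings, centered, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pca$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(pca$explained_variance_ratio), 1 + 1e-12)
})

test_that("rank-one data loads entirely on the first component", {
  v <- sin(seq_len(20))
  x <- outer(c(1, 3, -2, 5), v)
  pca <- fit_pca(x)
  expect_equal(pca$explained_variance_ratio[1], 1, tolerance = 1e-12)
  expect_error(fit_pca(x[1, , drop = FALSE]), "at least 2")
})

test_that("pca_transform reproduces training scores", {
  set.seed(5)
  x <- matrix(rnorm(80), 8, 10)
  pca <- fit_pca(x)
  expect_equal(pca_transform(pca, x), pca$scores, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("softening classes are firmness tertiles, firmest first", {
  expect_identical(assign_softening_classes(c(30, 20, 10)), c(1L, 2L, 3L))
  expect_identical(assign_softening_classes(9:1), rep(1:3, each = 3))
  expect_warning(lab <- assign_softening_classes(rep(5, 6)), "equal")
  expect_identical(lab, rep(1:3, each = 2))   # stable input order on ties
  expect_error(assign_softening_classes(c(1, 2), 3), "more classes")
})

test_that("component selection finds the discriminative axis", {
  set.seed(8)
  n <- 30
  labels <- rep(1:3, each = 10)
  scores <- matrix(rnorm(n * 8, sd = 3), n, 8)
  scores[, 7] <- labels * 10 + rnorm(n, sd = 0.1)   # only axis 7 separates
  fake_pca <- structure(list(scores = scores), class = "pca_model")
  sel <- select_components(fake_pca, scores, labels, k = 3)
  expect_identical(sel[1], 7L)
  expect_identical(select_components(fake_pca, scores, labels,
                                     override = c(1, 2, 7)), c(1L, 2L, 7L))
})

test_that("svm staging separates blobs, is seeded, and nulls out on shuffles", {
  set.seed(13)
  n_per <- 20
  centers <- matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE)
  x <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(n_per * 2, sd = 1), n_per, 2), 2, centers[k, ], "+")))
  labels <- rep(1:3, each = n_per)
  rep1 <- train_classify_svm(x, labels, folds = 5, seed = 2)
  expect_equal(rep1$overall_accuracy, 1.0)
  expect_identical(rep1$confusion_matrix,
                   train_classify_svm(x, labels, folds = 5, seed = 2)$confusion_matrix)

  # margins conserve class counts
  expect_equal(unname(colSums(rep1$confusion_matrix)), rep(n_per, 3))
  expect_equal(sum(rep1$confusion_matrix), 3 * n_per)
  expect_equal(rep1$overall_accuracy,
               sum(diag(rep1$confusion_matrix)) / (3 * n_per))

  # permuted labels: accuracy within binomial 99% bounds around 1/3
  perm <- sample(labels)
  rep0 <- train_classify_svm(x, perm, folds = 5, seed = 3)
  p0 <- 1 / 3; n <- 3 * n_per
  expect_lt(abs(rep0$overall_accuracy - p0), 2.58 * sqrt(p0 * (1 - p0) / n) + 1e-9)
})

test_that("a class missing from training folds is named in the error", {
  x <- matrix(rnorm(12), 6, 2)
  labels <- c(1, 1, 1, 2, 2, 3)   # class 3 has one sample: absent from its fold
  expect_error(train_classify_svm(x, labels, folds = 5, seed = 1), "3")
})
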