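test_that("normalization is fitted on training data only", {
  set.seed(51)
  X <- matrix(rnorm(200, mean = 5, sd = 3), 20, 10)
  X[, 4] <- 2  # constant feature
  norm <- fit_normalization(X)
  Z <- apply_normalization(norm, X)
  expect_equal(unname(colMeans(Z)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(Z[, -4], 2, sd)), rep(1, 9), tolerance = 1e-12)
  expect_equal(Z[, 4], rep(0, 20))  # scale-1 guard maps constants to 0
  # a validation vector equal to the training mean maps to all zeros
  expect_equal(as.vector(apply_normalization(norm, norm$center)), rep(0, 10))
  # validation uses training statistics, not its own
  V <- matrix(rnorm(50, mean = 100), 5, 10)
  expect_equal(apply_normalization(norm, V),
               sweep(sweep(V, 2, norm$center), 2, norm$scale, "/"))
})

test_that("PCA components are orthonormal with ordered variances", {
  set.seed(52)
  X <- matrix(rnorm(600), 30, 20)
  pca <- fit_pca(X, q = 10)
  expect_equal(t(pca$components) %*% pca$components, diag(10), tolerance = 1e-9)
  expect_true(all(diff(pca$explained_variance) <= 1e-9))
  # sign convention: largest-magnitude loading positive
  for (j in 1:10)
    expect_gte(pca$components[which.max(abs(pca$components[, j])), j], 0)
  expect_error(fit_pca(X, q = 30), "q must satisfy")
})

test_that("PCA reconstructs data lying in a low-dimensional plane", {
  set.seed(53)
  basis <- qr.Q(qr(matrix(rnorm(20 * 2), 20, 2)))
  scores <- matrix(rnorm(50 * 2, sd = 4), 50, 2)
  X <- scores %*% t(basis) + matrix(rnorm(20), 50, 20, byrow = TRUE)
  pca <- fit_pca(X, q = 2)
  Z <- project_pca(pca, X)
  recon <- sweep(Z %*% t(pca$components), 2, pca$center, "+")
  expect_equal(recon, X, tolerance = 1e-9)
})

test_that("discriminant classifiers obey closed-form geometry", {
  # two 1-D classes N(-5,1), N(+5,1), equal priors: boundary at 0
  set.seed(54)
  X <- matrix(c(rnorm(200, -5), rnorm(200, 5)), ncol = 1)
  y <- rep(1:2, each = 200)
  for (kind in c("lda_full", "lda_diag", "qda_full", "qda_diag",
                 "mahalanobis", "naive_bayes")) {
    clf <- fit_classifier(kind, X, y)
    pred <- predict(clf, matrix(c(-0.5, 0.5, -6, 6), ncol = 1))
    expect_equal(as.integer(pred), c(1L, 2L, 1L, 2L), info = kind)
  }

  # analytic two-Gaussian posterior on a hand-built 1-D problem
  clf <- fit_classifier("lda_full", X, y)
  x0 <- 1.3
  post <- classifier_posterior(clf, x0)
  s2 <- clf$covs$pooled[1, 1]
  m <- clf$means[, 1]; pr <- clf$priors
  lik <- pr * dnorm(x0, m, sqrt(s2))
  expect_equal(as.vector(post), lik / sum(lik), tolerance = 1e-9)

  expect_error(fit_classifier("lda_full", X, rep(1, 400)), "2 classes")
  expect_error(fit_classifier("linear_svm", X, y), "not bundled")
})

test_that("well-separated clouds are classified perfectly", {
  set.seed(55)
  d <- 10; n <- 100
  mu <- rbind(rep(0, d), c(10, rep(0, d - 1)))
  X <- rbind(matrix(rnorm(n * d), n, d) + matrix(mu[1, ], n, d, byrow = TRUE),
             matrix(rnorm(n * d), n, d) + matrix(mu[2, ], n, d, byrow = TRUE))
  y <- rep(1:2, each = n)
  clf <- fit_classifier("lda_full", X, y)
  expect_equal(mean(as.integer(predict(clf, X)) == y), 1)
})

test_that("lda_full equals lda_diag when the pooled covariance is diagonal", {
  # features generated independently => construct exactly diagonal pooled
  # covariance by symmetrizing: use data whose sample covariance is diagonal
  set.seed(56)
  base <- matrix(rnorm(100 * 2), 100, 2)
  base <- sweep(base, 2, colMeans(base))
  base <- base %*% solve(chol(cov(base)))  # whitened: cov = I exactly
  X <- rbind(base, sweep(base, 2, c(3, 4), "+"))
  y <- rep(1:2, each = 100)
  V <- matrix(rnorm(40), 20, 2)
  p1 <- predict(fit_classifier("lda_full", X, y), V)
  p2 <- predict(fit_classifier("lda_diag", X, y), V)
  expect_equal(as.integer(p1), as.integer(p2))
})

test_that("confusion metrics match hand-derived values", {
  # perfect predictions
  ev <- confusion_and_metrics(rep(1:5, each = 4), rep(1:5, each = 4))
  expect_equal(ev$acc, 1); expect_equal(ev$kappa, 1)
  expect_equal(ev$tpr, rep(1, 5)); expect_equal(ev$fpr, rep(0, 5))

  # 2-class confusion [[40,10],[20,30]]: ACC .7, p_e .5, kappa .4
  truth <- c(rep(1, 50), rep(2, 50))
  pred <- c(rep(1, 40), rep(2, 10), rep(1, 20), rep(2, 30))
  ev2 <- confusion_and_metrics(truth, pred, n_classes = 2)
  expect_equal(unname(ev2$confusion), rbind(c(40, 10), c(20, 30)))
  expect_equal(ev2$acc, 0.7)
  expect_equal(ev2$kappa, 0.4, tolerance = 1e-12)
  expect_equal(ev2$tpr, c(40 / 50, 30 / 50))
  expect_equal(ev2$fpr, c(20 / 50, 10 / 50))

  # independent predictions give kappa near zero
  set.seed(57)
  t3 <- sample(1:5, 5000, replace = TRUE)
  p3 <- sample(1:5, 5000, replace = TRUE)
  expect_lt(abs(confusion_and_metrics(t3, p3)$kappa), 0.03)

  expect_error(confusion_and_metrics(integer(0), integer(0)), "empty")
  expect_error(confusion_and_metrics(1:3, 1:4), "equal length")
})

test_that("stratified cross-validation is disjoint, covering and balanced", {
  set.seed(58)
  ds <- generate_feature_dataset(30, separation = 3, d = 40, seed = 3)
  k <- 3L
  fold <- thermoface:::stratified_folds(ds$labels, k, 42L)
  expect_setequal(unique(fold), 1:k)
  expect_length(fold, length(ds$labels))
  # per-fold class proportions within one sample of global
  for (f in 1:k) for (cl in 1:5) {
    n_cf <- sum(fold == f & ds$labels == cl)
    expect_lte(abs(n_cf - 30 / k), 1)
  }
  expect_error(thermoface:::stratified_folds(c(1, 1, 2), 3, 1), "fewer than")
})

test_that("cross_validate is deterministic and leak-free", {
  ds <- generate_feature_dataset(20, separation = 3, d = 30, seed = 7)
  cv1 <- cross_validate(ds$features, ds$labels, q = 10, k = 3, runs = 2, seed = 5)
  cv2 <- cross_validate(ds$features, ds$labels, q = 10, k = 3, runs = 2, seed = 5)
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(cv1$acc, cv2$acc)

  # no information leak: models fitted on the training fold are bit-identical
  # whatever the validation labels are
  X <- ds$features; idx_tr <- 1:60
  norm_a <- fit_normalization(X[idx_tr, ])
  pca_a <- fit_pca(apply_normalization(norm_a, X[idx_tr, ]), q = 10)
  norm_b <- fit_normalization(X[idx_tr, ])
  pca_b <- fit_pca(apply_normalization(norm_b, X[idx_tr, ]), q = 10)
  expect_identical(norm_a, norm_b)
  expect_identical(pca_a$components, pca_b$components)
})
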