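# Emotion recognition: z-score normalization, PCA (SVD) to 60 components,
# Gaussian discriminant classifiers, stratified k-fold cross-validation and
# ACC / Cohen's Kappa / per-class TPR-FPR metrics.
#
# The five emotion classes are disgust, fear, happiness, sadness, surprise
# (coded 1..5 throughout).

#' Emotion class labels
#' @format Character vector of the five class names in code order 1..5.
#' @export
emotion_classes <- c("disgust", "fear", "happiness", "sadness", "surprise")

#' Fit / apply per-feature z-score normalization
#'
#' Mean and standard deviation are estimated on the training set only and
#' reused unchanged on validation data (no leakage).  Zero-variance features
#' get scale 1, so constant columns map to zero instead of NaN.
#'
#' @param X Numeric n x d matrix of training feature vectors.
#' @return `fit_normalization`: an object of class `tf_norm_model` with
#'   fields `center`, `scale`.
#' @export
fit_normalization <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) stopf("empty training set")
  ctr <- colMeans(X)
  sc <- apply(X, 2L, stats::sd)
  sc[!is.finite(sc) | sc <= 0] <- 1
  structure(list(center = ctr, scale = sc), class = "tf_norm_model")
}

#' @rdname fit_normalization
#' @param model A `tf_norm_model`.
#' @param vectors Matrix (or single vector) to transform.
#' @return `apply_normalization`: the transformed matrix.
#' @export
apply_normalization <- function(model, vectors) {
  stopifnot(inherits(model, "tf_norm_model"))
  V <- if (is.null(dim(vectors))) matrix(vectors, nrow = 1L) else as.matrix(vectors)
  sweep(sweep(V, 2L, model$center), 2L, model$scale, "/")
}

#' Fit PCA by singular value decomposition
#'
#' Components are the right singular vectors of the column-centered data
#' matrix; explained variances are `d_i^2 / (n - 1)`, non-increasing by SVD
#' ordering.  The sign of each component is fixed so its largest-magnitude
#' loading is positive (SVD signs are otherwise arbitrary).
#'
#' @param X Normalized n x d training matrix, n >= 2.
#' @param q Number of components to keep, default 60; must satisfy
#'   `q <= min(n - 1, d)`.
#' @return An object of class `tf_pca_model` with fields `components`
#'   (d x q, orthonormal columns), `center`, `explained_variance`.
#' @export
fit_pca <- function(X, q = 60L) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n < 2L) stopf("PCA needs at least 2 samples")
  if (!is_count(q) || q < 1L || q > min(n - 1L, d))
    stopf("q must satisfy 1 <= q <= min(n-1, d) = %d", min(n - 1L, d))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sv <- svd(Xc, nu = 0, nv = q)
  V <- sv$v[, seq_len(q), drop = FALSE]
  for (j in seq_len(q)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  structure(list(components = V, center = ctr,
                 explained_variance = sv$d[seq_len(q)]^2 / (n - 1)),
            class = "tf_pca_model")
}

#' Project vectors onto fitted principal components
#' @param model A `tf_pca_model`.
#' @param vectors Matrix (or single vector) in the original feature space.
#' @return n x q matrix of scores.
#' @export
project_pca <- function(model, vectors) {
  stopifnot(inherits(model, "tf_pca_model"))
  V <- if (is.null(dim(vectors))) matrix(vectors, nrow = 1L) else as.matrix(vectors)
  sweep(V, 2L, model$center) %*% model$components
}

regularize_cov <- function(S, eps = 1e-6) {
  d <- nrow(S)
  S + diag(eps * sum(diag(S)) / d, d)
}

#' Fit a Gaussian discriminant classifier
#'
#' Closed-form Gaussian classification rules on the projected features:
#' \describe{
#'   \item{lda_full}{pooled full covariance, linear boundaries}
#'   \item{lda_diag}{pooled diagonal covariance}
#'   \item{qda_full}{per-class full covariance, quadratic boundaries}
#'   \item{qda_diag}{per-class diagonal covariance}
#'   \item{mahalanobis}{nearest class mean in the pooled-covariance metric
#'     (no priors, no log-determinant)}
#'   \item{naive_bayes}{independent per-class Gaussian per feature
#'     (per-class diagonal covariance with priors)}
#' }
#' Covariances are regularized by adding `1e-6 * trace/d` to the diagonal.
#' `linear_svm` is accepted in the interface for completeness but requires
#' an external solver not bundled here and raises an error.
#'
#' @param kind Classifier kind (see above).
#' @param X n x q matrix of projected training vectors.
#' @param y Training labels (factor or integer codes).
#' @return An object of class `tf_classifier`.
#' @export
fit_classifier <- function(kind = c("lda_full", "lda_diag", "qda_full",
                                    "qda_diag", "mahalanobis", "naive_bayes",
                                    "linear_svm"),
                           X, y) {
  kind <- match.arg(kind)
  if (kind == "linear_svm")
    stopf("linear_svm requires an external SVM solver which is not bundled")
  X <- as.matrix(X)
  y <- factor(y)
  classes <- levels(y)
  if (length(classes) < 2L) stopf("training needs at least 2 classes")
  n <- nrow(X); d <- ncol(X)
  means <- do.call(rbind, lapply(classes, function(cl)
    colMeans(X[y == cl, , drop = FALSE])))
  priors <- as.numeric(table(y)[classes]) / n
  per_class_full <- function() {
    lapply(classes, function(cl) {
      Xi <- X[y == cl, , drop = FALSE]
      S <- if (nrow(Xi) < 2L) diag(0, d) else stats::cov(Xi)
      regularize_cov(S)
    })
  }
  pooled_full <- function() {
    S <- matrix(0, d, d)
    for (cl in classes) {
      Xi <- X[y == cl, , drop = FALSE]
      if (nrow(Xi) >= 2L)
        S <- S + stats::cov(Xi) * (nrow(Xi) - 1L)
    }
    regularize_cov(S / (n - length(classes)))
  }
  covs <- switch(kind,
    lda_full = list(pooled = pooled_full()),
    mahalanobis = list(pooled = pooled_full()),
    lda_diag = list(pooled = diag(diag(pooled_full()), d)),
    qda_full = per_class_full(),
    qda_diag = lapply(per_class_full(), function(S) diag(diag(S), d)),
    naive_bayes = lapply(per_class_full(), function(S) diag(diag(S), d)))
  structure(list(kind = kind, classes = classes, means = means,
                 priors = priors, covs = covs, d = d),
            class = "tf_classifier")
}

#' Predict class labels with a fitted discriminant classifier
#'
#' @param object A `tf_classifier`.
#' @param newdata n x q matrix (or single vector) of projected features.
#' @param ... Unused.
#' @return Factor of predicted labels with the training levels.
#' @export
predict.tf_classifier <- function(object, newdata, ...) {
  V <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1L) else as.matrix(newdata)
  nc <- length(object$classes)
  scores <- matrix(0, nrow(V), nc)
  if (object$kind %in% c("lda_full", "lda_diag", "mahalanobis")) {
    Sinv <- solve(object$covs$pooled)
    for (j in seq_len(nc)) {
      mu <- object$means[j, ]
      diff <- sweep(V, 2L, mu)
      maha <- rowSums((diff %*% Sinv) * diff)
      scores[, j] <- if (object$kind == "mahalanobis") -maha
                     else -0.5 * maha + log(object$priors[j])
    }
  } else {
    for (j in seq_len(nc)) {
      S <- object$covs[[j]]
      Sinv <- solve(S)
      ld <- determinant(S, logarithm = TRUE)$modulus
      mu <- object$means[j, ]
      diff <- sweep(V, 2L, mu)
      maha <- rowSums((diff %*% Sinv) * diff)
      scores[, j] <- -0.5 * (maha + ld) + log(object$priors[j])
    }
  }
  best <- max.col(scores, ties.method = "first")
  factor(object$classes[best], levels = object$classes)
}

#' Posterior class probabilities from a discriminant classifier
#'
#' Softmax of the Gaussian discriminant scores (for `mahalanobis`, of the
#' negative squared distances).
#'
#' @inheritParams predict.tf_classifier
#' @param model A `tf_classifier`.
#' @return n x n_classes matrix of posteriors.
#' @export
classifier_posterior <- function(model, newdata) {
  stopifnot(inherits(model, "tf_classifier"))
  V <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1L) else as.matrix(newdata)
  nc <- length(model$classes)
  logp <- matrix(0, nrow(V), nc)
  for (j in seq_len(nc)) {
    S <- if (!is.null(model$covs$pooled)) model$covs$pooled else model$covs[[j]]
    Sinv <- solve(S)
    ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
    mu <- model$means[j, ]
    diff <- sweep(V, 2L, mu)
    maha <- rowSums((diff %*% Sinv) * diff)
    logp[, j] <- -0.5 * (maha + ld) + log(model$priors[j])
  }
  m <- apply(logp, 1L, max)
  p <- exp(logp - m)
  p / rowSums(p)
}

#' Confusion matrix and classification metrics
#'
#' ACC = trace/total; Cohen's Kappa = (p_o - p_e)/(1 - p_e) with expected
#' agreement p_e from the row/column marginals; per-class one-vs-rest
#' TPR = TP/(TP+FN) and FPR = FP/(FP+TN).
#'
#' @param true_labels,predicted_labels Equal-length label vectors (factors
#'   or integer codes 1..n_classes).
#' @param n_classes Number of classes (default 5).
#' @return An object of class `tf_evaluation`: `confusion` (true x
#'   predicted), `acc`, `kappa`, `tpr`, `fpr`.
#' @export
confusion_and_metrics <- function(true_labels, predicted_labels, n_classes = 5L) {
  if (length(true_labels) == 0L) stopf("empty label vectors")
  if (length(true_labels) != length(predicted_labels))
    stopf("label vectors must have equal length")
  lv <- as.character(seq_len(n_classes))
  tl <- coerce_codes(true_labels, n_classes)
  pl <- coerce_codes(predicted_labels, n_classes)
  cm <- table(factor(tl, levels = seq_len(n_classes)),
              factor(pl, levels = seq_len(n_classes)))
  cm <- matrix(as.numeric(cm), n_classes, n_classes,
               dimnames = list(true = lv, predicted = lv))
  total <- sum(cm)
  acc <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  kappa <- if (abs(1 - pe) < 1e-15) {
    if (acc >= 1 - 1e-15) 1 else 0
  } else (acc - pe) / (1 - pe)
  tpr <- fpr <- numeric(n_classes)
  for (j in seq_len(n_classes)) {
    tp <- cm[j, j]; fn <- sum(cm[j, ]) - tp
    fp <- sum(cm[, j]) - tp; tn <- total - tp - fn - fp
    tpr[j] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    fpr[j] <- if (fp + tn > 0) fp / (fp + tn) else NA_real_
  }
  structure(list(confusion = cm, acc = acc, kappa = kappa,
                 tpr = tpr, fpr = fpr, n = total),
            class = "tf_evaluation")
}

# map labels to integer codes 1..n_classes; factors use their level order
coerce_codes <- function(x, n_classes) {
  if (is.factor(x)) return(as.integer(x))
  xi <- as.integer(x)
  if (any(is.na(xi)) || any(xi < 1L) || any(xi > n_classes))
    stopf("labels must be codes in 1..%d or factors", n_classes)
  xi
}

#' @export
print.tf_evaluation <- function(x, ...) {
  cat(sprintf("<tf_evaluation n=%d ACC=%.4f Kappa=%.4f>\n", x$n, x$acc, x$kappa))
  invisible(x)
}

# stratified fold assignment: per class, shuffle members and deal them
# round-robin into k folds, so per-fold class proportions stay within one
# sample of the global proportions
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  y <- factor(y)
  fold <- integer(length(y))
  start <- 0L
  for (cl in levels(y)) {
    idx <- which(y == cl)
    if (length(idx) < k)
      stopf("class '%s' has %d members, fewer than k = %d", cl, length(idx), k)
    idx <- sample(idx)
    fold[idx] <- ((seq_along(idx) + start - 1L) %% k) + 1L
    start <- start + length(idx)  # stagger so small classes spread evenly
  }
  fold
}

#' Cross-validate the normalization + PCA + classifier pipeline
#'
#' Stratified k-fold cross-validation repeated over `runs` re-randomized
#' fold assignments.  Normalization and PCA are fitted inside each training
#' fold only; the held-out fold is transformed with the training-fold models
#' (no leakage).  Metrics are aggregated as mean +/- standard error over all
#' folds x runs.
#'
#' @param features n x d matrix of raw feature vectors.
#' @param labels Class labels (factor or codes 1..n_classes).
#' @param kind Classifier kind for [fit_classifier()].
#' @param q PCA components (default 60); capped at `min(n_train - 1, d)` is
#'   an error, not silent.
#' @param k Folds (default 3).
#' @param runs Repeats with distinct fold randomizations (default 10).
#' @param seed Root seed; all fold randomness derives from it.
#' @return An object of class `tf_cv_result`: `acc`, `kappa` (means),
#'   `acc_se`, `kappa_se`, per-class `tpr`/`fpr` means and SEs, the pooled
#'   `confusion`, and the per-fold table `folds`.
#' @export
cross_validate <- function(features, labels, kind = "lda_full", q = 60L,
                           k = 3L, runs = 10L, seed = 1L) {
  X <- as.matrix(features)
  y <- factor(labels)
  n_classes <- length(levels(y))
  if (n_classes < 2L) stopf("cross-validation needs at least 2 classes")
  per_fold <- list()
  pooled <- NULL
  for (r in seq_len(runs)) {
    fold <- stratified_folds(y, k, derive_seed(seed, r))
    for (f in seq_len(k)) {
      tr <- fold != f; va <- !tr
      norm <- fit_normalization(X[tr, , drop = FALSE])
      Xtr <- apply_normalization(norm, X[tr, , drop = FALSE])
      pca <- fit_pca(Xtr, q = q)
      Ztr <- project_pca(pca, Xtr)
      clf <- fit_classifier(kind, Ztr, y[tr])
      Zva <- project_pca(pca, apply_normalization(norm, X[va, , drop = FALSE]))
      pred <- predict(clf, Zva)
      ev <- confusion_and_metrics(as.integer(y[va]), as.integer(pred), n_classes)
      pooled <- if (is.null(pooled)) ev$confusion else pooled + ev$confusion
      per_fold[[length(per_fold) + 1L]] <-
        data.frame(run = r, fold = f, acc = ev$acc, kappa = ev$kappa,
                   t(stats::setNames(ev$tpr, paste0("tpr", seq_len(n_classes)))),
                   t(stats::setNames(ev$fpr, paste0("fpr", seq_len(n_classes)))))
    }
  }
  folds <- do.call(rbind, per_fold)
  se <- function(v) stats::sd(v) / sqrt(length(v))
  tpr_cols <- paste0("tpr", seq_len(n_classes))
  fpr_cols <- paste0("fpr", seq_len(n_classes))
  structure(list(acc = mean(folds$acc), acc_se = se(folds$acc),
                 kappa = mean(folds$kappa), kappa_se = se(folds$kappa),
                 tpr = colMeans(folds[tpr_cols], na.rm = TRUE),
                 tpr_se = vapply(folds[tpr_cols], se, numeric(1)),
                 fpr = colMeans(folds[fpr_cols], na.rm = TRUE),
                 fpr_se = vapply(folds[fpr_cols], se, numeric(1)),
                 confusion = pooled, folds = folds,
                 classes = levels(y), kind = kind, q = q, k = k, runs = runs),
            class = "tf_cv_result")
}

#' @export
print.tf_cv_result <- function(x, ...) {
  cat(sprintf("<tf_cv_result %s q=%d kfold=%d runs=%d ACC=%.4f+/-%.4f Kappa=%.4f+/-%.4f>\n",
              x$kind, x$q, x$k, x$runs, x$acc, x$acc_se, x$kappa, x$kappa_se))
  invisible(x)
}
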