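# Classifier backends behind a single train/score surface. Random forest
# and SVM are delegated to randomForest and e1071; LDA is a
# ridge-regularised Gaussian discriminant (the feature matrices have many
# more columns than rows, where an unregularised pooled covariance is
# singular); kNN is a direct distance-matrix implementation.

#' Classifier specification
#'
#' Fixed hyperparameter bundles for the five supported classifier kinds:
#'
#' * `rf` — random forest, 150 trees, Gini splitting, at most 150 splits
#'   per tree, minimum leaf size 1;
#' * `lda` — linear discriminant analysis with a small ridge on the pooled
#'   covariance (`lambda`, relative to its mean diagonal);
#' * `knn` — k-nearest neighbour, `k = 1`, Euclidean metric,
#'   inverse-distance weighting (moot at k = 1 but honoured for larger k);
#' * `svm` — support vector machine with a degree-2 polynomial kernel,
#'   `C = 1`, one-vs-one multiclass, Platt-scaled posteriors;
#' * `cnn` — the compact 1D convolutional network of [cnn_train()].
#'
#' @param kind classifier kind.
#' @param ... overrides of the kind's defaults (e.g. `k`, `lambda`,
#'   `epochs`, `seed`).
#' @return list of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("rf", "lda", "knn", "svm", "cnn"), ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    rf = list(ntree = 150, max_splits = 150, min_leaf = 1),
    lda = list(lambda = 1e-3),
    knn = list(k = 1),
    svm = list(degree = 2, cost = 1, coef0 = 1),
    cnn = list(epochs = 200, batch_size = 128, lr = 1e-4, dropout = 0.5,
               dense_units = 128))
  override <- list(...)
  defaults[names(override)] <- override
  structure(c(list(kind = kind, seed = override$seed %||% 1L), defaults),
            class = "classifier_spec")
}

#' Train a classifier and score test samples
#'
#' Fits the classifier described by `spec` on the training features and
#' scores every test sample, returning per-class posterior (or
#' posterior-like) scores and argmax predictions.
#'
#' @param spec a [classifier_spec()].
#' @param x_train,x_test numeric matrices (samples x features, flat
#'   layout). For the CNN the rows are reshaped internally to
#'   `n_freq x n_channels` using `n_channels`.
#' @param y_train factor of training labels (>= 2 classes).
#' @param n_channels number of feature combos per sample (CNN input
#'   channels); required for `kind = "cnn"`.
#' @return list of class `score_set`: `scores` (n_test x n_classes matrix,
#'   rows summing to 1, columns named by class), `predicted` (factor),
#'   `classes`.
#' @export
train_and_score <- function(spec, x_train, y_train, x_test,
                            n_channels = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  y_train <- droplevels(as.factor(y_train))
  if (nlevels(y_train) < 2) stop("training data must contain >= 2 classes")
  x_train <- as.matrix(x_train)
  x_test <- as.matrix(x_test)
  scores <- switch(spec$kind,
    rf = {
      fit <- with_seed(spec$seed,
        randomForest::randomForest(
          x = x_train, y = y_train, ntree = spec$ntree,
          nodesize = spec$min_leaf,
          maxnodes = min(spec$max_splits + 1, nrow(x_train))))
      predict(fit, x_test, type = "prob")
    },
    lda = {
      fit <- ridge_lda_fit(x_train, y_train, spec$lambda)
      ridge_lda_posterior(fit, x_test)
    },
    knn = knn_scores(x_train, y_train, x_test, spec$k),
    svm = {
      fit <- with_seed(spec$seed,
        e1071::svm(x_train, y_train, kernel = "polynomial",
                   degree = spec$degree, coef0 = spec$coef0,
                   cost = spec$cost, probability = TRUE))
      p <- attr(predict(fit, x_test, probability = TRUE), "probabilities")
      p[, levels(y_train), drop = FALSE]
    },
    cnn = {
      if (is.null(n_channels)) stop("cnn requires n_channels")
      fit <- cnn_train(flat_to_channels(x_train, n_channels), y_train, spec)
      cnn_predict(fit, flat_to_channels(x_test, n_channels))
    })
  scores <- as.matrix(scores)[, levels(y_train), drop = FALSE]
  predicted <- factor(levels(y_train)[max.col(scores, ties.method = "first")],
                      levels = levels(y_train))
  structure(list(scores = scores, predicted = predicted,
                 classes = levels(y_train)),
            class = "score_set")
}

# Reshape flat (family, combo, frequency)-ordered rows into an
# n x n_freq x n_channels array for the CNN.
flat_to_channels <- function(x, n_channels) {
  n_freq <- ncol(x) / n_channels
  stopifnot(n_freq == round(n_freq))
  aperm(array(t(x), dim = c(n_freq, n_channels, nrow(x))), c(3, 1, 2))
}

# --- ridge-regularised LDA -------------------------------------------------

ridge_lda_fit <- function(x, y, lambda = 1e-3) {
  classes <- levels(y)
  p <- ncol(x)
  means <- t(vapply(classes, function(cl)
    colMeans(x[y == cl, , drop = FALSE]), numeric(p)))
  centred <- x - means[as.integer(y), , drop = FALSE]
  s <- crossprod(centred) / max(1, nrow(x) - length(classes))
  s <- s + diag(lambda * mean(diag(s)) + 1e-12, p)
  sinv <- chol2inv(chol(s))
  list(classes = classes, means = means, sinv = sinv,
       log_prior = log(as.numeric(table(y)) / length(y)))
}

ridge_lda_posterior <- function(fit, x) {
  # linear discriminant: x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log pi_k
  a <- fit$sinv %*% t(fit$means)                  # p x K
  const <- -0.5 * colSums(t(fit$means) * a) + fit$log_prior
  d <- x %*% a + rep(const, each = nrow(x))
  d <- d - apply(d, 1, max)
  e <- exp(d)
  out <- e / rowSums(e)
  colnames(out) <- fit$classes
  out
}

# --- k-nearest neighbour ---------------------------------------------------

knn_scores <- function(x_train, y_train, x_test, k = 1, eps = 1e-12) {
  d2 <- outer(rowSums(x_test^2), rowSums(x_train^2), `+`) -
    2 * tcrossprod(x_test, x_train)
  d <- sqrt(pmax(d2, 0))
  classes <- levels(y_train)
  # per-class score: normalised inverse distance to the class's nearest
  # training point; at k = 1 the argmax is the 1-NN prediction.
  nearest <- vapply(classes, function(cl)
    apply(d[, y_train == cl, drop = FALSE], 1, min), numeric(nrow(x_test)))
  nearest <- matrix(nearest, nrow = nrow(x_test),
                    dimnames = list(NULL, classes))
  w <- 1 / (nearest + eps)
  if (k > 1) {
    # distance-weighted vote among the k nearest neighbours overall,
    # blended with the per-class nearest-distance score for classes
    # outside the neighbourhood.
    vote <- t(apply(d, 1, function(row) {
      nb <- order(row)[seq_len(min(k, length(row)))]
      tapply(1 / (row[nb] + eps), factor(y_train[nb], levels = classes),
             sum, default = 0)
    }))
    w <- vote + eps * w
  }
  w / rowSums(w)
}
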