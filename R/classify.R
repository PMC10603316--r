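#' Classifier specification
#'
#' The classifier battery: LDA with pseudo-inverse pooled covariance (so it
#' remains defined when features outnumber instances), soft-margin SVM with
#' RBF kernel and penalty `C = 1`, nearest-neighbour with Euclidean distance
#' and `k = 1`, and a RANDOM benchmark predicting each class with
#' probability one half.
#'
#' @param kind one of `"LDA"`, `"SVM"`, `"KNN"`, `"RANDOM"`.
#' @param svm_c SVM penalty parameter (default 1).
#' @param svm_gamma RBF kernel width; `NULL` (default) uses the scale
#'   heuristic `1 / (n_features * var(X))`, recorded in the fit metadata.
#' @param knn_k number of neighbours (default 1; equidistant ties go to the
#'   lowest training index).
#' @param seed optional seed for the RANDOM benchmark when called standalone;
#'   inside the cross-validation harness randomness flows from the harness
#'   seed instead.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("LDA", "SVM", "KNN", "RANDOM"),
                            svm_c = 1, svm_gamma = NULL, knn_k = 1L,
                            seed = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, svm_c = svm_c, svm_gamma = svm_gamma,
                 knn_k = as.integer(knn_k), seed = seed),
            class = "classifier_spec")
}

#' @rdname classifier_spec
#' @export
default_classifier_specs <- function() {
  list(LDA = classifier_spec("LDA"), SVM = classifier_spec("SVM"),
       KNN = classifier_spec("KNN"), RANDOM = classifier_spec("RANDOM"))
}

# LDA with shared covariance inverted by Moore-Penrose pseudo-inverse and
# empirical class priors. Works (as a minimum-norm discriminant) even when
# the pooled covariance is singular, the usual situation at features >>
# instances.
lda_pinv_predict <- function(xtr, ytr, xte) {
  x0 <- xtr[ytr == 0L, , drop = FALSE]
  x1 <- xtr[ytr == 1L, , drop = FALSE]
  n0 <- nrow(x0); n1 <- nrow(x1)
  mu0 <- colMeans(x0); mu1 <- colMeans(x1)
  sc0 <- sweep(x0, 2L, mu0); sc1 <- sweep(x1, 2L, mu1)
  s <- (crossprod(sc0) + crossprod(sc1)) / max(1L, n0 + n1 - 2L)
  sinv <- MASS::ginv(s)
  w <- sinv %*% cbind(mu0, mu1)                       # [d x 2]
  const <- -0.5 * colSums(cbind(mu0, mu1) * w) +
    log(c(n0, n1) / (n0 + n1))
  scores <- sweep(xte %*% w, 2L, const, `+`)
  as.integer(scores[, 2L] > scores[, 1L])
}

knn1_predict <- function(xtr, ytr, xte) {
  d2 <- outer(rowSums(xte^2), rep(1, nrow(xtr))) +
    outer(rep(1, nrow(xte)), rowSums(xtr^2)) - 2 * tcrossprod(xte, xtr)
  ytr[max.col(-d2, ties.method = "first")]
}

svm_rbf_predict <- function(xtr, ytr, xte, cost, gamma) {
  if (is.null(gamma)) {
    v <- stats::var(as.vector(xtr))
    gamma <- if (v > 0) 1 / (ncol(xtr) * v) else 1 / ncol(xtr)
  }
  fit <- e1071::svm(x = xtr, y = factor(ytr, levels = c(0L, 1L)),
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  as.integer(as.character(stats::predict(fit, xte)))
}

# Matrix-level dispatch used by both the public train_predict and the CV
# harness. RANDOM draws from the current RNG stream.
fit_predict <- function(spec, xtr, ytr, xte) {
  if (spec$kind != "RANDOM" && length(unique(ytr)) < 2L) {
    stop("single-class training set: cannot fit ", spec$kind, call. = FALSE)
  }
  switch(spec$kind,
    LDA = lda_pinv_predict(xtr, ytr, xte),
    SVM = svm_rbf_predict(xtr, ytr, xte, spec$svm_c, spec$svm_gamma),
    KNN = {
      if (spec$knn_k != 1L) stop("only k = 1 is supported", call. = FALSE)
      knn1_predict(xtr, ytr, xte)
    },
    RANDOM = sample(c(0L, 1L), nrow(xte), replace = TRUE)
  )
}

#' Train a classifier and predict test labels
#'
#' @param spec a [classifier_spec()].
#' @param train,test [feature_matrix()] objects with aligned feature columns.
#' @return Integer vector of predicted 0/1 labels for the test instances.
#' @export
train_predict <- function(spec, train, test) {
  stopifnot(inherits(spec, "classifier_spec"),
            inherits(train, "feature_matrix"),
            inherits(test, "feature_matrix"))
  if (ncol(train$values) != ncol(test$values)) {
    stop("train and test feature columns are not aligned", call. = FALSE)
  }
  if (spec$kind == "RANDOM" && !is.null(spec$seed)) {
    with_seed(spec$seed,
              fit_predict(spec, train$values, train$labels, test$values))
  } else {
    fit_predict(spec, train$values, train$labels, test$values)
  }
}

#' Classification accuracy
#'
#' Fraction of correct predictions — the evaluation metric throughout, which
#' is meaningful here because the two classes are approximately balanced.
#'
#' @param predicted,actual equal-length 0/1 label vectors.
#' @return Fraction correct in `[0, 1]`.
#' @export
accuracy <- function(predicted, actual) {
  if (length(predicted) == 0L || length(predicted) != length(actual)) {
    stop("`predicted` and `actual` must be non-empty and of equal length",
         call. = FALSE)
  }
  mean(predicted == actual)
}
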