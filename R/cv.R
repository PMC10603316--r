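#' Stratified fold assignments for repeated cross-validation
#'
#' Draws, per repetition, a seeded stratified partition of the instances
#' into `n_folds` folds (each instance tested exactly once per repeat; class
#' proportions preserved per fold up to rounding).
#'
#' @param labels binary instance labels.
#' @param n_folds,n_repeats cross-validation scheme (defaults 10 and 10).
#' @param seed integer seed; the same seed gives the same partitions.
#' @return List of length `n_repeats`; each element an integer fold id per
#'   instance.
#' @export
make_folds <- function(labels, n_folds = 10L, n_repeats = 10L, seed = 1L) {
  labels <- as.integer(labels)
  if (min(table(labels)) < n_folds) {
    stop("too few instances: need at least ", n_folds,
         " per class for stratified ", n_folds, "-fold CV", call. = FALSE)
  }
  with_seed(seed, {
    lapply(seq_len(n_repeats), function(r) {
      fold <- integer(length(labels))
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        fold[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
      fold
    })
  })
}

# One pass over the folds of a single repeat. Feature selection is
# recomputed on the training portion of every fold ("fold" scope, the
# leakage-safe default); "full" scope reuses a selection computed once on
# all instances (kept only to demonstrate the optimistic bias it causes);
# "none" disables selection. RANDOM predictions draw from the caller's RNG
# stream. Returns [n_folds x n_specs] accuracies.
cv_one_repeat <- function(x, y, specs, fold_ids, threshold_frac,
                          selection_scope, full_selection = NULL) {
  n_folds <- max(fold_ids)
  acc <- matrix(NA_real_, n_folds, length(specs),
                dimnames = list(NULL, names(specs)))
  for (f in seq_len(n_folds)) {
    tr <- fold_ids != f
    keep <- switch(selection_scope,
      fold = select_by_cumulative_score(
        point_biserial_r2(x[tr, , drop = FALSE], y[tr]), threshold_frac),
      full = full_selection,
      none = seq_len(ncol(x)))
    xtr <- x[tr, keep, drop = FALSE]
    xte <- x[!tr, keep, drop = FALSE]
    for (j in seq_along(specs)) {
      pred <- fit_predict(specs[[j]], xtr, y[tr], xte)
      acc[f, j] <- accuracy(pred, y[!tr])
    }
  }
  acc
}

#' Repeated stratified cross-validation with in-fold feature selection
#'
#' The evaluation harness: `n_repeats` repetitions of stratified
#' `n_folds`-fold cross-validation. Within every fold, feature scores
#' (squared point-biserial correlation) and the cumulative-threshold
#' selection are computed on the training portion only, then applied to both
#' portions — selection never sees test labels, avoiding the optimistic bias
#' of selecting before splitting. Each repetition yields one mean accuracy
#' per classifier; with the default battery of four classifiers and 10
#' repeats the result is a 10 x 4 matrix.
#'
#' @param features a [feature_matrix()].
#' @param specs named list of [classifier_spec()]s (default: LDA, SVM, KNN,
#'   RANDOM).
#' @param n_folds,n_repeats cross-validation scheme (defaults 10, 10).
#' @param threshold_frac cumulative r-squared selection threshold
#'   (default 0.90).
#' @param seed integer; folds and the RANDOM benchmark both derive from it,
#'   so equal seeds give identical results end to end.
#' @param selection_scope `"fold"` (default, leakage-safe), `"full"`
#'   (selection once on all data — biased, kept for demonstrating leakage),
#'   or `"none"`.
#' @return An object of class `cv_result`: `mean_accuracy`
#'   (`n_repeats x n_classifiers`), `fold_accuracy`
#'   (`n_repeats x n_folds x n_classifiers`), and the configuration echo.
#' @export
repeated_cv <- function(features, specs = default_classifier_specs(),
                        n_folds = 10L, n_repeats = 10L,
                        threshold_frac = 0.90, seed = 1L,
                        selection_scope = c("fold", "full", "none")) {
  stopifnot(inherits(features, "feature_matrix"))
  selection_scope <- match.arg(selection_scope)
  x <- features$values
  y <- features$labels
  folds <- make_folds(y, n_folds, n_repeats, seed)
  full_sel <- if (selection_scope == "full") {
    select_by_cumulative_score(point_biserial_r2(x, y), threshold_frac)
  }
  fold_acc <- array(NA_real_, c(n_repeats, n_folds, length(specs)),
                    dimnames = list(NULL, NULL, names(specs)))
  with_seed(derive_seed(seed, 7L), {
    for (r in seq_len(n_repeats)) {
      fold_acc[r, , ] <- cv_one_repeat(x, y, specs, folds[[r]],
                                       threshold_frac, selection_scope,
                                       full_sel)
    }
  })
  mean_acc <- apply(fold_acc, c(1L, 3L), mean)
  structure(
    list(mean_accuracy = mean_acc, fold_accuracy = fold_acc,
         config = list(n_folds = n_folds, n_repeats = n_repeats,
                       threshold_frac = threshold_frac, seed = seed,
                       selection_scope = selection_scope,
                       classifiers = names(specs))),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d repeats x %d-fold CV\nmean accuracy per classifier:\n",
              x$config$n_repeats, x$config$n_folds))
  print(round(colMeans(x$mean_accuracy), 4))
  invisible(x)
}

#' Segment-wise repeated cross-validation (dynamic decoding)
#'
#' Runs the repeated-CV harness independently on each sliding-segment
#' feature matrix, producing per-classifier accuracy sequences over time.
#' Fold assignments are drawn once per repetition (from the seed) and reused
#' across segments, so per-segment accuracies are paired across the
#' time axis; the RANDOM benchmark redraws its predictions at every segment.
#'
#' @param segment_features list of [feature_matrix()] objects from
#'   [dynamic_spectral_features()] or [dynamic_temporal_features()].
#' @inheritParams repeated_cv
#' @return An object of class `dynamic_cv_result`: `accuracy` array
#'   `[n_repeats x n_segments x n_classifiers]`, `segment_times` (s, the
#'   window onsets), and the configuration echo.
#' @export
dynamic_repeated_cv <- function(segment_features,
                                specs = default_classifier_specs(),
                                n_folds = 10L, n_repeats = 10L,
                                threshold_frac = 0.90, seed = 1L,
                                selection_scope = c("fold", "full", "none")) {
  if (length(segment_features) == 0L) {
    stop("empty segment list", call. = FALSE)
  }
  selection_scope <- match.arg(selection_scope)
  y <- segment_features[[1L]]$labels
  for (fm in segment_features) {
    if (!identical(fm$labels, y)) {
      stop("segments disagree on instances/labels", call. = FALSE)
    }
  }
  folds <- make_folds(y, n_folds, n_repeats, seed)
  n_seg <- length(segment_features)
  acc <- array(NA_real_, c(n_repeats, n_seg, length(specs)),
               dimnames = list(NULL, NULL, names(specs)))
  with_seed(derive_seed(seed, 7L), {
    for (s in seq_len(n_seg)) {
      x <- segment_features[[s]]$values
      full_sel <- if (selection_scope == "full") {
        select_by_cumulative_score(point_biserial_r2(x, y), threshold_frac)
      }
      for (r in seq_len(n_repeats)) {
        acc[r, s, ] <- colMeans(cv_one_repeat(
          x, y, specs, folds[[r]], threshold_frac, selection_scope,
          full_sel))
      }
    }
  })
  times <- vapply(segment_features, function(fm) fm$time_s %||% NA_real_,
                  numeric(1L))
  structure(
    list(accuracy = acc, segment_times = times,
         config = list(n_folds = n_folds, n_repeats = n_repeats,
                       threshold_frac = threshold_frac, seed = seed,
                       selection_scope = selection_scope,
                       classifiers = names(specs))),
    class = "dynamic_cv_result"
  )
}

#' Write cross-validation results as tidy CSV
#'
#' Static results get columns `repeat`, `classifier`, `accuracy`; dynamic
#' results additionally `segment` and `time_s`.
#'
#' @param result a `cv_result` or `dynamic_cv_result`.
#' @param path output CSV path.
#' @export
write_cv_csv <- function(result, path) {
  if (inherits(result, "cv_result")) {
    m <- result$mean_accuracy
    dt <- data.table::data.table(
      rep = rep(seq_len(nrow(m)), ncol(m)),
      classifier = rep(colnames(m), each = nrow(m)),
      accuracy = as.vector(m))
  } else if (inherits(result, "dynamic_cv_result")) {
    a <- result$accuracy
    d <- dim(a)
    dt <- data.table::data.table(
      rep = rep(seq_len(d[1L]), times = d[2L] * d[3L]),
      segment = rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L]),
      time_s = rep(rep(result$segment_times, each = d[1L]), times = d[3L]),
      classifier = rep(dimnames(a)[[3L]], each = d[1L] * d[2L]),
      accuracy = as.vector(a))
  } else {
    stop("`result` must be a cv_result or dynamic_cv_result", call. = FALSE)
  }
  data.table::fwrite(dt, path)
  invisible(path)
}
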