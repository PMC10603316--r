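#' Right-tailed pooled two-sample t-test
#'
#' Compares a classifier's per-repetition accuracies against the RANDOM
#' benchmark's: pooled-variance (Student) two-sample t statistic with
#' `df = n1 + n2 - 2` (two samples of 10 repetitions give the t(18)
#' reference distribution) and an upper-tail p-value — the alternative is
#' that the classifier outperforms the benchmark. Degenerate inputs follow
#' fixed conventions: zero pooled variance with equal means gives `p = 0.5`;
#' zero pooled variance with unequal means gives `p = 0` or `1` by the sign
#' of the difference.
#'
#' @param sample_a,sample_b numeric vectors of at least 2 accuracies;
#'   `sample_a` is the classifier under test, `sample_b` the benchmark.
#' @param alpha significance level for the `significant` flag
#'   (default 0.05); refers to the uncorrected p-value.
#' @return An object of class `test_result`: `t_stat`, `df`, `p_raw`,
#'   `p_corrected` (initialised to `p_raw` until a correction is applied)
#'   and `significant`.
#' @export
t_test_right <- function(sample_a, sample_b, alpha = 0.05) {
  n1 <- length(sample_a); n2 <- length(sample_b)
  if (n1 < 2L || n2 < 2L) {
    stop("both samples need at least 2 values", call. = FALSE)
  }
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(sample_a) + (n2 - 1) * stats::var(sample_b)) /
    df
  delta <- mean(sample_a) - mean(sample_b)
  if (sp2 == 0) {
    t_stat <- if (delta == 0) 0 else sign(delta) * Inf
    p <- if (delta == 0) 0.5 else if (delta > 0) 0 else 1
  } else {
    t_stat <- delta / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- stats::pt(t_stat, df, lower.tail = FALSE)
  }
  structure(list(t_stat = t_stat, df = df, p_raw = p, p_corrected = p,
                 significant = p < alpha, alpha = alpha),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g%s\n", x$df, x$t_stat, x$p_raw,
              if (x$p_corrected != x$p_raw)
                sprintf(" (corrected %.4g)", x$p_corrected) else ""))
  invisible(x)
}

#' Bonferroni-Holm step-down correction
#'
#' Adjusts a sequence of p-values for multiple comparisons by Holm's
#' step-down procedure: the i-th smallest p is multiplied by `m - i + 1`,
#' monotonicity is enforced by a running maximum, values are capped at 1 and
#' returned in the original order. Never less conservative than the raw
#' p-values, never more conservative than plain Bonferroni.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Corrected p-values, same length and order.
#' @examples
#' holm_correct(c(0.01, 0.02, 0.04))  # 0.03 0.04 0.04
#' @export
holm_correct <- function(p_values) {
  if (any(p_values < 0 | p_values > 1) || anyNA(p_values)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "holm")
}

#' Best accuracy point of a dynamic decoding sequence
#'
#' Among the segments whose corrected p-value is below `alpha`, picks the
#' one with the highest mean accuracy (ties go to the earliest window) and
#' reports the left extreme of its temporal window plus the accuracy there.
#'
#' @param mean_acc per-segment mean accuracies.
#' @param p_corrected per-segment corrected p-values.
#' @param segment_times per-segment window-onset times, seconds.
#' @param alpha significance level (default 0.05).
#' @return A list (`best_point`) with `segment_index`, `time_s`, `accuracy`,
#'   or `NULL` when no segment is significant.
#' @export
best_accuracy_point <- function(mean_acc, p_corrected, segment_times,
                                alpha = 0.05) {
  n <- length(mean_acc)
  if (length(p_corrected) != n || length(segment_times) != n) {
    stop("sequence lengths differ", call. = FALSE)
  }
  sig <- which(p_corrected < alpha)
  if (length(sig) == 0L) return(NULL)
  best_acc <- max(mean_acc[sig])
  cand <- sig[mean_acc[sig] == best_acc]
  pick <- cand[which.min(segment_times[cand])]
  structure(list(segment_index = pick, time_s = segment_times[pick],
                 accuracy = best_acc),
            class = "best_point")
}

#' Compare classifiers against the RANDOM benchmark (static)
#'
#' Right-tailed pooled t-test of each classifier's per-repetition mean
#' accuracies against the benchmark column of the same [repeated_cv()]
#' result.
#'
#' @param cv a `cv_result` containing a `"RANDOM"` column.
#' @param alpha significance level (default 0.05).
#' @return Named list of `test_result` objects, one per non-benchmark
#'   classifier.
#' @export
benchmark_tests <- function(cv, alpha = 0.05) {
  stopifnot(inherits(cv, "cv_result"))
  m <- cv$mean_accuracy
  if (!"RANDOM" %in% colnames(m)) {
    stop("cv result lacks a RANDOM benchmark column", call. = FALSE)
  }
  others <- setdiff(colnames(m), "RANDOM")
  stats::setNames(
    lapply(others, function(cl) t_test_right(m[, cl], m[, "RANDOM"], alpha)),
    others)
}

#' Segment-wise benchmark comparison with Holm correction (dynamic)
#'
#' For each classifier, tests every segment's 10 repetition accuracies
#' against the benchmark's at the same segment (right-tailed pooled t-test),
#' Holm-corrects the resulting p-value sequence over segments — each
#' classifier's sequence is its own correction family — and locates the best
#' accuracy point.
#'
#' @param dyn a `dynamic_cv_result` containing a `"RANDOM"` classifier.
#' @param alpha significance level (default 0.05).
#' @return An object of class `dynamic_result`: per classifier, a list with
#'   `mean_acc`, `p_raw`, `p_corrected` (length = number of segments) and
#'   `best_point`; plus `segment_times`.
#' @export
dynamic_benchmark_stats <- function(dyn, alpha = 0.05) {
  stopifnot(inherits(dyn, "dynamic_cv_result"))
  cls <- dimnames(dyn$accuracy)[[3L]]
  if (!"RANDOM" %in% cls) {
    stop("dynamic result lacks a RANDOM benchmark", call. = FALSE)
  }
  n_seg <- dim(dyn$accuracy)[2L]
  out <- list()
  for (cl in setdiff(cls, "RANDOM")) {
    p_raw <- numeric(n_seg)
    for (s in seq_len(n_seg)) {
      p_raw[s] <- t_test_right(dyn$accuracy[, s, cl],
                               dyn$accuracy[, s, "RANDOM"])$p_raw
    }
    p_corr <- holm_correct(p_raw)
    mean_acc <- colMeans(dyn$accuracy[, , cl])
    out[[cl]] <- list(
      mean_acc = mean_acc, p_raw = p_raw, p_corrected = p_corr,
      best_point = best_accuracy_point(mean_acc, p_corr,
                                       dyn$segment_times, alpha))
  }
  structure(list(classifiers = out, segment_times = dyn$segment_times,
                 alpha = alpha),
            class = "dynamic_result")
}

#' Spearman correlation between best accuracies and their times
#'
#' Convenience summary over a table of significant results: rank correlation
#' of accuracy with window-onset time, to ask whether better decoding
#' clusters early or late in the anticipation window.
#'
#' @param accuracies,times_s equal-length numeric vectors.
#' @return List with `rho` and `p_value` (from [stats::cor.test()]).
#' @export
accuracy_time_correlation <- function(accuracies, times_s) {
  ct <- stats::cor.test(accuracies, times_s, method = "spearman",
                        exact = FALSE)
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Write a summary table of significant decoding results
#'
#' One row per classifier with its best accuracy, window-onset time and the
#' associated corrected p-value — the layout used to summarise significant
#' dynamic classifications.
#'
#' @param dynres a `dynamic_result`.
#' @param path output CSV path.
#' @param group,feature optional annotation columns echoed in every row.
#' @export
write_dynamic_summary_csv <- function(dynres, path, group = NA_character_,
                                      feature = NA_character_) {
  stopifnot(inherits(dynres, "dynamic_result"))
  rows <- lapply(names(dynres$classifiers), function(cl) {
    r <- dynres$classifiers[[cl]]
    bp <- r$best_point
    data.table::data.table(
      classifier = cl,
      accuracy = if (is.null(bp)) NA_real_ else bp$accuracy,
      time_s = if (is.null(bp)) NA_real_ else bp$time_s,
      p_corrected = if (is.null(bp)) NA_real_ else
        r$p_corrected[bp$segment_index],
      group = group, feature = feature)
  })
  data.table::fwrite(data.table::rbindlist(rows), path)
  invisible(path)
}
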