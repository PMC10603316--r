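#' End-to-end run configuration
#'
#' Bundles every tunable of a decoding run. The defaults reproduce the
#' reference analysis configuration: all four classifiers, 10 repetitions of
#' stratified 10-fold cross-validation with in-fold selection at a 90%
#' cumulative-r-squared threshold, significance level 0.05, half-open
#' theta/alpha/beta bands.
#'
#' @param mode `"static"` (one feature vector per epoch) or `"dynamic"`
#'   (one per sliding 500 ms segment).
#' @param feature_kind `"spectral"` (band ratios) or `"temporal"` (decimated
#'   slow-wave traces).
#' @param classifiers character subset of `c("LDA","SVM","KNN","RANDOM")`;
#'   `RANDOM` is required as the statistical benchmark.
#' @param bands a [band_definition()].
#' @param n_folds,n_repeats cross-validation scheme.
#' @param selection_threshold cumulative score threshold (default 0.90).
#' @param alpha significance level (default 0.05).
#' @param seed integer; drives fold shuffling and the benchmark.
#' @param out_dir optional directory; when set, [run_pipeline()] writes
#'   result CSVs there.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("static", "dynamic"),
                       feature_kind = c("spectral", "temporal"),
                       classifiers = c("LDA", "SVM", "KNN", "RANDOM"),
                       bands = band_definition(),
                       n_folds = 10L, n_repeats = 10L,
                       selection_threshold = 0.90, alpha = 0.05,
                       seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  feature_kind <- match.arg(feature_kind)
  bad <- setdiff(classifiers, c("LDA", "SVM", "KNN", "RANDOM"))
  if (length(bad)) stop("unknown classifier(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!"RANDOM" %in% classifiers) {
    stop("`classifiers` must include RANDOM (the statistical benchmark)",
         call. = FALSE)
  }
  structure(
    list(mode = mode, feature_kind = feature_kind, classifiers = classifiers,
         bands = bands, n_folds = as.integer(n_folds),
         n_repeats = as.integer(n_repeats),
         selection_threshold = selection_threshold, alpha = alpha,
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML key-value file
#'
#' Recognised keys mirror the [run_config()] arguments (band edges as
#' `theta`, `alpha_band`, `beta` three two-element lists under `bands`).
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$bands)) {
    raw$bands <- do.call(band_definition, raw$bands)
  }
  do.call(run_config, raw)
}

#' Run the full decoding pipeline on an epoch set
#'
#' Orchestrates feature extraction, whole-data feature scoring (for the
#' scalp map), repeated cross-validated classification with in-fold
#' selection, and the statistical comparison against the RANDOM benchmark —
#' segment-wise with Holm correction and best-point detection in dynamic
#' mode. When `config$out_dir` is set, results are written as CSVs
#' (`selection.csv`, `cv.csv` / `dynamic_cv.csv`, `summary.csv`) along with
#' a `run_log.txt` recording every convention-dependent setting.
#'
#' @param config a [run_config()].
#' @param epochs an [epoch_set()] with binary labels.
#' @return A list: `features` (or first segment thereof), `selection`
#'   (whole-data [select_features()] result), `cv` and `tests` in static
#'   mode, `dynamic_cv` and `dynamic_stats` in dynamic mode.
#' @export
run_pipeline <- function(config, epochs) {
  stopifnot(inherits(config, "run_config"), inherits(epochs, "epoch_set"))
  specs <- default_classifier_specs()[config$classifiers]

  feats <- switch(paste(config$mode, config$feature_kind),
    "static spectral" = static_spectral_features(
      epochs, config$bands, window_len = min(250L, n_samples(epochs))),
    "static temporal" = static_temporal_features(epochs),
    "dynamic spectral" = dynamic_spectral_features(epochs, config$bands),
    "dynamic temporal" = dynamic_temporal_features(epochs))

  out <- list(config = config)
  if (config$mode == "static") {
    out$features <- feats
    out$selection <- select_features(feats, config$selection_threshold)
    out$cv <- repeated_cv(feats, specs, config$n_folds, config$n_repeats,
                          config$selection_threshold, config$seed)
    out$tests <- benchmark_tests(out$cv, config$alpha)
  } else {
    out$features <- feats[[1L]]
    out$selection <- select_features(feats[[1L]], config$selection_threshold)
    out$dynamic_cv <- dynamic_repeated_cv(feats, specs, config$n_folds,
                                          config$n_repeats,
                                          config$selection_threshold,
                                          config$seed)
    out$dynamic_stats <- dynamic_benchmark_stats(out$dynamic_cv,
                                                 config$alpha)
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$out_dir, f)
    write_selection_csv(out$selection, out$features, p("selection.csv"))
    if (config$mode == "static") {
      write_cv_csv(out$cv, p("cv.csv"))
      tests <- out$tests
      data.table::fwrite(data.table::data.table(
        classifier = names(tests),
        mean_accuracy = vapply(names(tests), function(cl)
          mean(out$cv$mean_accuracy[, cl]), numeric(1L)),
        t_stat = vapply(tests, function(t) t$t_stat, numeric(1L)),
        df = vapply(tests, function(t) t$df, numeric(1L)),
        p_value = vapply(tests, function(t) t$p_raw, numeric(1L))),
        p("summary.csv"))
    } else {
      write_cv_csv(out$dynamic_cv, p("dynamic_cv.csv"))
      write_dynamic_summary_csv(out$dynamic_stats, p("summary.csv"),
                                feature = config$feature_kind)
    }
    writeLines(c(
      sprintf("mode=%s feature=%s", config$mode, config$feature_kind),
      sprintf("classifiers=%s", paste(config$classifiers, collapse = ",")),
      sprintf("cv=%dx%d-fold seed=%d", config$n_repeats, config$n_folds,
              config$seed),
      sprintf("selection_threshold=%g alpha=%g",
              config$selection_threshold, config$alpha),
      sprintf("band_edges=%s log_base=natural theta_beta=as-printed",
              config$bands$edge_convention),
      "svm: C=1 RBF gamma=1/(d*var) | knn: k=1 Euclidean, lowest-index ties",
      "lda: pseudo-inverse pooled covariance, empirical priors",
      "zscore: n-1 denominator | welch: one-sided density scaling"),
      p("run_log.txt"))
  }
  out
}
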