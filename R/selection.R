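#' Squared point-biserial correlation of features with a binary label
#'
#' The discriminability score used for feature reduction: the squared
#' Pearson correlation between a feature and the 0/1 label vector (for a
#' genuinely dichotomous label, Pearson on 0/1 is the point-biserial
#' coefficient; no latent-normal correction is applied). Values lie in
#' `[0, 1]`.
#'
#' @param feature numeric vector (one value per instance), or a numeric
#'   matrix / [feature_matrix()] to score every column at once.
#' @param labels binary 0/1 vector; both classes must be present. Taken from
#'   the object when `feature` is a `feature_matrix`.
#' @return Numeric scalar (vector input) or vector of per-feature scores.
#' @examples
#' point_biserial_r2(c(1, 2, 3, 4), c(0, 0, 1, 1))  # 0.8
#' @export
point_biserial_r2 <- function(feature, labels = NULL) {
  if (inherits(feature, "feature_matrix")) {
    labels <- feature$labels
    feature <- feature$values
  }
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to score features", call. = FALSE)
  }
  score_matrix <- function(m) {
    sds <- apply(m, 2L, stats::sd)
    if (any(sds == 0)) {
      stop("constant feature (column ", which(sds == 0)[1L],
           "): correlation undefined", call. = FALSE)
    }
    as.numeric(stats::cor(m, labels))^2
  }
  if (is.matrix(feature)) score_matrix(feature)
  else score_matrix(matrix(as.numeric(feature), ncol = 1L))
}

#' Select features by cumulative score threshold
#'
#' Sorts features by descending score (stable: ties keep ascending original
#' index) and keeps the smallest prefix whose score sum reaches
#' `threshold_frac` of the total score.
#'
#' @param r2 non-negative per-feature scores, at least one positive.
#' @param threshold_frac fraction of the total score to retain
#'   (default 0.90).
#' @return Integer vector of selected feature indices in descending-score
#'   order.
#' @export
select_by_cumulative_score <- function(r2, threshold_frac = 0.90) {
  if (any(r2 < 0)) stop("scores must be non-negative", call. = FALSE)
  total <- sum(r2)
  if (total == 0) stop("all feature scores are zero", call. = FALSE)
  ord <- order(-r2, seq_along(r2))
  cum <- cumsum(r2[ord])
  k <- which(cum >= threshold_frac * total - 1e-12)[1L]
  ord[seq_len(k)]
}

#' Per-channel scalp scores
#'
#' Aggregates per-feature discriminability onto channels for topographic
#' display: each channel's score is the mean of its features' r-squared
#' values (2 per channel for spectral features, 20 for temporal), and the
#' channel vector is normalised to sum to 100 (percent of total score).
#'
#' @param r2 per-feature scores.
#' @param channel_map integer vector, one channel index per feature (as in
#'   [feature_matrix()]).
#' @return Numeric vector of per-channel percentages (sums to 100), named by
#'   channel index.
#' @export
channel_scalp_scores <- function(r2, channel_map) {
  if (length(r2) != length(channel_map) || anyNA(channel_map)) {
    stop("every feature must be mapped to a channel", call. = FALSE)
  }
  means <- tapply(r2, factor(channel_map, levels = sort(unique(channel_map))),
                  mean)
  pct <- 100 * means / sum(means)
  stats::setNames(as.numeric(pct), names(means))
}

#' Score, select and aggregate features in one step
#'
#' Convenience wrapper producing the full selection result for a feature
#' matrix: per-feature r-squared, the cumulative-threshold selection, and
#' per-channel percentage scores.
#'
#' @param features a [feature_matrix()].
#' @param threshold_frac cumulative score threshold (default 0.90).
#' @return An object of class `selection_result`: list with `r2`,
#'   `selected`, `threshold_frac`, `channel_percent`.
#' @export
select_features <- function(features, threshold_frac = 0.90) {
  stopifnot(inherits(features, "feature_matrix"))
  r2 <- point_biserial_r2(features)
  structure(
    list(r2 = r2,
         selected = select_by_cumulative_score(r2, threshold_frac),
         threshold_frac = threshold_frac,
         channel_percent = channel_scalp_scores(r2, features$channel_map)),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> %d/%d features kept (threshold %.0f%% of total r2)\n",
    length(x$selected), length(x$r2), 100 * x$threshold_frac))
  invisible(x)
}

#' Write a selection result as CSV
#'
#' Per-feature table (feature index, channel, r2, selected flag) suitable
#' for plotting; the per-channel percentage table is written alongside with
#' suffix `_channels.csv`.
#'
#' @param sel a `selection_result`.
#' @param features the [feature_matrix()] it was computed from.
#' @param path output CSV path.
#' @export
write_selection_csv <- function(sel, features, path) {
  stopifnot(inherits(sel, "selection_result"))
  dt <- data.table::data.table(
    feature = seq_along(sel$r2),
    channel = features$channel_ids[features$channel_map],
    r2 = sel$r2,
    selected = seq_along(sel$r2) %in% sel$selected)
  data.table::fwrite(dt, path)
  chan <- data.table::data.table(
    channel = features$channel_ids[as.integer(names(sel$channel_percent))],
    percent = as.numeric(sel$channel_percent))
  data.table::fwrite(chan, sub("\\.csv$", "_channels.csv", path))
  invisible(path)
}
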