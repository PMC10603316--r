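#' Labelled epoched EEG container
#'
#' An `epoch_set` holds epoched multichannel EEG as a numeric array of
#' dimension `n_epochs x n_channels x n_samples`, together with the sampling
#' rate, a binary arousal label per epoch (high = 1, low = 0) and ordered
#' channel identifiers. It is the universal input of the pipeline: every
#' signal-conditioning and feature-extraction function consumes one.
#'
#' @param data numeric array `[n_epochs, n_channels, n_samples]` in microvolts
#'   (or z-units downstream of normalisation).
#' @param fs sampling rate in Hz (positive scalar).
#' @param labels integer/numeric vector of 0/1 labels, one per epoch.
#' @param channel_ids optional character vector of channel identifiers;
#'   defaults to `"ch1" ... "chN"`.
#' @return An object of class `epoch_set`.
#' @examples
#' x <- epoch_set(array(rnorm(2 * 3 * 10), c(2, 3, 10)), fs = 10,
#'                labels = c(0, 1))
#' n_epochs(x)
#' @export
epoch_set <- function(data, fs, labels, channel_ids = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-d array [epochs x channels x samples]",
         call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive scalar (Hz)", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (length(labels) != dim(data)[1L]) {
    stop("`labels` must have one entry per epoch", call. = FALSE)
  }
  if (!all(labels %in% c(0L, 1L))) {
    stop("`labels` must be binary (0 = low arousal, 1 = high arousal)",
         call. = FALSE)
  }
  if (is.null(channel_ids)) {
    channel_ids <- paste0("ch", seq_len(dim(data)[2L]))
  }
  if (length(channel_ids) != dim(data)[2L]) {
    stop("`channel_ids` must have one entry per channel", call. = FALSE)
  }
  structure(
    list(data = data, fs = fs, labels = labels,
         channel_ids = as.character(channel_ids)),
    class = "epoch_set"
  )
}

#' @rdname epoch_set
#' @param x an `epoch_set`.
#' @export
n_epochs <- function(x) dim(x$data)[1L]

#' @rdname epoch_set
#' @export
n_channels <- function(x) dim(x$data)[2L]

#' @rdname epoch_set
#' @export
n_samples <- function(x) dim(x$data)[3L]

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d epochs x %d channels x %d samples @ %g Hz (%d high / %d low)\n",
    n_epochs(x), n_channels(x), n_samples(x), x$fs,
    sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' Extract a contiguous sample window from every epoch
#'
#' @param x an `epoch_set`.
#' @param samples integer vector of (1-based) sample indices to keep.
#' @return An `epoch_set` restricted to those samples.
#' @keywords internal
subset_samples <- function(x, samples) {
  if (any(samples < 1L) || any(samples > n_samples(x))) {
    stop("sample window outside epoch bounds", call. = FALSE)
  }
  epoch_set(x$data[, , samples, drop = FALSE], x$fs, x$labels, x$channel_ids)
}
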