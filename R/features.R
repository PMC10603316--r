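#' EEG frequency band definition
#'
#' Theta, alpha and beta band edges in Hz for the band-power totals. The
#' defaults are theta 4-6 Hz, alpha 6-13 Hz, beta 13-30 Hz. Adjacent bands
#' share an edge, so by default intervals are half-open `[low, high)` —
#' otherwise the 6 Hz and 13 Hz bins would be counted in two bands; a
#' closed-interval convention is available as a switch.
#'
#' @param theta,alpha,beta numeric length-2 vectors `c(low, high)` in Hz.
#' @param edge_convention `"half_open"` (default) or `"closed"`.
#' @return An object of class `band_definition`.
#' @export
band_definition <- function(theta = c(4, 6), alpha = c(6, 13),
                            beta = c(13, 30),
                            edge_convention = c("half_open", "closed")) {
  edge_convention <- match.arg(edge_convention)
  for (b in list(theta = theta, alpha = alpha, beta = beta)) {
    if (length(b) != 2L || b[1L] >= b[2L]) {
      stop("each band must be c(low, high) with low < high", call. = FALSE)
    }
  }
  if (edge_convention == "half_open" &&
      (theta[2L] > alpha[1L] || alpha[2L] > beta[1L])) {
    stop("bands must be ordered and non-overlapping", call. = FALSE)
  }
  structure(list(theta = theta, alpha = alpha, beta = beta,
                 edge_convention = edge_convention),
            class = "band_definition")
}

#' Band totals of a log-transformed power spectrum
#'
#' Sums the natural-log-transformed PSD bins falling in the theta, alpha and
#' beta bands. The log transform compensates the skewness of raw power
#' values; the totals feed the beta/alpha (emotional arousal) and theta/beta
#' (cognitive arousal) ratios.
#'
#' @param psd a `psd` object from [welch_psd()].
#' @param bands a [band_definition()].
#' @return Named numeric vector `c(theta, alpha, beta)` of log-power sums.
#' @export
band_totals <- function(psd, bands = band_definition()) {
  stopifnot(inherits(psd, "psd"), inherits(bands, "band_definition"))
  in_band <- function(edges) {
    if (bands$edge_convention == "half_open") {
      psd$freqs >= edges[1L] & psd$freqs < edges[2L]
    } else {
      psd$freqs >= edges[1L] & psd$freqs <= edges[2L]
    }
  }
  one <- function(edges) {
    v <- psd$values[in_band(edges)]
    if (length(v) == 0L) {
      stop("no PSD bins fall in band [", edges[1L], ", ", edges[2L], ") Hz",
           call. = FALSE)
    }
    if (any(v <= 0)) {
      stop("non-positive PSD bin in band [", edges[1L], ", ", edges[2L],
           ") Hz: log-power undefined", call. = FALSE)
    }
    sum(log(v))
  }
  c(theta = one(bands$theta), alpha = one(bands$alpha), beta = one(bands$beta))
}

#' Feature matrix container
#'
#' Instances x features with labels, a feature-to-channel index map (needed
#' for per-channel scalp aggregation) and the feature kind. Dynamic features
#' additionally carry their segment index and window-onset time.
#'
#' @param values numeric matrix `[n_instances x n_features]`.
#' @param labels binary labels, one per instance.
#' @param channel_map integer vector, one channel index per feature.
#' @param kind `"spectral"` or `"temporal"`.
#' @param channel_ids channel identifiers the map indexes into.
#' @param segment_index,time_s optional segment position (dynamic features).
#' @param metadata list of extraction settings, echoed for provenance.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels, channel_map, kind, channel_ids,
                           segment_index = NULL, time_s = NULL,
                           metadata = list()) {
  values <- as.matrix(values)
  if (length(channel_map) != ncol(values)) {
    stop("`channel_map` must map every feature to exactly one channel",
         call. = FALSE)
  }
  labels <- as.integer(labels)
  if (length(labels) != nrow(values) || !all(labels %in% c(0L, 1L))) {
    stop("`labels` must be binary, one per instance", call. = FALSE)
  }
  structure(
    list(values = values, labels = labels,
         channel_map = as.integer(channel_map), kind = kind,
         channel_ids = channel_ids,
         segment_index = segment_index, time_s = time_s,
         metadata = metadata),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d instances x %d %s features%s\n",
              nrow(x$values), ncol(x$values), x$kind,
              if (is.null(x$segment_index)) "" else
                sprintf(" (segment %d, t = %.3f s)",
                        x$segment_index, x$time_s)))
  invisible(x)
}

#' Static spectral features: band-power ratios per channel
#'
#' Per epoch and channel, estimates the PSD by Welch's periodogram
#' (Hamming windows, 50% overlap), forms log-power band totals, and emits
#' the pair `beta/alpha` (emotional arousal) and `theta/beta` (cognitive
#' arousal). Feature vectors concatenate the two ratios channel by channel,
#' giving `2 x n_channels` features (256 at 128 channels).
#'
#' @param epochs an [epoch_set()].
#' @param bands a [band_definition()].
#' @param window_len,nfft,overlap_frac Welch settings; defaults are the
#'   whole-epoch configuration (250-point window, no zero padding).
#' @param invert_theta_beta if `TRUE`, emit `beta/theta` instead of
#'   `theta/beta` as the second ratio.
#' @return A [feature_matrix()] of kind `"spectral"`.
#' @export
static_spectral_features <- function(epochs, bands = band_definition(),
                                     window_len = 250L, nfft = window_len,
                                     overlap_frac = 0.5,
                                     invert_theta_beta = FALSE) {
  stopifnot(inherits(epochs, "epoch_set"))
  ne <- n_epochs(epochs); nc <- n_channels(epochs)
  out <- matrix(NA_real_, ne, 2L * nc)
  for (e in seq_len(ne)) {
    for (ch in seq_len(nc)) {
      psd <- welch_psd(epochs$data[e, ch, ], epochs$fs,
                       window_len = window_len, nfft = nfft,
                       overlap_frac = overlap_frac)
      tot <- band_totals(psd, bands)
      if (tot[["alpha"]] == 0 || tot[["beta"]] == 0) {
        stop("zero band total (epoch ", e, ", channel ",
             epochs$channel_ids[ch], "): ratio undefined", call. = FALSE)
      }
      r2 <- if (invert_theta_beta) tot[["beta"]] / tot[["theta"]]
            else tot[["theta"]] / tot[["beta"]]
      out[e, c(2L * ch - 1L, 2L * ch)] <-
        c(tot[["beta"]] / tot[["alpha"]], r2)
    }
  }
  feature_matrix(out, epochs$labels, rep(seq_len(nc), each = 2L),
                 kind = "spectral", channel_ids = epochs$channel_ids,
                 metadata = list(window_len = window_len, nfft = nfft,
                                 overlap_frac = overlap_frac,
                                 log_base = "natural",
                                 edge_convention = bands$edge_convention,
                                 invert_theta_beta = invert_theta_beta))
}

# Band-pass the whole epoch set along time: returns array of same shape.
filter_epoch_array <- function(epochs, low, high, order) {
  out <- epochs$data
  for (e in seq_len(n_epochs(epochs))) {
    for (ch in seq_len(n_channels(epochs))) {
      out[e, ch, ] <- bandpass_butter_zerophase(epochs$data[e, ch, ],
                                                epochs$fs, low, high, order)
    }
  }
  out
}

# Linear interpolation of a [epochs x channels x samples] array at
# fractional 0-based sample positions; returns [epochs x channels x k].
interp_array <- function(arr, pos0) {
  ns <- dim(arr)[3L]
  i0 <- pmin(floor(pos0), ns - 2)      # 0-based left neighbour
  w <- pos0 - i0
  out <- array(NA_real_, c(dim(arr)[1L], dim(arr)[2L], length(pos0)))
  for (k in seq_along(pos0)) {
    out[, , k] <- arr[, , i0[k] + 1L] * (1 - w[k]) + arr[, , i0[k] + 2L] * w[k]
  }
  out
}

# z-score each epoch x channel block of a [epochs x channels x k] array
# along its k time points (sample sd, n - 1 denominator).
zscore_blocks <- function(arr, channel_ids) {
  k <- dim(arr)[3L]
  m <- apply(arr, c(1L, 2L), mean)
  s <- apply(arr, c(1L, 2L), stats::sd)
  if (any(s == 0)) {
    bad <- which(s == 0, arr.ind = TRUE)[1L, ]
    stop("flat channel ", channel_ids[bad[2L]], " in epoch ", bad[1L],
         ": temporal standard deviation is zero", call. = FALSE)
  }
  for (j in seq_len(k)) arr[, , j] <- (arr[, , j] - m) / s
  arr
}

# Flatten [epochs x channels x k] channel-major into [epochs x (channels*k)]:
# all k time points of channel 1, then channel 2, ...
flatten_channel_major <- function(arr) {
  ne <- dim(arr)[1L]; nc <- dim(arr)[2L]; k <- dim(arr)[3L]
  out <- matrix(NA_real_, ne, nc * k)
  for (ch in seq_len(nc)) {
    out[, (ch - 1L) * k + seq_len(k)] <- arr[, ch, ]
  }
  out
}

#' Static temporal features: filtered, decimated, z-scored traces
#'
#' The slow-wave (CNV-like) feature family: each channel is band-pass
#' filtered 0.05-10 Hz with a zero-phase 2nd-order Butterworth filter,
#' decimated to 20 Hz, and z-scored with its own temporal mean and standard
#' deviation. The per-channel blocks are concatenated, giving
#' `n_points x n_channels` features: 20 points per channel for a 1000 ms
#' epoch, hence 2560 features at 128 channels. The 0.05-10 Hz band-pass
#' doubles as the anti-alias filter (its upper edge is the 20 Hz output
#' Nyquist), so decimation interpolates the filtered trace directly.
#'
#' @param epochs an [epoch_set()].
#' @param low,high,order band-pass settings (defaults 0.05-10 Hz, order 2).
#' @param fs_out decimation target rate, Hz (default 20).
#' @return A [feature_matrix()] of kind `"temporal"`.
#' @export
static_temporal_features <- function(epochs, low = 0.05, high = 10,
                                     order = 2L, fs_out = 20) {
  stopifnot(inherits(epochs, "epoch_set"))
  filt <- filter_epoch_array(epochs, low, high, order)
  n_out <- floor(n_samples(epochs) * fs_out / epochs$fs)
  pos0 <- (seq_len(n_out) - 1) * epochs$fs / fs_out
  dec <- interp_array(filt, pos0)
  z <- zscore_blocks(dec, epochs$channel_ids)
  feature_matrix(flatten_channel_major(z), epochs$labels,
                 rep(seq_len(n_channels(epochs)), each = n_out),
                 kind = "temporal", channel_ids = epochs$channel_ids,
                 metadata = list(band = c(low, high), order = order,
                                 fs_out = fs_out, sd_denominator = "n-1"))
}

#' Partition epochs into sliding temporal segments
#'
#' Returns stride-`shift_samples` views of the epoch set, each
#' `window_ms` long. The window onset time (the segment's left extreme,
#' `(i-1)/fs` seconds for segment `i`) indexes the dynamic accuracy
#' sequences. A 1000 ms epoch at 250 Hz with a 500 ms window and one-sample
#' shift yields 125 segments with onsets 0 to 0.496 s; the last formally
#' admissible window is dropped to realise that count.
#'
#' @param epochs an [epoch_set()].
#' @param window_ms segment duration, ms (default 500).
#' @param shift_samples stride between consecutive segments (default 1).
#' @return List of `epoch_set` objects, each with attributes `time_s` and
#'   `segment_index`.
#' @export
segment_epoch <- function(epochs, window_ms = 500, shift_samples = 1L) {
  stopifnot(inherits(epochs, "epoch_set"))
  wl <- as.integer(round(window_ms / 1000 * epochs$fs))
  ns <- n_samples(epochs)
  if (wl > ns) {
    stop("segment window (", wl, " samples) longer than epoch (", ns, ")",
         call. = FALSE)
  }
  starts0 <- seq.int(0L, ns - wl, by = as.integer(shift_samples))
  if (length(starts0) > 1L) starts0 <- starts0[-length(starts0)]
  lapply(seq_along(starts0), function(i) {
    seg <- subset_samples(epochs, starts0[i] + seq_len(wl))
    attr(seg, "time_s") <- starts0[i] / epochs$fs
    attr(seg, "segment_index") <- i
    attr(seg, "start_sample0") <- starts0[i]
    seg
  })
}

#' Dynamic spectral features: band-ratio features per sliding segment
#'
#' [static_spectral_features()] applied to each 500 ms sliding segment, with
#' the short-window Welch configuration: a 16-point Hamming window
#' zero-padded to 250 FFT points (so the 1 Hz bin grid of the static variant
#' is preserved), 50% overlap. Feature dimensionality per segment equals the
#' static one (`2 x n_channels`).
#'
#' @inheritParams static_spectral_features
#' @param window_ms,shift_samples segmentation settings, see
#'   [segment_epoch()].
#' @return List of [feature_matrix()] objects, one per segment.
#' @export
dynamic_spectral_features <- function(epochs, bands = band_definition(),
                                      window_len = 16L, nfft = 250L,
                                      overlap_frac = 0.5,
                                      window_ms = 500, shift_samples = 1L,
                                      invert_theta_beta = FALSE) {
  segs <- segment_epoch(epochs, window_ms, shift_samples)
  lapply(segs, function(seg) {
    fm <- static_spectral_features(seg, bands, window_len = window_len,
                                   nfft = nfft, overlap_frac = overlap_frac,
                                   invert_theta_beta = invert_theta_beta)
    fm$segment_index <- attr(seg, "segment_index")
    fm$time_s <- attr(seg, "time_s")
    fm
  })
}

#' Dynamic temporal features: decimated traces per sliding segment
#'
#' The temporal pipeline applied per 500 ms sliding segment: the epoch is
#' band-pass filtered once at the full rate (avoiding filter transients on
#' 125-sample segments), then each segment is decimated to 20 Hz — 10 points
#' per channel, hence 1280 features per segment at 128 channels — and
#' z-scored per channel within the segment.
#'
#' @inheritParams static_temporal_features
#' @param window_ms,shift_samples segmentation settings.
#' @return List of [feature_matrix()] objects, one per segment.
#' @export
dynamic_temporal_features <- function(epochs, low = 0.05, high = 10,
                                      order = 2L, fs_out = 20,
                                      window_ms = 500, shift_samples = 1L) {
  stopifnot(inherits(epochs, "epoch_set"))
  filt <- filter_epoch_array(epochs, low, high, order)
  wl <- as.integer(round(window_ms / 1000 * epochs$fs))
  ns <- n_samples(epochs)
  if (wl > ns) stop("segment window longer than epoch", call. = FALSE)
  starts0 <- seq.int(0L, ns - wl, by = as.integer(shift_samples))
  if (length(starts0) > 1L) starts0 <- starts0[-length(starts0)]
  n_out <- floor(wl * fs_out / epochs$fs)
  rel_pos0 <- (seq_len(n_out) - 1) * epochs$fs / fs_out
  nc <- n_channels(epochs)
  lapply(seq_along(starts0), function(i) {
    dec <- interp_array(filt, starts0[i] + rel_pos0)
    z <- zscore_blocks(dec, epochs$channel_ids)
    feature_matrix(flatten_channel_major(z), epochs$labels,
                   rep(seq_len(nc), each = n_out),
                   kind = "temporal", channel_ids = epochs$channel_ids,
                   segment_index = i, time_s = starts0[i] / epochs$fs,
                   metadata = list(band = c(low, high), order = order,
                                   fs_out = fs_out, window_ms = window_ms))
  })
}
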