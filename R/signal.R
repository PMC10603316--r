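#' Signal-conditioning primitives
#'
#' Deterministic building blocks used by the preprocessing and
#' feature-extraction stages: zero-phase IIR band-pass filtering, linear-phase
#' FIR band-pass filtering, common average re-referencing, baseline
#' correction, decimation and Welch's averaged periodogram.
#'
#' @name signal-primitives
NULL

# Steady-state initial filter state for a unit-step input (the classic
# lfilter_zi construction): solving (I - A') zi = B for the companion-form
# state matrix makes the filter start in equilibrium, which matters here
# because the 0.05 Hz high-pass edge would otherwise ring for seconds.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b))) / a[1L]
  a <- c(a, numeric(n - length(a))) / a[1L]
  if (n == 1L) return(numeric(0))
  comp_t <- cbind(-a[2:n], rbind(diag(1, n - 2L), 0))  # companion transposed
  B <- b[2:n] - a[2:n] * b[1L]
  solve(diag(1, n - 1L) - comp_t, B)
}

# Direct-form-II-transposed filtering with an explicit initial state.
df2t_filter <- function(b, a, x, zi) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b))) / a[1L]
  a <- c(a, numeric(n - length(a))) / a[1L]
  z <- c(zi, 0)
  bt <- b[-1L]; at <- a[-1L]
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    yi <- b[1L] * x[i] + z[1L]
    z <- c(bt * x[i] + z[-1L] - at * yi, 0)
    y[i] <- yi
  }
  y
}

# Forward-backward filtering with odd reflection padding at both ends
# (padding length 3 x filter order) and steady-state initial conditions, so
# the effective magnitude response is |H|^2, the phase response is zero, and
# edge transients are suppressed even for very low cutoff frequencies.
zerophase_filter <- function(b, a, x) {
  b <- as.numeric(b); a <- as.numeric(a)
  n <- length(x)
  p <- 3L * (max(length(a), length(b)) - 1L)
  if (p >= n) {
    stop("series too short for the filter's warm-up (need > ", p, " samples)",
         call. = FALSE)
  }
  zi <- lfilter_zi(b, a)
  pre  <- 2 * x[1L] - x[(p + 1L):2L]
  post <- 2 * x[n]  - x[(n - 1L):(n - p)]
  v <- c(pre, x, post)
  y <- df2t_filter(b, a, v, zi * v[1L])
  y <- rev(y)
  y <- rev(df2t_filter(b, a, y, zi * y[1L]))
  y[(p + 1L):(p + n)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass filter forward and backward (reflection
#' padding at the edges), giving zero phase shift and the squared magnitude
#' response of the underlying filter. The defaults are the slow-wave band
#' used ahead of temporal feature extraction.
#'
#' @param x single-channel numeric series.
#' @param fs sampling rate, Hz.
#' @param low,high band edges in Hz; `0 <= low < high < fs/2`.
#' @param order Butterworth order per band edge (default 2).
#' @return Filtered series of the same length as `x`.
#' @export
bandpass_butter_zerophase <- function(x, fs, low = 0.05, high = 10,
                                      order = 2L) {
  stopifnot_scalar(fs, "fs")
  if (!(low >= 0 && low < high && high < fs / 2)) {
    stop("band [", low, ", ", high, "] Hz must satisfy 0 <= low < high < fs/2",
         call. = FALSE)
  }
  bt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  zerophase_filter(bt$b, bt$a, x)
}

#' Linear-phase FIR band-pass filter (Hamming-windowed sinc)
#'
#' Designs a Hamming-windowed sinc band-pass FIR filter and applies it with
#' group-delay compensation (`order/2` samples), so the output is aligned
#' with the input. Intended for continuous raw recordings before epoching;
#' the synthetic pipeline, which starts from epoched data, does not use it
#' by default.
#'
#' @inheritParams bandpass_butter_zerophase
#' @param order FIR order; must be even and shorter than the series.
#' @return Filtered series of the same length as `x`.
#' @export
fir_bandpass <- function(x, fs, low = 0.1, high = 45, order = 16500L) {
  stopifnot_scalar(fs, "fs")
  order <- as.integer(order)
  if (order %% 2L != 0L) stop("`order` must be even", call. = FALSE)
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("band [", low, ", ", high, "] Hz must lie inside (0, fs/2)",
         call. = FALSE)
  }
  n <- length(x)
  if (n <= order) {
    stop("series (", n, " samples) shorter than FIR order ", order,
         call. = FALSE)
  }
  b <- as.numeric(signal::fir1(order, c(low, high) / (fs / 2), type = "pass",
                               window = signal::hamming(order + 1L)))
  half <- order %/% 2L
  y <- as.numeric(signal::filter(b, 1, c(x, numeric(half))))
  y[(half + 1L):(half + n)]
}

#' Common average reference
#'
#' Re-references every channel to the instantaneous mean across channels, so
#' that at every time point the channel mean is zero. Idempotent and linear.
#'
#' @param epochs an [epoch_set()].
#' @return The re-referenced `epoch_set`.
#' @export
common_average_reference <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (n_channels(epochs) < 2L) {
    stop("common average reference needs at least 2 channels", call. = FALSE)
  }
  m <- apply(epochs$data, c(1L, 3L), mean)     # [epochs x samples]
  out <- epochs$data
  for (ch in seq_len(n_channels(epochs))) {
    out[, ch, ] <- out[, ch, ] - m
  }
  epoch_set(out, epochs$fs, epochs$labels, epochs$channel_ids)
}

#' Baseline correction
#'
#' Subtracts, per epoch and channel, the mean amplitude over a baseline
#' sample window from the whole trace.
#'
#' @param epochs an [epoch_set()].
#' @param baseline_window integer vector of 1-based sample indices defining
#'   the baseline interval (e.g. `1:50` for the first 200 ms at 250 Hz).
#' @return The baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, baseline_window) {
  stopifnot(inherits(epochs, "epoch_set"))
  baseline_window <- as.integer(baseline_window)
  if (length(baseline_window) == 0L) {
    stop("empty baseline window", call. = FALSE)
  }
  if (any(baseline_window < 1L) || any(baseline_window > n_samples(epochs))) {
    stop("baseline window outside epoch bounds", call. = FALSE)
  }
  m <- apply(epochs$data[, , baseline_window, drop = FALSE], c(1L, 2L), mean)
  out <- epochs$data
  for (s in seq_len(n_samples(epochs))) {
    out[, , s] <- out[, , s] - m
  }
  epoch_set(out, epochs$fs, epochs$labels, epochs$channel_ids)
}

#' Decimate a series to a lower sampling rate
#'
#' Zero-phase anti-alias low-pass filtering (8th-order Butterworth magnitude,
#' cutoff `0.8 * fs_out/2`) followed by resampling on the output time grid
#' `k / fs_out`. Integer rate ratios reduce to classical decimation (keep
#' every q-th sample); rational ratios — such as the 250 Hz to 20 Hz step of
#' the temporal feature pipeline, which maps 1000 ms onto 20 samples — are
#' handled by interpolating the filtered, band-limited series at the output
#' instants.
#'
#' @param x single-channel numeric series.
#' @param fs_in,fs_out input and output sampling rates, Hz; `fs_out <= fs_in`.
#' @param antialias logical; set `FALSE` only when `x` is already band-limited
#'   below `fs_out/2` (e.g. after the 0.05-10 Hz band-pass).
#' @return Numeric series of `floor(n * fs_out / fs_in)` samples.
#' @export
decimate_to <- function(x, fs_in, fs_out, antialias = TRUE) {
  stopifnot_scalar(fs_in, "fs_in")
  stopifnot_scalar(fs_out, "fs_out")
  if (fs_out > fs_in) {
    stop("`fs_out` (", fs_out, ") exceeds `fs_in` (", fs_in, ")",
         call. = FALSE)
  }
  if (fs_out == fs_in) return(x)
  n <- length(x)
  n_out <- floor(n * fs_out / fs_in)
  if (n_out < 1L) stop("series too short to decimate", call. = FALSE)
  if (antialias) {
    bt <- signal::butter(4L, 0.8 * fs_out / fs_in, type = "low")
    x <- zerophase_filter(bt$b, bt$a, x)
  }
  ratio <- fs_in / fs_out
  if (abs(ratio - round(ratio)) < 1e-9) {
    x[seq(1L, by = round(ratio), length.out = n_out)]
  } else {
    t_in <- (seq_len(n) - 1) / fs_in
    t_out <- (seq_len(n_out) - 1) / fs_out
    stats::approx(t_in, x, xout = t_out)$y
  }
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram over Hamming-windowed, overlapping segments,
#' with one-sided density scaling (power divided by `fs * sum(w^2)`, doubled
#' off DC/Nyquist). The defaults match whole-epoch spectral feature
#' extraction (250-point window, 50% overlap); the sliding-window variant
#' uses a 16-point window zero-padded to `nfft = 250`.
#'
#' @param x single-channel numeric series.
#' @param fs sampling rate, Hz.
#' @param window_len Hamming window length in samples; `<= length(x)`.
#' @param nfft FFT length (zero-padding beyond `window_len`); sets the
#'   frequency resolution `fs / nfft`.
#' @param overlap_frac fractional overlap between consecutive windows,
#'   in `[0, 1)`.
#' @return An object of class `psd`: list with `freqs` (Hz, from 0 to
#'   `fs/2`), `values` (power density per bin) and `resolution` (Hz).
#' @export
welch_psd <- function(x, fs, window_len = 250L, nfft = window_len,
                      overlap_frac = 0.5) {
  stopifnot_scalar(fs, "fs")
  window_len <- as.integer(window_len)
  nfft <- as.integer(nfft)
  n <- length(x)
  if (window_len > n) {
    stop("Welch window (", window_len, ") longer than series (", n, ")",
         call. = FALSE)
  }
  if (nfft < window_len) stop("`nfft` must be >= `window_len`", call. = FALSE)
  if (overlap_frac < 0 || overlap_frac >= 1) {
    stop("`overlap_frac` must be in [0, 1)", call. = FALSE)
  }
  hop <- max(1L, window_len - as.integer(floor(overlap_frac * window_len)))
  starts <- seq.int(1L, n - window_len + 1L, by = hop)
  w <- signal::hamming(window_len)
  u <- sum(w^2)
  n_keep <- nfft %/% 2L + 1L
  acc <- numeric(n_keep)
  for (s in starts) {
    seg <- x[s:(s + window_len - 1L)] * w
    if (nfft > window_len) seg <- c(seg, numeric(nfft - window_len))
    px <- Mod(stats::fft(seg))^2 / (fs * u)
    acc <- acc + px[seq_len(n_keep)]
  }
  values <- acc / length(starts)
  # one-sided: double everything except DC and (for even nfft) Nyquist
  dbl <- rep(2, n_keep)
  dbl[1L] <- 1
  if (nfft %% 2L == 0L) dbl[n_keep] <- 1
  values <- values * dbl
  structure(
    list(freqs = (seq_len(n_keep) - 1) * fs / nfft,
         values = values,
         resolution = fs / nfft),
    class = "psd"
  )
}
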