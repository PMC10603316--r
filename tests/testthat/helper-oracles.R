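# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately written from first principles (explicit
# DFT sums, explicit sort-based step-down, explicit Pearson formula) so the
# package implementations are checked against a different code path.

# Brute-force Welch estimate: explicit complex-exponential DFT per
# Hamming-windowed segment, averaged, one-sided density scaling.
welch_oracle <- function(x, fs, window_len, nfft = window_len,
                         overlap_frac = 0.5) {
  n <- length(x)
  k <- seq_len(window_len) - 1
  w <- 0.54 - 0.46 * cos(2 * pi * k / (window_len - 1))
  hop <- max(1, window_len - floor(overlap_frac * window_len))
  starts <- seq(1, n - window_len + 1, by = hop)
  n_keep <- nfft %/% 2 + 1
  acc <- numeric(n_keep)
  for (s in starts) {
    seg <- x[s:(s + window_len - 1)] * w
    for (j in seq_len(n_keep)) {
      d <- sum(seg * exp(-2i * pi * (j - 1) * (seq_len(window_len) - 1) / nfft))
      acc[j] <- acc[j] + Mod(d)^2 / (fs * sum(w^2))
    }
  }
  v <- acc / length(starts)
  dbl <- rep(2, n_keep); dbl[1] <- 1
  if (nfft %% 2 == 0) dbl[n_keep] <- 1
  v * dbl
}

# Holm step-down written literally: ascending sort, multiply the i-th
# smallest by (m - i + 1), running maximum, cap at 1, original order.
holm_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * (m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Squared Pearson correlation from the raw moment formula.
pearson_r2_oracle <- function(x, y) {
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  (sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))^2
}

# Digital filter frequency response |H(f)| evaluated from the transfer
# function coefficients directly.
filter_gain <- function(b, a, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs * (seq_along(b) - 1))
  num <- sum(b * z)
  z <- exp(-1i * 2 * pi * f / fs * (seq_along(a) - 1))
  Mod(num / sum(a * z))
}

# Deterministic epoch set built from explicit per-channel signal functions
# (each a function of time in seconds), replicated over epochs.
signal_epochs <- function(channel_funs, fs = 250, dur_s = 1, n_epochs = 1,
                          labels = rep(0, n_epochs)) {
  t <- (seq_len(fs * dur_s) - 1) / fs
  nc <- length(channel_funs)
  data <- array(0, c(n_epochs, nc, length(t)))
  for (e in seq_len(n_epochs)) {
    for (ch in seq_len(nc)) data[e, ch, ] <- channel_funs[[ch]](t)
  }
  epoch_set(data, fs, labels)
}

# Small random epoch set for property checks.
random_epochs <- function(n_epochs = 6, n_channels = 3, n_samp = 250,
                          fs = 250, seed = 1) {
  set.seed(seed)
  epoch_set(array(rnorm(n_epochs * n_channels * n_samp),
                  c(n_epochs, n_channels, n_samp)),
            fs, rep_len(c(0, 1), n_epochs))
}

# Amplitude of an oscillation in the interior of a series (excludes edge
# transients), measured as max |value| over the central half.
interior_amplitude <- function(x) {
  n <- length(x)
  max(abs(x[(n %/% 4):(3 * n %/% 4)]))
}
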