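#' Configuration for the synthetic EEG generator
#'
#' Describes a two-class epoched EEG dataset with the statistical structure
#' the analysis pipeline assumes: a 1/f-coloured noise background, additive
#' narrow-band oscillators with random phase per epoch, and two optional
#' class effects carried only by "high arousal" epochs — a beta-band
#' amplitude multiplier on a channel subset (spectral effect) and a slow
#' negative ramp emulating anticipatory CNV-like activity (temporal effect).
#' Channel topography is abstract: "central-parietal" is whatever channel
#' subset you configure.
#'
#' @param n_epochs_per_class epochs per class before imbalance adjustment.
#' @param n_channels number of channels (default 128, a high-density net).
#' @param fs sampling rate, Hz (default 250).
#' @param epoch_ms epoch duration, ms (default 1000, a pre-stimulus ISI);
#'   `fs * epoch_ms / 1000` must be an integer number of samples.
#' @param noise_exponent spectral slope of the background: power falls as
#'   `1/f^noise_exponent` (default 1).
#' @param noise_sd background noise standard deviation in microvolts
#'   (default 40, an EEG-like amplitude; the scale matters because the
#'   spectral features sum log-transformed power densities).
#' @param osc_components list of oscillators, each a list with `freq` (Hz),
#'   `amplitude` (microvolts), and `channels` (integer indices, `NULL` =
#'   all). Defaults: 10 Hz at 20 uV and 20 Hz at 10 uV on all channels,
#'   giving the alpha/beta band structure the spectral features read out.
#' @param spectral_effect list with `channels` (integer indices) and
#'   `multiplier`: on high-arousal epochs, beta-band oscillators (13-30 Hz)
#'   on those channels have their amplitude multiplied by `multiplier`.
#'   `multiplier = 1` disables the effect.
#' @param temporal_effect list with `channels`, `amplitude` (ramp endpoint
#'   in units of `noise_sd`, i.e. z-units of the background; negative for a
#'   CNV-like negativity), `onset_ms` and
#'   `shape` (only `"linear"`): on high-arousal epochs, a ramp rising from 0
#'   at onset to `amplitude` at epoch end is added to those channels.
#'   `amplitude = 0` disables the effect.
#' @param class_imbalance fraction of high-arousal epochs, in `[0.4, 0.6]`
#'   (the classes stay approximately balanced, default 0.5).
#' @param seed integer; all randomness flows from it, so equal configs give
#'   bit-identical epoch sets.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_epochs_per_class,
                             n_channels = 128L,
                             fs = 250,
                             epoch_ms = 1000,
                             noise_exponent = 1.0,
                             noise_sd = 40,
                             osc_components = list(
                               list(freq = 10, amplitude = 20, channels = NULL),
                               list(freq = 20, amplitude = 10, channels = NULL)),
                             spectral_effect = list(channels = integer(0),
                                                    multiplier = 1.0),
                             temporal_effect = list(channels = integer(0),
                                                    amplitude = 0,
                                                    onset_ms = 500,
                                                    shape = "linear"),
                             class_imbalance = 0.5,
                             seed = 1L) {
  n_epochs_per_class <- as.integer(n_epochs_per_class)
  n_channels <- as.integer(n_channels)
  if (is.na(n_epochs_per_class) || n_epochs_per_class < 1L) {
    stop("invalid `n_epochs_per_class`: need at least 1 epoch per class",
         call. = FALSE)
  }
  if (is.na(n_channels) || n_channels < 2L) {
    stop("invalid `n_channels`: need at least 2 channels", call. = FALSE)
  }
  stopifnot_scalar(fs, "fs")
  stopifnot_scalar(epoch_ms, "epoch_ms")
  n_samp <- fs * epoch_ms / 1000
  if (abs(n_samp - round(n_samp)) > 1e-9) {
    stop("invalid `fs`/`epoch_ms`: fs * epoch_ms / 1000 = ", n_samp,
         " is not an integer number of samples", call. = FALSE)
  }
  if (class_imbalance < 0.4 || class_imbalance > 0.6) {
    stop("invalid `class_imbalance`: ", class_imbalance,
         " outside [0.4, 0.6]", call. = FALSE)
  }
  for (comp in osc_components) {
    if (is.null(comp$freq) || is.null(comp$amplitude)) {
      stop("invalid `osc_components`: each needs `freq` and `amplitude`",
           call. = FALSE)
    }
    if (comp$freq >= fs / 2) {
      stop("invalid `osc_components`: oscillator at ", comp$freq,
           " Hz is at or above Nyquist", call. = FALSE)
    }
  }
  chk_ch <- c(spectral_effect$channels, temporal_effect$channels)
  if (length(chk_ch) && (any(chk_ch < 1L) || any(chk_ch > n_channels))) {
    stop("effect channels outside 1..n_channels", call. = FALSE)
  }
  if (!identical(temporal_effect$shape %||% "linear", "linear")) {
    stop("invalid `temporal_effect`: only shape = \"linear\" is supported",
         call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    stop("invalid `noise_sd`: must be a positive amplitude", call. = FALSE)
  }
  structure(
    list(n_epochs_per_class = n_epochs_per_class,
         n_channels = n_channels, fs = fs, epoch_ms = epoch_ms,
         noise_exponent = noise_exponent, noise_sd = noise_sd,
         osc_components = osc_components,
         spectral_effect = spectral_effect,
         temporal_effect = temporal_effect,
         class_imbalance = class_imbalance,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# White noise shaped to a 1/f^exponent power spectrum in the frequency
# domain, rescaled to unit variance.
colored_noise <- function(n, exponent) {
  white <- stats::rnorm(n)
  if (exponent == 0) return(white)
  sp <- stats::fft(white)
  f <- c(0, pmin(seq_len(n - 1L), n - seq_len(n - 1L)))  # symmetric bin freq
  scale <- c(0, f[-1L]^(-exponent / 2))
  x <- Re(stats::fft(sp * scale, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate a labelled synthetic EEG epoch set
#'
#' Draws `2 * n_epochs_per_class` epochs (split by `class_imbalance`), each
#' channel an independent 1/f-coloured noise trace plus the configured
#' oscillators (random phase per epoch and component, shared across that
#' component's channels). High-arousal epochs additionally carry the
#' configured spectral and/or temporal effects. Labels are shuffled
#' deterministically by the seed, so class and epoch order are unconfounded.
#'
#' @param config a [generator_config()].
#' @return An [epoch_set()].
#' @examples
#' cfg <- generator_config(n_epochs_per_class = 5, n_channels = 4)
#' generate_epochs(cfg)
#' @export
generate_epochs <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n_samp <- as.integer(round(config$fs * config$epoch_ms / 1000))
  total <- 2L * config$n_epochs_per_class
  n_high <- as.integer(round(total * config$class_imbalance))
  n_chan <- config$n_channels
  t_sec <- (seq_len(n_samp) - 1) / config$fs

  beta_band <- function(f) f >= 13 & f < 30
  sp_ch <- as.integer(config$spectral_effect$channels %||% integer(0))
  sp_mult <- config$spectral_effect$multiplier %||% 1.0
  te_ch <- as.integer(config$temporal_effect$channels %||% integer(0))
  te_amp <- config$temporal_effect$amplitude %||% 0
  onset_ms <- config$temporal_effect$onset_ms %||% 500
  ramp <- numeric(n_samp)
  if (te_amp != 0) {
    onset_i <- min(n_samp, max(1L, 1L + as.integer(round(
      onset_ms / 1000 * config$fs))))
    k <- onset_i:n_samp
    # amplitude is expressed in z-units of the background noise
    ramp[k] <- te_amp * config$noise_sd *
      (k - onset_i) / max(1L, n_samp - onset_i)
  }

  with_seed(config$seed, {
    labels <- sample(c(rep(1L, n_high), rep(0L, total - n_high)))
    data <- array(0, dim = c(total, n_chan, n_samp))
    for (e in seq_len(total)) {
      phases <- stats::runif(length(config$osc_components), 0, 2 * pi)
      for (ch in seq_len(n_chan)) {
        trace <- config$noise_sd * colored_noise(n_samp, config$noise_exponent)
        for (j in seq_along(config$osc_components)) {
          comp <- config$osc_components[[j]]
          comp_ch <- comp$channels %||% seq_len(n_chan)
          if (!(ch %in% comp_ch)) next
          amp <- comp$amplitude
          if (labels[e] == 1L && beta_band(comp$freq) && ch %in% sp_ch) {
            amp <- amp * sp_mult
          }
          trace <- trace + amp * sin(2 * pi * comp$freq * t_sec + phases[j])
        }
        if (labels[e] == 1L && ch %in% te_ch) trace <- trace + ramp
        data[e, ch, ] <- trace
      }
    }
    epoch_set(data, config$fs, labels)
  })
}

#' Read / write a generator configuration as a flat key-value file
#'
#' YAML serialisation of a [generator_config()]; round-trips exactly.
#'
#' @param config a `generator_config`.
#' @param path file path.
#' @return `read_generator_config` returns a `generator_config`.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(generator_config, raw)
}
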