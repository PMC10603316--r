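test_that("zero-phase Butterworth band-pass passes the band and blocks outside it", {
  # the 0.05 Hz edge rings for seconds, so gains are measured in the
  # settled central fifth of a 40 s series
  fs <- 250
  t <- (0:(40 * fs - 1)) / fs
  bt <- signal::butter(2, c(0.05, 10) / (fs / 2), type = "pass")
  settled <- function(y) {
    n <- length(y)
    max(abs(y[(2 * n %/% 5):(3 * n %/% 5)]))
  }

  # deep in the passband the signal comes through unchanged
  y1 <- bandpass_butter_zerophase(sin(2 * pi * 1 * t), fs, 0.05, 10, 2)
  expect_gt(settled(y1), 0.99)
  expect_lt(settled(y1), 1.01)

  # near the band edge, forward-backward application realises the squared
  # magnitude of the designed filter
  y5 <- bandpass_butter_zerophase(sin(2 * pi * 5 * t), fs, 0.05, 10, 2)
  expect_lt(abs(settled(y5) - filter_gain(bt$b, bt$a, 5, fs)^2), 0.05)

  # the stopband is strongly attenuated
  y40 <- bandpass_butter_zerophase(sin(2 * pi * 40 * t), fs, 0.05, 10, 2)
  expect_lt(settled(y40), 0.05)

  # the 0.05 Hz high-pass edge removes DC
  ydc <- bandpass_butter_zerophase(rep(1, 2500), fs, 0.05, 10, 2)
  expect_lt(max(abs(ydc)), 1e-6)

  expect_error(bandpass_butter_zerophase(sin(t), fs, 10, 200, 2), "fs/2")
})

test_that("zero phase: a band-interior sinusoid is not shifted in time", {
  fs <- 250
  t <- (0:(40 * fs - 1)) / fs
  x <- sin(2 * pi * 2 * t)
  y <- bandpass_butter_zerophase(x, fs, 0.05, 10, 2)
  n <- length(y)
  mid <- (2 * n %/% 5):(3 * n %/% 5)
  expect_lt(max(abs(y[mid] - x[mid])), 0.02)
  # lag-0 alignment beats any shifted alignment
  lag_cor <- vapply(-3:3, function(l)
    cor(y[mid], x[mid + l]), numeric(1))
  expect_equal(which.max(lag_cor), 4L)
})

test_that("FIR band-pass is linear-phase with compensated group delay", {
  fs <- 250; order <- 200L
  t <- (0:(6 * fs - 1)) / fs

  y20 <- fir_bandpass(sin(2 * pi * 20 * t), fs, 0.1, 45, order)
  expect_gt(interior_amplitude(y20), 0.99)

  b <- signal::fir1(order, c(0.1, 45) / (fs / 2), type = "pass",
                    window = signal::hamming(order + 1))
  y60 <- fir_bandpass(sin(2 * pi * 60 * t), fs, 0.1, 45, order)
  expected <- filter_gain(b, 1, 60, fs)
  expect_lt(abs(interior_amplitude(y60) - expected), 0.02)
  expect_lt(interior_amplitude(y60), 0.05)

  # impulse response equals the windowed-sinc kernel, centred on the impulse
  imp <- numeric(501); n0 <- 251
  imp[n0] <- 1
  y <- fir_bandpass(imp, fs, 0.1, 45, order)
  expect_equal(y[(n0 - order / 2):(n0 + order / 2)], as.numeric(b),
               tolerance = 1e-12)

  expect_error(fir_bandpass(rnorm(100), fs, 0.1, 45, order), "shorter")
  expect_error(fir_bandpass(rnorm(300), fs, 0.1, 45, 201L), "even")
})

test_that("common average reference zeroes the channel mean, is idempotent, and matches hand algebra on 2 channels", {
  ep <- random_epochs(4, 5, 100)
  car <- common_average_reference(ep)
  means <- apply(car$data, c(1, 3), mean)
  expect_lt(max(abs(means)), 1e-12)
  again <- common_average_reference(car)
  expect_equal(again$data, car$data, tolerance = 1e-12)

  a <- sin(2 * pi * 3 * (0:99) / 100); b <- cos(2 * pi * 5 * (0:99) / 100)
  two <- epoch_set(array(0, c(1, 2, 100)), 100, 0)
  two$data[1, 1, ] <- a; two$data[1, 2, ] <- b
  out <- common_average_reference(two)
  expect_equal(out$data[1, 1, ], (a - b) / 2, tolerance = 1e-12)
  expect_equal(out$data[1, 2, ], (b - a) / 2, tolerance = 1e-12)

  one <- epoch_set(array(rnorm(50), c(1, 1, 50)), 50, 0)
  expect_error(common_average_reference(one), "2 channels")
})

test_that("baseline correction subtracts the baseline-window mean", {
  tr <- epoch_set(array(c(1, 2, 3, 4), c(1, 1, 4)), 4, 0)
  out <- baseline_correct(tr, 1:2)
  expect_equal(as.numeric(out$data[1, 1, ]), c(-0.5, 0.5, 1.5, 2.5))

  const <- epoch_set(array(7, c(2, 2, 10)), 10, c(0, 1))
  expect_equal(max(abs(baseline_correct(const, 1:5)$data)), 0)

  ep <- random_epochs(3, 2, 60)
  once <- baseline_correct(ep, 5:20)
  twice <- baseline_correct(once, 5:20)
  expect_equal(twice$data, once$data, tolerance = 1e-12)

  expect_error(baseline_correct(ep, integer(0)), "empty")
  expect_error(baseline_correct(ep, 50:70), "bounds")
})

test_that("decimation yields the output-rate sample count and preserves slow content", {
  x <- rnorm(250)
  expect_length(decimate_to(x, 250, 20), 20)
  expect_identical(decimate_to(x, 250, 250), x)
  expect_error(decimate_to(x, 250, 500), "exceeds")

  const <- rep(3.7, 250)
  expect_equal(decimate_to(const, 250, 20), rep(3.7, 20), tolerance = 1e-6)

  # 2 Hz sinusoid, well under the 10 Hz output Nyquist
  t <- (0:999) / 250
  y <- decimate_to(sin(2 * pi * 2 * t), 250, 20)
  expected <- sin(2 * pi * 2 * (0:(length(y) - 1)) / 20)
  keep <- 5:(length(y) - 4)   # edge transient of the anti-alias filter
  expect_lt(max(abs(y[keep] - expected[keep])), 0.01)

  # integer-ratio path: every q-th sample of the filtered series
  y2 <- decimate_to(sin(2 * pi * 2 * t), 250, 50)
  expected2 <- sin(2 * pi * 2 * (0:(length(y2) - 1)) / 50)
  keep2 <- 10:(length(y2) - 9)
  expect_lt(max(abs(y2[keep2] - expected2[keep2])), 0.01)
})

test_that("Welch periodogram matches a brute-force windowed-DFT oracle", {
  set.seed(42)
  cases <- list(
    list(n = 250, wl = 250, nfft = 250, ov = 0.5),   # single segment
    list(n = 250, wl = 16, nfft = 250, ov = 0.5),    # zero-padded short window
    list(n = 300, wl = 64, nfft = 64, ov = 0.5),
    list(n = 200, wl = 50, nfft = 128, ov = 0.25))
  for (cs in cases) {
    x <- rnorm(cs$n)
    got <- welch_psd(x, 250, cs$wl, cs$nfft, cs$ov)
    want <- welch_oracle(x, 250, cs$wl, cs$nfft, cs$ov)
    expect_equal(got$values, want, tolerance = 1e-10)
    expect_equal(got$freqs[1], 0)
    expect_equal(max(got$freqs), 125)
    expect_equal(got$resolution, 250 / cs$nfft)
  }
})

test_that("Welch scaling integrates white noise to its variance and locates sinusoid peaks", {
  set.seed(7)
  x <- rnorm(50000, sd = 2)
  p <- welch_psd(x, 250, 250, 250, 0.5)
  total <- sum(p$values) * p$resolution
  expect_lt(abs(total - var(x)) / var(x), 0.05)

  s <- sin(2 * pi * 10 * (0:249) / 250)
  ps <- welch_psd(s, 250, 250, 250, 0.5)
  expect_equal(ps$freqs[which.max(ps$values)], 10)

  expect_error(welch_psd(rnorm(100), 250, 250), "longer than series")
})
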