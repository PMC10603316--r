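make_psd <- function(values, freqs = seq_along(values) - 1) {
  structure(list(freqs = freqs, values = values,
                 resolution = diff(freqs[1:2])), class = "psd")
}

test_that("band totals sum log-power over half-open or closed band edges", {
  p_e <- make_psd(rep(exp(1), 126))          # 1 Hz bins, 0..125
  tot <- band_totals(p_e)                    # log e = 1 per bin
  expect_equal(unname(tot), c(2, 7, 17))     # bins 4,5 | 6..12 | 13..29

  tot_closed <- band_totals(p_e, band_definition(edge_convention = "closed"))
  expect_equal(unname(tot_closed), c(3, 8, 18))

  p_1 <- make_psd(rep(1, 126))
  expect_equal(unname(band_totals(p_1)), c(0, 0, 0))

  # hand-summed logs on arbitrary known bin values
  set.seed(2)
  v <- runif(126, 0.5, 2)
  tot_v <- band_totals(make_psd(v))
  expect_equal(unname(tot_v[1]), sum(log(v[5:6])))     # freqs 4,5
  expect_equal(unname(tot_v[2]), sum(log(v[7:13])))    # freqs 6..12
  expect_equal(unname(tot_v[3]), sum(log(v[14:30])))   # freqs 13..29

  expect_error(band_totals(make_psd(c(rep(1, 5), 0, rep(1, 120)))),
               "non-positive")
})

test_that("static spectral features are the per-channel (beta/alpha, theta/beta) ratios", {
  ep <- random_epochs(4, 3, 250, seed = 5)
  fm <- static_spectral_features(ep)
  expect_equal(ncol(fm$values), 2 * 3)
  expect_equal(fm$channel_map, rep(1:3, each = 2))

  # glue check: features equal ratios of band totals computed independently
  p <- welch_psd(ep$data[2, 3, ], 250, 250, 250, 0.5)
  tot <- band_totals(p)
  expect_equal(fm$values[2, 5], tot[["beta"]] / tot[["alpha"]])
  expect_equal(fm$values[2, 6], tot[["theta"]] / tot[["beta"]])

  inv <- static_spectral_features(ep, invert_theta_beta = TRUE)
  expect_equal(inv$values[2, 6], tot[["beta"]] / tot[["theta"]])

  # identical epochs give identical feature rows
  ep2 <- epoch_set(ep$data[c(1, 1), , ], 250, c(0, 1))
  fm2 <- static_spectral_features(ep2)
  expect_equal(fm2$values[1, ], fm2$values[2, ])
})

test_that("static temporal features are z-scored 20-point traces per channel", {
  ep <- random_epochs(3, 4, 250, seed = 8)
  fm <- static_temporal_features(ep)
  expect_equal(ncol(fm$values), 20 * 4)
  expect_equal(fm$channel_map, rep(1:4, each = 20))
  for (ch in 1:4) {
    block <- fm$values[2, (ch - 1) * 20 + 1:20]
    expect_equal(mean(block), 0, tolerance = 1e-12)
    expect_equal(sd(block), 1, tolerance = 1e-12)
  }
})

test_that("a slow sinusoid survives the temporal pipeline as its analytic decimated z-score", {
  ep <- signal_epochs(list(function(t) sin(2 * pi * 2 * t),
                           function(t) cos(2 * pi * 3 * t)))
  fm <- static_temporal_features(ep)
  tk <- (0:19) / 20
  s <- sin(2 * pi * 2 * tk)
  expected <- (s - mean(s)) / sd(s)
  got <- fm$values[1, 1:20]
  # the slow high-pass edge leaves a small transient across a 1 s epoch,
  # so the match is approximate but the shape is preserved
  interior <- 3:18
  expect_lt(max(abs(got[interior] - expected[interior])), 0.2)
  expect_gt(cor(got, expected), 0.99)
})

test_that("feature dimensionality identities hold for any channel count", {
  for (nc in c(2, 5, 9)) {
    ep <- random_epochs(2, nc, 250, seed = nc)
    expect_equal(ncol(static_spectral_features(ep)$values), 2 * nc)
    expect_equal(ncol(static_temporal_features(ep)$values), 20 * nc)
  }
})

test_that("feature extraction is permutation-equivariant in channels", {
  ep <- random_epochs(3, 4, 250, seed = 13)
  perm <- c(3, 1, 4, 2)
  epp <- epoch_set(ep$data[, perm, , drop = FALSE], ep$fs, ep$labels,
                   ep$channel_ids[perm])
  f1 <- static_temporal_features(ep)
  f2 <- static_temporal_features(epp)
  for (j in seq_along(perm)) {
    expect_equal(f2$values[, (j - 1) * 20 + 1:20],
                 f1$values[, (perm[j] - 1) * 20 + 1:20])
  }
})

test_that("epoch segmentation produces 125 one-sample-stride 500 ms windows", {
  ep <- random_epochs(2, 2, 250, seed = 1)
  segs <- segment_epoch(ep)
  expect_length(segs, 125)
  expect_equal(attr(segs[[1]], "time_s"), 0)
  expect_equal(attr(segs[[125]], "time_s"), 124 / 250)
  expect_equal(n_samples(segs[[1]]), 125)
  # exhaustive index check: segment i is samples i .. i+124
  for (i in c(1, 2, 60, 125)) {
    expect_equal(segs[[i]]$data, ep$data[, , i:(i + 124), drop = FALSE])
  }
  short <- random_epochs(1, 2, 100, seed = 2)
  expect_error(segment_epoch(short), "longer than epoch")
})

test_that("dynamic features have the documented per-segment dimensionality", {
  ep <- random_epochs(2, 3, 250, seed = 4)
  dt <- dynamic_temporal_features(ep)
  expect_length(dt, 125)
  expect_equal(ncol(dt[[1]]$values), 10 * 3)
  expect_equal(dt[[17]]$segment_index, 17)
  expect_equal(dt[[17]]$time_s, 16 / 250)
  # each 10-point channel block is z-scored within its segment
  blk <- dt[[40]]$values[1, 11:20]
  expect_equal(mean(blk), 0, tolerance = 1e-12)
  expect_equal(sd(blk), 1, tolerance = 1e-12)

  ds <- dynamic_spectral_features(ep)
  expect_length(ds, 125)
  expect_equal(ncol(ds[[1]]$values), 2 * 3)
  expect_equal(ds[[5]]$time_s, 4 / 250)
})

test_that("dynamic spectral features of a stationary signal track the static ones", {
  # heterogeneous alpha topography gives genuine cross-channel band
  # structure for both window lengths to agree on
  cfg <- generator_config(
    n_epochs_per_class = 15, n_channels = 24, seed = 6,
    osc_components = list(
      list(freq = 10, amplitude = 20, channels = 1:12),
      list(freq = 20, amplitude = 10, channels = NULL)))
  ep <- generate_epochs(cfg)
  stat <- static_spectral_features(ep)
  seg1 <- dynamic_spectral_features(ep, shift_samples = 125L)[[1]]
  # the 16-point window estimates each epoch noisily but preserves the
  # band structure in expectation: mean feature vectors agree
  expect_gt(cor(colMeans(stat$values), colMeans(seg1$values)), 0.9)
})
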