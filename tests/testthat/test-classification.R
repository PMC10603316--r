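toy_fm <- function(x, y) {
  feature_matrix(x, y, rep(1L, ncol(x)), "temporal",
                 channel_ids = "ch1")
}

test_that("1-NN returns the label of the nearest (lowest-index on ties) training point", {
  xtr <- matrix(c(0, 0, 1, 1, 5, 5), 3, 2, byrow = TRUE)
  ytr <- c(0L, 1L, 0L)
  tr <- toy_fm(xtr, ytr)
  te <- toy_fm(matrix(c(1, 1), 1, 2), 1L)
  expect_equal(train_predict(classifier_spec("KNN"), tr, te), 1L)

  # equidistant neighbours with conflicting labels: lowest index wins
  xtr2 <- matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE)
  tr2 <- toy_fm(xtr2, c(1L, 0L))
  te2 <- toy_fm(matrix(c(1, 0), 1, 2), 0L)
  expect_equal(train_predict(classifier_spec("KNN"), tr2, te2), 1L)

  # resubstitution: every training point is its own nearest neighbour
  set.seed(2)
  x <- matrix(rnorm(60), 20, 3)
  y <- rep(0:1, 10)
  fm <- toy_fm(x, y)
  expect_equal(train_predict(classifier_spec("KNN"), fm, fm), y)
})

test_that("LDA separates well-separated Gaussian clouds near the Bayes rate", {
  set.seed(11)
  n <- 100
  xtr <- rbind(matrix(rnorm(2 * n, mean = 0), ncol = 2) +
                 matrix(c(-3, 0), n, 2, byrow = TRUE),
               matrix(rnorm(2 * n, mean = 0), ncol = 2) +
                 matrix(c(3, 0), n, 2, byrow = TRUE))
  ytr <- rep(0:1, each = n)
  xte <- rbind(matrix(rnorm(2 * n), ncol = 2) +
                 matrix(c(-3, 0), n, 2, byrow = TRUE),
               matrix(rnorm(2 * n), ncol = 2) +
                 matrix(c(3, 0), n, 2, byrow = TRUE))
  pred <- train_predict(classifier_spec("LDA"), toy_fm(xtr, ytr),
                        toy_fm(xte, ytr))
  expect_gt(accuracy(pred, ytr), 0.95)

  # pseudo-inverse keeps LDA defined when features outnumber instances
  set.seed(12)
  xw <- matrix(rnorm(10 * 50), 10, 50)
  yw <- rep(0:1, 5)
  expect_length(train_predict(classifier_spec("LDA"), toy_fm(xw, yw),
                              toy_fm(xw, yw)), 10)
})

test_that("SVM learns a separable nonlinear problem and RANDOM stays at chance", {
  set.seed(4)
  n <- 80
  r <- c(runif(n, 0, 1), runif(n, 2, 3))     # concentric annuli
  th <- runif(2 * n, 0, 2 * pi)
  x <- cbind(r * cos(th), r * sin(th))
  y <- rep(0:1, each = n)
  pred <- train_predict(classifier_spec("SVM"), toy_fm(x, y), toy_fm(x, y))
  expect_gt(accuracy(pred, y), 0.9)

  big <- toy_fm(matrix(rnorm(10000), 10000, 1), rep(0:1, 5000))
  pr <- train_predict(classifier_spec("RANDOM", seed = 99),
                      toy_fm(matrix(rnorm(10), 10, 1), rep(0:1, 5)), big)
  expect_lt(abs(accuracy(pr, big$labels) - 0.5), 0.015)
  # seeded RANDOM is reproducible
  pr2 <- train_predict(classifier_spec("RANDOM", seed = 99),
                       toy_fm(matrix(rnorm(10), 10, 1), rep(0:1, 5)), big)
  expect_identical(pr, pr2)
})

test_that("accuracy counts correct predictions", {
  expect_equal(accuracy(c(1, 0, 1, 1), c(1, 1, 1, 0)), 0.5)
  expect_equal(accuracy(1:0, 1:0), 1)
  p <- c(0L, 1L, 1L, 0L, 1L); a <- c(0L, 1L, 0L, 0L, 0L)
  expect_equal(accuracy(p, a) + accuracy(1L - p, a), 1)
  expect_error(accuracy(integer(0), integer(0)), "non-empty")
  expect_error(accuracy(1:3, 1:4), "equal length")
})

test_that("single-class training sets are rejected", {
  fm1 <- toy_fm(matrix(rnorm(12), 6, 2), rep(1L, 6))
  fm2 <- toy_fm(matrix(rnorm(4), 2, 2), c(0L, 1L))
  expect_error(train_predict(classifier_spec("LDA"), fm1, fm2),
               "single-class")
})

test_that("fold assignments form a stratified partition, reproducible by seed", {
  y <- rep(c(0, 1), c(24, 36))
  folds <- make_folds(y, n_folds = 6, n_repeats = 4, seed = 8)
  expect_length(folds, 4)
  for (f in folds) {
    expect_length(f, 60)
    expect_setequal(unique(f), 1:6)
    for (k in 1:6) {                     # per-fold class balance
      expect_equal(sum(f == k & y == 0), 4)
      expect_equal(sum(f == k & y == 1), 6)
    }
  }
  expect_false(identical(folds[[1]], folds[[2]]))
  expect_identical(folds, make_folds(y, 6, 4, seed = 8))
  expect_error(make_folds(rep(c(0, 1), c(3, 30)), 10, 2), "too few")
})

test_that("repeated CV returns the repeats-by-classifiers accuracy matrix deterministically", {
  cfg <- generator_config(n_epochs_per_class = 20, n_channels = 3, seed = 2)
  fm <- static_spectral_features(generate_epochs(cfg))
  cv <- repeated_cv(fm, n_folds = 5, n_repeats = 3, seed = 10)
  expect_equal(dim(cv$mean_accuracy), c(3, 4))
  expect_equal(colnames(cv$mean_accuracy),
               c("LDA", "SVM", "KNN", "RANDOM"))
  expect_true(all(cv$mean_accuracy >= 0 & cv$mean_accuracy <= 1))
  expect_equal(dim(cv$fold_accuracy), c(3, 5, 4))
  expect_equal(apply(cv$fold_accuracy, c(1, 3), mean), cv$mean_accuracy)

  cv2 <- repeated_cv(fm, n_folds = 5, n_repeats = 3, seed = 10)
  expect_identical(cv$mean_accuracy, cv2$mean_accuracy)
  cv3 <- repeated_cv(fm, n_folds = 5, n_repeats = 3, seed = 11)
  expect_false(identical(cv$mean_accuracy, cv3$mean_accuracy))
})

test_that("strong temporal effects are decoded near-perfectly by the harness", {
  cfg <- generator_config(
    n_epochs_per_class = 40, n_channels = 6,
    temporal_effect = list(channels = 1:4, amplitude = -4,
                           onset_ms = 500, shape = "linear"),
    seed = 1)
  fm <- static_temporal_features(generate_epochs(cfg))
  cv <- repeated_cv(fm, default_classifier_specs()[c("KNN", "RANDOM")],
                    n_folds = 5, n_repeats = 2, seed = 4)
  expect_gt(mean(cv$mean_accuracy[, "KNN"]), 0.9)
  expect_lt(abs(mean(cv$mean_accuracy[, "RANDOM"]) - 0.5), 0.2)

  # brute-force cross-check: nearest neighbour on raw decimated traces
  ep <- generate_epochs(cfg)
  raw <- t(apply(ep$data, 1, function(m)
    as.vector(t(m[, seq(1, 250, by = 12)]))))
  hit <- vapply(seq_len(nrow(raw)), function(i) {
    d <- colSums((t(raw[-i, ]) - raw[i, ])^2)
    ep$labels[-i][which.min(d)] == ep$labels[i]
  }, logical(1))
  expect_gt(mean(hit), 0.9)
})

test_that("dynamic CV yields per-segment sequences aligned with segment times", {
  cfg <- generator_config(n_epochs_per_class = 15, n_channels = 2, seed = 5)
  ep <- generate_epochs(cfg)
  segs <- dynamic_temporal_features(ep, shift_samples = 25L)
  dyn <- dynamic_repeated_cv(segs,
                             default_classifier_specs()[c("KNN", "RANDOM")],
                             n_folds = 5, n_repeats = 2, seed = 3)
  expect_equal(dim(dyn$accuracy), c(2, length(segs), 2))
  expect_equal(dyn$segment_times,
               vapply(segs, function(s) s$time_s, numeric(1)))
  dyn2 <- dynamic_repeated_cv(segs,
                              default_classifier_specs()[c("KNN", "RANDOM")],
                              n_folds = 5, n_repeats = 2, seed = 3)
  expect_identical(dyn$accuracy, dyn2$accuracy)
})
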