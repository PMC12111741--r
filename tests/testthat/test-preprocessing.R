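test_that("z-score fit uses population moments and rejects degenerate input", {
  p <- zscore_fit(c(1, 2, 3))
  expect_equal(p$mean, 2)
  expect_equal(p$std, sqrt(2 / 3))
  expect_error(zscore_fit(rep(4, 10)), "constant")
  expect_error(zscore_fit(5), "at least 2")

  expect_equal(zscore_apply(c(1, 2, 3), p),
               c(-1, 0, 1) * 1 / sqrt(2 / 3), tolerance = 1e-4)
  expect_equal(zscore_apply(c(1, 2, 3), p)[1], -1.2247, tolerance = 1e-4)
})

test_that("z-score apply/invert round-trips and standardizes", {
  set.seed(21)
  x <- rnorm(200, 15, 7)
  p <- zscore_fit(x)
  z <- zscore_apply(x, p)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-9)
  expect_equal(zscore_invert(z, p), x, tolerance = 1e-12)

  expect_equal(zscore_apply(2, structure(list(mean = 2, std = 1),
                                         class = "zscore_params")), 0)

  s <- make_series(x[1:50])
  rt <- zscore_invert(zscore_apply(s, p), p)
  expect_equal(rt$values, s$values, tolerance = 1e-12)
})

test_that("chronological split is a contiguous ordered partition", {
  s <- make_series(seq_len(1000))
  sp <- chronological_split(s, 0.8)
  expect_length(sp$train, 800)
  expect_length(sp$test, 200)
  expect_equal(c(sp$train$values, sp$test$values), s$values)
  expect_true(max(as.numeric(sp$train$timestamps)) <
                min(as.numeric(sp$test$timestamps)))

  sp10 <- chronological_split(make_series(1:10), 0.8)
  expect_length(sp10$train, 8)
  expect_length(sp10$test, 2)

  expect_error(chronological_split(s, 0), "strictly between")
  expect_error(chronological_split(make_series(1:1), 0.5), "too short")
})

test_that("sliding windows enumerate every one-step pair in order", {
  ds1 <- make_windows(make_series(1:11), 10)
  expect_equal(nrow(ds1$inputs), 1)
  expect_equal(as.numeric(ds1$inputs[1, ]), 1:10)
  expect_equal(ds1$targets, 11)

  ds <- make_windows(make_series(1:100), 10)
  expect_equal(nrow(ds$inputs), 90)
  expect_equal(as.numeric(ds$inputs[1, ]), 1:10)
  expect_equal(ds$targets[1], 11)
  expect_equal(as.numeric(ds$inputs[90, ]), 90:99)
  expect_equal(ds$targets[90], 100)
  expect_equal(ds$horizon, 1L)

  # default lookback is ten (daily) samples
  expect_equal(eval(formals(make_windows)$lookback), 10)
  expect_error(make_windows(make_series(1:10), 10), "exceed")
})

test_that("daily aggregation averages complete days", {
  v <- rep(c(0, 6, 12, 18, 24, 30), 3) + rep(c(0, 100, 200), each = 6)
  s <- make_series(v, cadence_hours = 4)
  d <- aggregate_daily(s)
  expect_length(d, 3)
  expect_equal(d$values, c(15, 115, 215))
  expect_equal(d$cadence_hours, 24)
})

test_that("dataset construction augments train only and never leaks", {
  s <- make_seasonal_series(n_days = 100, noise_sd = 0.3)

  plain <- build_datasets(s, lookback = 10, augment = FALSE)
  raw_train <- make_windows(zscore_apply(plain$slices$train, plain$params), 10)
  expect_equal(plain$train$inputs, raw_train$inputs)
  expect_equal(plain$train$targets, raw_train$targets)

  aug <- build_datasets(s, lookback = 10, augment = TRUE, seed = 4)
  expect_equal(nrow(aug$train$inputs), 3 * (80 - 10))
  # test windows identical with and without augmentation up to normalization
  expect_equal(zscore_invert(aug$test$targets, aug$params),
               zscore_invert(plain$test$targets, plain$params),
               tolerance = 1e-9)
  # test targets denormalize to the raw test slice exactly
  expect_equal(zscore_invert(aug$test$targets, aug$params),
               plain$slices$test$values[11:20], tolerance = 1e-12)

  # no leakage: every test target strictly later than all train samples
  expect_true(min(as.numeric(aug$test$target_times)) >
                max(as.numeric(plain$slices$train$timestamps)))

  # normalization params come from the train pool only
  pool <- unlist(lapply(augment_training_set(aug$slices$train, seed = 4),
                        function(v) v$values))
  expect_equal(aug$params$mean, mean(pool), tolerance = 1e-12)
  expect_equal(plain$params$mean, mean(plain$slices$train$values),
               tolerance = 1e-12)
})
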