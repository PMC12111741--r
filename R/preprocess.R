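#' Z-score normalization parameters
#'
#' Fits `(x - mu) / sigma` standardization on a gap-free, non-constant
#' series using the population standard deviation (divide by `n`).
#'
#' @param series a `grain_series` or numeric vector.
#' @return A `zscore_params` list with `mean` and `std`.
#' @examples
#' zscore_fit(c(1, 2, 3))  # mean 2, std sqrt(2/3)
#' @export
zscore_fit <- function(series) {
  x <- if (inherits(series, "grain_series")) series$values else as.numeric(series)
  if (anyNA(x)) stop_bad("zscore_fit requires gap-free data")
  n <- length(x)
  if (n < 2) stop_bad("need at least 2 samples to fit a z-score")
  m <- mean(x)
  s <- sqrt(sum((x - m)^2) / n)
  if (s == 0) stop_bad("constant series: standard deviation is zero")
  structure(list(mean = m, std = s), class = "zscore_params")
}

#' @export
print.zscore_params <- function(x, ...) {
  cat(sprintf("<zscore_params> mean = %.6g, std = %.6g\n", x$mean, x$std))
  invisible(x)
}

#' Apply / invert z-score normalization
#'
#' `zscore_apply` maps `x -> (x - mu)/sigma`; `zscore_invert` maps back
#' `x -> x*sigma + mu`. The round trip is the identity to machine precision.
#' Both accept a `grain_series` (returned as a series) or a numeric vector.
#'
#' @param x a `grain_series` or numeric vector.
#' @param params a `zscore_params`.
#' @export
zscore_apply <- function(x, params) {
  stopifnot(inherits(params, "zscore_params"))
  if (params$std <= 0) stop_bad("std must be > 0")
  if (inherits(x, "grain_series"))
    series_with_values(x, (x$values - params$mean) / params$std)
  else (x - params$mean) / params$std
}

#' @rdname zscore_apply
#' @export
zscore_invert <- function(x, params) {
  stopifnot(inherits(params, "zscore_params"))
  if (params$std <= 0) stop_bad("std must be > 0")
  if (inherits(x, "grain_series"))
    series_with_values(x, x$values * params$std + params$mean)
  else x * params$std + params$mean
}

#' Aggregate a sub-daily series to daily means
#'
#' Averages all samples sharing a calendar day (UTC). Used to turn the raw
#' 4-hour cadence into the daily cadence of the 10-day lookback window.
#' Requires complete days (cadence dividing 24) and a gap-free series.
#'
#' @param series a `grain_series`.
#' @return A daily-cadence `grain_series` stamped at midnight of each day.
#' @export
aggregate_daily <- function(series) {
  stopifnot(inherits(series, "grain_series"))
  if (series$cadence_hours == 24) return(series)
  require_gap_free(series, "aggregate_daily")
  per_day <- 24 / series$cadence_hours
  n_days <- floor(length(series) / per_day)
  if (n_days < 1) stop_bad("series shorter than one day")
  keep <- seq_len(n_days * per_day)
  day_ix <- rep(seq_len(n_days), each = per_day)
  vals <- as.numeric(tapply(series$values[keep], day_ix, mean))
  days <- series$timestamps[seq(1, by = per_day, length.out = n_days)]
  days <- as.POSIXct(trunc(days, "days"), tz = "UTC")
  grain_series(days, vals, 24, label = paste0(series$label, "/daily"))
}

#' Chronological train/test split
#'
#' First `floor(n * train_fraction)` samples form the training slice, the
#' remainder the test slice; no shuffling, slices contiguous and disjoint,
#' concatenation reproduces the input.
#'
#' @param series a `grain_series`.
#' @param train_fraction in (0, 1); default 0.8.
#' @return List with `train` and `test` (`grain_series`).
#' @export
chronological_split <- function(series, train_fraction = 0.8) {
  stopifnot(inherits(series, "grain_series"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_bad("train_fraction must be strictly between 0 and 1")
  n <- length(series)
  n_train <- floor(n * train_fraction)
  if (n_train < 1 || n_train >= n)
    stop_bad("series too short to split at this fraction")
  idx_tr <- seq_len(n_train)
  list(
    train = grain_series(series$timestamps[idx_tr], series$values[idx_tr],
                         series$cadence_hours, paste0(series$label, "/train")),
    test = grain_series(series$timestamps[-idx_tr], series$values[-idx_tr],
                        series$cadence_hours, paste0(series$label, "/test")))
}

#' Sliding-window supervised dataset
#'
#' Builds one-step-ahead (lookback, target) pairs: input row `i` spans
#' samples `i .. i+lookback-1` and its target is sample `i+lookback`, so a
#' series of length `n` yields `n - lookback` windows, ordered
#' chronologically. Default lookback: 10 daily samples (ten days of history
#' to forecast the following day).
#'
#' @param series a gap-free `grain_series` or numeric vector.
#' @param lookback window length in samples (default 10).
#' @param timestamps optional POSIXct vector aligned with a numeric input.
#' @return A `windowed_dataset`: `inputs` (matrix n_windows x lookback),
#'   `targets` (vector), `lookback`, `horizon` (always 1), and
#'   `target_times` when timestamps are known.
#' @export
make_windows <- function(series, lookback = 10, timestamps = NULL) {
  if (inherits(series, "grain_series")) {
    require_gap_free(series, "make_windows")
    x <- series$values
    timestamps <- series$timestamps
  } else x <- as.numeric(series)
  if (anyNA(x)) stop_bad("make_windows requires gap-free data")
  check_scalar_num(lookback, "lookback", 1)
  n <- length(x)
  if (n <= lookback)
    stop_bad(sprintf("series length (%d) must exceed lookback (%d)", n, lookback))
  n_win <- n - lookback
  inputs <- matrix(0, n_win, lookback)
  for (j in seq_len(lookback)) inputs[, j] <- x[j:(j + n_win - 1L)]
  structure(list(
    inputs = inputs,
    targets = x[(lookback + 1L):n],
    lookback = as.integer(lookback),
    horizon = 1L,
    target_times = if (!is.null(timestamps)) timestamps[(lookback + 1L):n]),
    class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf("<windowed_dataset> %d windows, lookback %d, horizon %d\n",
              nrow(x$inputs), x$lookback, x$horizon))
  invisible(x)
}

n_windows <- function(ds) nrow(ds$inputs)

rbind_windows <- function(a, b) {
  stopifnot(a$lookback == b$lookback)
  structure(list(inputs = rbind(a$inputs, b$inputs),
                 targets = c(a$targets, b$targets),
                 lookback = a$lookback, horizon = 1L,
                 target_times = NULL),
            class = "windowed_dataset")
}

#' Build train/test datasets with leakage-free augmentation
#'
#' The full preprocessing recipe: chronological 80/20 split of the raw
#' series; dual-domain augmentation of the *training slice only*; z-score
#' parameters fitted on the pooled augmented training values; each training
#' variant normalized and windowed separately (windows never straddle
#' variant boundaries) and the windows concatenated; the untouched test
#' slice normalized with the train-fitted parameters and windowed. Test
#' windows never contain augmented values, and every test target is strictly
#' later than every training sample.
#'
#' @param series a gap-free `grain_series` (daily cadence expected for the
#'   default lookback; see [aggregate_daily()]).
#' @param lookback window length in samples.
#' @param train_fraction chronological split fraction.
#' @param augment apply dual-domain augmentation to the training slice?
#' @param sigma,mu,amplification_factor,amplify_dc augmentation settings.
#' @param seed seed for the augmentation noise.
#' @return List `train` (windowed), `test` (windowed), `params`
#'   (`zscore_params`), `slices` (the raw train/test `grain_series`).
#' @export
build_datasets <- function(series, lookback = 10, train_fraction = 0.8,
                           augment = FALSE, sigma = 0.01, mu = 0,
                           amplification_factor = 1.2, amplify_dc = FALSE,
                           seed = 1L) {
  stopifnot(inherits(series, "grain_series"))
  require_gap_free(series, "build_datasets")
  sp <- chronological_split(series, train_fraction)
  if (length(sp$train) <= lookback || length(sp$test) <= lookback)
    stop_bad("series too short: each slice must exceed the lookback")

  variants <- if (augment)
    augment_training_set(sp$train, sigma = sigma, mu = mu,
                         amplification_factor = amplification_factor,
                         amplify_dc = amplify_dc, seed = seed)
  else list(sp$train)

  pool <- unlist(lapply(variants, function(s) s$values))
  params <- zscore_fit(pool)

  train_ds <- NULL
  for (v in variants) {
    ds <- make_windows(zscore_apply(v, params), lookback)
    train_ds <- if (is.null(train_ds)) ds else rbind_windows(train_ds, ds)
  }
  test_ds <- make_windows(zscore_apply(sp$test, params), lookback)
  list(train = train_ds, test = test_ds, params = params, slices = sp)
}

#' Export windowed datasets to CSV
#'
#' Writes normalized windows with columns `x0..x{L-1},y`.
#'
#' @param ds a `windowed_dataset`.
#' @param path output path.
#' @export
write_windows_csv <- function(ds, path) {
  df <- as.data.frame(ds$inputs)
  names(df) <- paste0("x", seq_len(ds$lookback) - 1L)
  df$y <- ds$targets
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
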