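#' Fit a grain-storage temperature forecasting model
#'
#' The package's main entry point. Takes a gap-free temperature series,
#' aggregates it to daily means when sampled sub-daily, splits it
#' chronologically (default 80/20), optionally applies dual-domain
#' augmentation (Gaussian jitter sigma = 0.01 degC and 1.2x non-DC spectrum
#' amplification) to the training slice, fits z-score normalization on the
#' training pool, builds one-step-ahead sliding windows (default lookback:
#' ten days), trains the requested architecture with Adam, and evaluates
#' MAE/RMSE on the untouched test slice.
#'
#' Augmentation defaults to on for `FTA-`-prefixed model names and off
#' otherwise; pass `augment` explicitly to override. Metrics are reported
#' on the normalized scale by default (`metric_scale = "celsius"` scores
#' the denormalized predictions instead).
#'
#' @param series a `grain_series` (gap-free; see [inject_gaps()] /
#'   [layer_mean_series()] for preparing sensor data).
#' @param model architecture name; see [model_names()].
#' @param lookback window length in daily samples.
#' @param train_fraction chronological split fraction.
#' @param augment logical; `NULL` (default) derives it from the model name.
#' @param sigma,amplification_factor augmentation settings.
#' @param epochs,batch_size,learning_rate,l2_coefficient training settings.
#' @param dropout dropout rate of the LSTM hybrids.
#' @param se_reduction,se_position SE block settings (see [build_model()]).
#' @param metric_scale `"normalized"` or `"celsius"`.
#' @param daily aggregate sub-daily input to daily means first? Default TRUE.
#' @param seed global seed; every stochastic stage derives its own stream.
#' @return An object of class `grain_forecast` with components `net`
#'   (trained `grain_net`), `datasets`, `params` (`zscore_params`),
#'   `metrics` (`mae`, `rmse`, `n`), `predictions` (degC),
#'   `predictions_normalized`, `loss_history`, and the call settings.
#' @examples
#' \donttest{
#' lay <- generate_layout(1, 1, 1)
#' sims <- simulate_temperatures(lay, simulation_config(duration_days = 120,
#'                                                      seed = 7))
#' fit <- grain_forecast(sims[[1]], model = "LSTM", epochs = 10, seed = 7)
#' print(fit)
#' }
#' @export
grain_forecast <- function(series, model = "FTA-CNN-SE-LSTM", lookback = 10,
                           train_fraction = 0.8, augment = NULL,
                           sigma = 0.01, amplification_factor = 1.2,
                           epochs = 100, batch_size = 32, learning_rate = 1e-3,
                           l2_coefficient = 1e-4, dropout = 0.2,
                           se_reduction = 4,
                           se_position = c("after_conv", "between_lstm"),
                           metric_scale = c("normalized", "celsius"),
                           daily = TRUE, seed = 1L) {
  stopifnot(inherits(series, "grain_series"))
  metric_scale <- match.arg(metric_scale)
  se_position <- match.arg(se_position)
  if (is.null(augment)) augment <- uses_augmentation(model)

  work <- if (daily && series$cadence_hours < 24) aggregate_daily(series)
          else series
  ds <- build_datasets(work, lookback = lookback,
                       train_fraction = train_fraction, augment = augment,
                       sigma = sigma,
                       amplification_factor = amplification_factor,
                       seed = derive_seed(seed, "augment"))

  net <- build_model(model, lookback = lookback, dropout = dropout,
                     se_reduction = se_reduction, se_position = se_position,
                     seed = seed)
  net <- train_model(net, ds$train,
                     train_config(epochs = epochs, batch_size = batch_size,
                                  learning_rate = learning_rate,
                                  l2_coefficient = l2_coefficient,
                                  seed = seed))

  pred_norm <- predict_windows(net, ds$test)
  pred_c <- zscore_invert(pred_norm, ds$params)
  actual_norm <- ds$test$targets
  actual_c <- zscore_invert(actual_norm, ds$params)
  metrics <- if (metric_scale == "normalized")
    list(mae = mae(actual_norm, pred_norm), rmse = rmse(actual_norm, pred_norm),
         n = length(pred_norm))
  else
    list(mae = mae(actual_c, pred_c), rmse = rmse(actual_c, pred_c),
         n = length(pred_c))

  structure(list(
    net = net, datasets = ds, params = ds$params,
    model = model, lookback = lookback, augment = augment,
    metric_scale = metric_scale,
    metrics = metrics,
    predictions = pred_c, predictions_normalized = pred_norm,
    actual = actual_c,
    target_times = ds$test$target_times,
    loss_history = net$loss_history,
    series_label = series$label, seed = seed),
    class = "grain_forecast")
}

#' @export
print.grain_forecast <- function(x, ...) {
  cat(sprintf("Grain temperature forecast: %s%s\n", x$model,
              if (x$augment) " (dual-domain augmented training)" else ""))
  cat(sprintf("  series '%s', lookback %d days, %d test predictions\n",
              x$series_label, x$lookback, x$metrics$n))
  cat(sprintf("  test MAE = %.4f, RMSE = %.4f (%s scale)\n",
              x$metrics$mae, x$metrics$rmse, x$metric_scale))
  invisible(x)
}

#' @export
summary.grain_forecast <- function(object, ...) {
  res <- residuals(object)
  structure(list(
    model = object$model, augment = object$augment,
    lookback = object$lookback,
    n_train = nrow(object$datasets$train$inputs),
    n_test = object$metrics$n,
    parameters = count_parameters(object$net),
    metrics = object$metrics,
    metric_scale = object$metric_scale,
    final_loss = utils::tail(object$loss_history, 1),
    residual_summary = summary(res)),
    class = "summary.grain_forecast")
}

#' @export
print.summary.grain_forecast <- function(x, ...) {
  cat(sprintf("Model: %s (%d parameters)%s\n", x$model, x$parameters,
              if (x$augment) ", augmented training" else ""))
  cat(sprintf("Windows: %d train / %d test (lookback %d)\n",
              x$n_train, x$n_test, x$lookback))
  cat(sprintf("Final training MSE: %.6g\n", x$final_loss))
  cat(sprintf("Test MAE %.4f / RMSE %.4f (%s scale)\n",
              x$metrics$mae, x$metrics$rmse, x$metric_scale))
  cat("Residuals (degC):\n")
  print(x$residual_summary)
  invisible(x)
}

#' @export
predict.grain_forecast <- function(object, newdata = NULL,
                                   scale = c("celsius", "normalized"), ...) {
  scale <- match.arg(scale)
  if (is.null(newdata))
    return(if (scale == "celsius") object$predictions
           else object$predictions_normalized)
  ds <- if (inherits(newdata, "windowed_dataset")) newdata
  else if (inherits(newdata, "grain_series")) {
    work <- if (newdata$cadence_hours < 24) aggregate_daily(newdata) else newdata
    make_windows(zscore_apply(work, object$params), object$lookback)
  } else if (is.matrix(newdata)) {
    structure(list(inputs = zscore_apply(newdata, object$params),
                   targets = rep(NA_real_, nrow(newdata)),
                   lookback = object$lookback, horizon = 1L),
              class = "windowed_dataset")
  } else stop_bad("newdata must be a grain_series, windowed_dataset or matrix")
  p <- predict_windows(object$net, ds)
  if (scale == "celsius") zscore_invert(p, object$params) else p
}

#' @export
residuals.grain_forecast <- function(object, ...) {
  object$actual - object$predictions
}

#' @export
fitted.grain_forecast <- function(object, ...) object$predictions

#' @export
coef.grain_forecast <- function(object, ...) {
  if (object$net$name == "LSM") return(object$net$lsm_coef)
  lapply(object$net$layers, function(l) l$params)
}

#' Plot a fitted forecast
#'
#' `which = "predictions"` overlays predicted and actual test temperatures;
#' `which = "loss"` draws the training-loss curve.
#'
#' @param x a `grain_forecast`.
#' @param which `"predictions"` or `"loss"`.
#' @param ... passed to the underlying plot call.
#' @export
plot.grain_forecast <- function(x, which = c("predictions", "loss"), ...) {
  which <- match.arg(which)
  if (which == "loss") {
    graphics::plot(seq_along(x$loss_history), x$loss_history, type = "l",
                   xlab = "epoch", ylab = "training MSE",
                   main = paste(x$model, "training loss"), ...)
  } else {
    idx <- x$target_times %||% seq_along(x$actual)
    graphics::plot(idx, x$actual, type = "l", xlab = "time",
                   ylab = "temperature (degC)",
                   main = paste(x$model, "test predictions"), ...)
    graphics::lines(idx, x$predictions, col = 2, lty = 2)
    graphics::legend("topright", legend = c("actual", "predicted"),
                     col = c(1, 2), lty = c(1, 2), bty = "n")
  }
  invisible(x)
}
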