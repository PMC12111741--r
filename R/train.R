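#' Mean absolute error and root mean square error
#'
#' `mae` is the mean of `|x_i - xhat_i|`; `rmse` is the square root of the
#' mean of `(x_i - xhat_i)^2`. By Jensen's inequality `rmse >= mae` for any
#' prediction set.
#'
#' @param actual,predicted numeric vectors of equal nonzero length.
#' @return scalar error, in the units of the inputs.
#' @examples
#' mae(c(0, 0), c(1, -1))   # 1
#' rmse(c(0, 0), c(1, -1))  # 1
#' @export
mae <- function(actual, predicted) {
  check_metric_args(actual, predicted)
  mean(abs(actual - predicted))
}

#' @rdname mae
#' @export
rmse <- function(actual, predicted) {
  check_metric_args(actual, predicted)
  sqrt(mean((actual - predicted)^2))
}

check_metric_args <- function(actual, predicted) {
  if (length(actual) == 0L) stop_bad("empty prediction set")
  if (length(actual) != length(predicted))
    stop_bad("actual and predicted must have equal length")
  if (anyNA(actual) || anyNA(predicted)) stop_bad("metrics require complete data")
  invisible(TRUE)
}

#' Training configuration
#'
#' Defaults: 100 epochs of Adam (learning rate 1e-3) on mini-batches of 32
#' with mean-squared-error loss and L2 weight decay 1e-4 on all weight
#' matrices (biases excluded).
#'
#' @param epochs number of full passes over the training windows.
#' @param batch_size mini-batch size.
#' @param learning_rate Adam step size.
#' @param l2_coefficient L2 penalty added to weight-matrix gradients.
#' @param shuffle reshuffle windows every epoch?
#' @param seed seed driving shuffling and dropout masks.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 100, batch_size = 32, learning_rate = 1e-3,
                         l2_coefficient = 1e-4, shuffle = TRUE, seed = 1L) {
  check_scalar_num(epochs, "epochs", 1)
  check_scalar_num(batch_size, "batch_size", 1)
  check_scalar_num(learning_rate, "learning_rate", 0, strict_lower = TRUE)
  check_scalar_num(l2_coefficient, "l2_coefficient", 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 l2_coefficient = l2_coefficient,
                 shuffle = isTRUE(shuffle), seed = as.integer(seed)),
            class = "train_config")
}

adam_init <- function(net) {
  lapply(net$layers, function(l)
    lapply(l$params, function(p)
      list(m = array(0, dim(p) %||% length(p)),
           v = array(0, dim(p) %||% length(p)))))
}

#' Train a forecasting network
#'
#' Minimizes mean-squared-error on the training windows with Adam. For the
#' `"LSM"` baseline the ordinary-least-squares solution is computed in
#' closed form instead (QR on the flattened windows); its loss history has
#' a single entry. Fully reproducible given the config seed. Aborts with a
#' diagnostic if the loss goes non-finite.
#'
#' @param net a `grain_net` from [build_model()].
#' @param dataset a `windowed_dataset` (normalized training windows).
#' @param config a [train_config()].
#' @return The trained net, with `loss_history` (per-epoch mean training
#'   MSE) attached.
#' @export
train_model <- function(net, dataset, config = train_config()) {
  stopifnot(inherits(net, "grain_net"), inherits(dataset, "windowed_dataset"))
  X <- dataset$inputs; y <- dataset$targets
  if (nrow(X) < 1) stop_bad("empty training dataset")
  if (ncol(X) != net$lookback)
    stop_bad("dataset lookback does not match the network input")

  if (net$name == "LSM") {
    fit <- stats::lm.fit(cbind(1, X), y)
    net$lsm_coef <- unname(fit$coefficients)
    net$lsm_coef[is.na(net$lsm_coef)] <- 0
    net$trained <- TRUE
    net$loss_history <- mean(fit$residuals^2)
    return(net)
  }

  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  state <- adam_init(net)
  step <- 0L
  n <- nrow(X)
  loss_hist <- numeric(config$epochs)

  with_seed(derive_seed(config$seed, paste0("train-", net$name)), {
    for (epoch in seq_len(config$epochs)) {
      ord <- if (config$shuffle) sample.int(n) else seq_len(n)
      batch_losses <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        ix <- ord[start:min(start + config$batch_size - 1L, n)]
        Xb <- X[ix, , drop = FALSE]; yb <- y[ix]
        fw <- net_forward(net, Xb, train = TRUE, keep_caches = TRUE)
        err <- fw$pred - yb
        loss <- mean(err^2)
        if (!is.finite(loss))
          stop_bad(sprintf("training diverged (non-finite loss at epoch %d)", epoch))
        batch_losses <- c(batch_losses, loss)
        grads <- net_backward(net, 2 * err / length(ix), fw$caches)
        step <- step + 1L
        for (li in seq_along(net$layers)) {
          pn <- names(net$layers[[li]]$params)
          for (p in pn) {
            g <- grads[[li]][[p]]
            w <- net$layers[[li]]$params[[p]]
            if (config$l2_coefficient > 0 && p %in% c("W", "Wx", "Wh", "W1", "W2"))
              g <- g + config$l2_coefficient * w
            st <- state[[li]][[p]]
            st$m <- beta1 * st$m + (1 - beta1) * g
            st$v <- beta2 * st$v + (1 - beta2) * g^2
            mhat <- st$m / (1 - beta1^step)
            vhat <- st$v / (1 - beta2^step)
            net$layers[[li]]$params[[p]] <- w -
              config$learning_rate * mhat / (sqrt(vhat) + eps)
            state[[li]][[p]] <- st
          }
        }
      }
      loss_hist[epoch] <- mean(batch_losses)
    }
  })
  net$trained <- TRUE
  net$loss_history <- loss_hist
  net
}

#' Predict from a trained network
#'
#' Forward pass over the test windows (normalized scale); when
#' `norm_params` is supplied the predictions are inverse-normalized back to
#' degrees Celsius, one value per window.
#'
#' @param net a trained `grain_net`.
#' @param dataset a `windowed_dataset`.
#' @param norm_params optional `zscore_params` from the training fit.
#' @return numeric vector of predictions.
#' @export
predict_windows <- function(net, dataset, norm_params = NULL) {
  stopifnot(inherits(net, "grain_net"))
  if (!isTRUE(net$trained)) stop_bad("model has not been trained")
  preds <- if (net$name == "LSM")
    as.numeric(cbind(1, dataset$inputs) %*% net$lsm_coef)
  else net_forward(net, dataset$inputs, train = FALSE)$pred
  if (!is.null(norm_params)) preds <- zscore_invert(preds, norm_params)
  preds
}
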