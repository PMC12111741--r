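# Architecture registry: assembles the forecasting networks from the layer
# primitives. Every model maps a lookback window (length L) to one scalar
# through a linear output unit; classification heads are deliberately absent.

#' Model registry
#'
#' Names of the available forecasting architectures, from the closed-form
#' least-squares baseline (`"LSM"`) up the ladder to the dual-domain
#' augmented hybrid (`"FTA-CNN-SE-LSTM"`). `FTA-CNN-SE-LSTM` shares the
#' CNN-SE-LSTM architecture; the `FTA-` prefix only switches on dual-domain
#' augmentation of the training data upstream.
#'
#' @return character vector of model names.
#' @export
model_names <- function() {
  c("LSM", "BP", "GRU", "CNN", "TCN", "LSTM",
    "CNN-LSTM", "CNN-SE-LSTM", "FTA-CNN-SE-LSTM")
}

#' Does a model name request augmented training data?
#' @param name model name.
#' @export
uses_augmentation <- function(name) startsWith(name, "FTA-")

#' Build an initialized forecasting network
#'
#' Assembles the requested architecture for a given lookback length and
#' initializes its weights (uniform Glorot fan-based init, LSTM forget-gate
#' bias 1) from the seed. The hybrid stack is
#' `Conv1d(64 ch, k=3, ReLU) -> MaxPool(2) -> SE(64, r) -> LSTM(64) ->
#' Dropout -> LSTM(32) -> Dropout -> Dense(1)`; `se_position =
#' "between_lstm"` instead inserts the SE block between the two LSTM
#' layers. `CNN-LSTM` omits the SE block; the plain `LSTM` baseline is
#' `LSTM(8) -> Dense(1)`; `BP` is `Dense(64, ReLU) -> Dense(32, ReLU) ->
#' Dense(1)`; `GRU` is `GRU(64, ReLU) -> Dense(1)`; `CNN` is conv/pool/
#' flatten/dense; `TCN` stacks a causal conv and two conv+pool stages
#' before the dense head. `LSM` is ordinary least squares on the flattened
#' window (no layers; closed-form fit).
#'
#' @param name one of [model_names()].
#' @param lookback input window length in samples (default 10).
#' @param dropout dropout rate for the LSTM hybrids (default 0.2).
#' @param se_reduction SE bottleneck ratio r (default 4, i.e. 64 -> 16 -> 64).
#' @param se_position `"after_conv"` (default) or `"between_lstm"`.
#' @param seed initialization seed.
#' @return A `grain_net`: list of layers plus metadata (`name`, `lookback`,
#'   `spec` summary table).
#' @examples
#' net <- build_model("LSTM", lookback = 10, seed = 1)
#' count_parameters(net)
#' @export
build_model <- function(name, lookback = 10, dropout = 0.2, se_reduction = 4,
                        se_position = c("after_conv", "between_lstm"),
                        seed = 1L) {
  se_position <- match.arg(se_position)
  if (!name %in% model_names())
    stop_bad("unknown model '", name, "'; available: ",
             paste(model_names(), collapse = ", "))
  check_scalar_num(lookback, "lookback", 2)

  layers <- with_seed(derive_seed(seed, paste0("init-", name)), {
    if (name == "LSM") {
      list()
    } else if (name == "BP") {
      list(layer_dense(lookback, 64), layer_relu(),
           layer_dense(64, 32), layer_relu(),
           layer_dense(32, 1))
    } else if (name == "GRU") {
      list(layer_seq_reshape(), layer_gru(1, 64, activation = "relu"),
           layer_dense(64, 1))
    } else if (name == "LSTM") {
      list(layer_seq_reshape(), layer_lstm(1, 8, return_sequences = FALSE),
           layer_dense(8, 1))
    } else if (name == "CNN") {
      t_out <- (lookback - 3 + 1) %/% 2
      list(layer_seq_reshape(), layer_conv1d(1, 64, 3), layer_relu(),
           layer_maxpool1d(2), layer_flatten(),
           layer_dense(t_out * 64, 1))
    } else if (name == "TCN") {
      t1 <- lookback                 # causal conv keeps length
      t2 <- (t1 - 2) %/% 2           # conv k=3 valid, pool 2
      t3 <- (t2 - 2) %/% 2
      if (t3 < 1) stop_bad("lookback too short for the TCN stack")
      list(layer_seq_reshape(),
           layer_conv1d(1, 32, 3, padding = "causal"), layer_relu(),
           layer_conv1d(32, 32, 3), layer_relu(), layer_maxpool1d(2),
           layer_conv1d(32, 32, 3), layer_relu(), layer_maxpool1d(2),
           layer_flatten(), layer_dense(t3 * 32, 1))
    } else {  # CNN-LSTM family
      with_se <- name %in% c("CNN-SE-LSTM", "FTA-CNN-SE-LSTM")
      base <- list(layer_seq_reshape(), layer_conv1d(1, 64, 3), layer_relu(),
                   layer_maxpool1d(2))
      if (with_se && se_position == "after_conv")
        base <- c(base, list(layer_se_block(64, se_reduction)))
      base <- c(base, list(layer_lstm(64, 64, return_sequences = TRUE),
                           layer_dropout(dropout)))
      if (with_se && se_position == "between_lstm")
        base <- c(base, list(layer_se_block(64, se_reduction)))
      c(base, list(layer_lstm(64, 32, return_sequences = FALSE),
                   layer_dropout(dropout),
                   layer_dense(32, 1)))
    }
  })

  structure(list(name = name, lookback = as.integer(lookback),
                 layers = layers, seed = as.integer(seed),
                 trained = FALSE,
                 lsm_coef = NULL),
            class = "grain_net")
}

#' @export
print.grain_net <- function(x, ...) {
  cat(sprintf("<grain_net> %s (lookback %d, %s, %d parameters)\n",
              x$name, x$lookback,
              if (x$trained) "trained" else "untrained",
              count_parameters(x)))
  for (l in x$layers) cat("  -", layer_describe(l), "\n")
  invisible(x)
}

layer_describe <- function(l) {
  switch(l$type,
    seq_reshape = "reshape [B,L] -> [B,L,1]",
    conv1d = sprintf("conv1d %d->%d ch, k=%d, %s", l$in_channels,
                     l$out_channels, l$kernel_size, l$padding),
    relu = "relu",
    maxpool1d = sprintf("maxpool1d pool=%d", l$pool_size),
    se_block = sprintf("SE block C=%d, r=%d", l$channels, l$reduction),
    lstm = sprintf("lstm %d->%d%s", l$input_size, l$hidden_size,
                   if (l$return_sequences) " (sequences)" else ""),
    gru = sprintf("gru %d->%d (%s)", l$input_size, l$hidden_size, l$activation),
    dropout = sprintf("dropout %.2f", l$rate),
    flatten = "flatten",
    dense = sprintf("dense %d->%d", l$input_size, l$output_size),
    l$type)
}

#' Number of trainable parameters of a network
#' @param net a `grain_net`.
#' @export
count_parameters <- function(net) {
  if (net$name == "LSM") return(net$lookback + 1L)
  sum(vapply(net$layers, function(l)
    sum(vapply(l$params, length, integer(1)), 0L), numeric(1)))
}

# Forward pass through the whole network: X is [B, lookback]; returns
# list(pred [B], caches) — caches only kept when backward = TRUE.
net_forward <- function(net, X, train = FALSE, keep_caches = FALSE) {
  a <- X
  caches <- if (keep_caches) vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    r <- nn_forward(net$layers[[i]], a, train = train)
    a <- r$out
    if (keep_caches) caches[[i]] <- r$cache
  }
  list(pred = as.numeric(a), caches = caches)
}

# Backward pass: dpred is [B] gradient of loss w.r.t. predictions.
# Returns list of per-layer grads (shaped like each layer's params).
net_backward <- function(net, dpred, caches) {
  grads <- vector("list", length(net$layers))
  dout <- matrix(dpred, ncol = 1)
  for (i in rev(seq_along(net$layers))) {
    r <- nn_backward(net$layers[[i]], dout, caches[[i]])
    grads[[i]] <- r$grads
    dout <- r$dx
  }
  grads
}
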