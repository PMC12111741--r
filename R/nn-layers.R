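# Neural-network building blocks, implemented from first principles on base R
# matrices. Sequence activations are 3-D arrays [batch, time, channels]; flat
# activations are matrices [batch, features]. Every layer provides a forward
# pass returning (out, cache) and a backward pass returning (dx, grads) with
# grads shaped exactly like the layer's params, so a generic Adam loop can
# drive any architecture. Analytic gradients are verified against numerical
# differentiation in the test suite.

glorot <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

slice_t <- function(x, t) {
  # [B, T, C] -> [B, C] at time t, robust to B == 1
  matrix(x[, t, ], nrow = dim(x)[1])
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- constructors ---------------------------------------------------------

layer_seq_reshape <- function() list(type = "seq_reshape", params = list())

layer_conv1d <- function(in_channels, out_channels, kernel_size,
                         padding = c("valid", "causal")) {
  padding <- match.arg(padding)
  lim <- sqrt(6 / (kernel_size * in_channels + out_channels))
  W <- array(stats::runif(kernel_size * in_channels * out_channels, -lim, lim),
             c(kernel_size, in_channels, out_channels))
  list(type = "conv1d", params = list(W = W, b = numeric(out_channels)),
       kernel_size = kernel_size, in_channels = in_channels,
       out_channels = out_channels, padding = padding)
}

layer_relu <- function() list(type = "relu", params = list())

layer_maxpool1d <- function(pool_size = 2) {
  stopifnot(pool_size >= 1)
  list(type = "maxpool1d", params = list(), pool_size = pool_size)
}

layer_se_block <- function(channels, reduction = 4) {
  if (channels %% reduction != 0)
    stop_bad("SE block: channels must be divisible by the reduction ratio")
  mid <- channels %/% reduction
  list(type = "se_block",
       params = list(W1 = glorot(mid, channels), W2 = glorot(channels, mid)),
       channels = channels, reduction = reduction)
}

layer_lstm <- function(input_size, hidden_size, return_sequences = FALSE) {
  # gate order in the concatenated weight blocks: i, f, o, g (candidate)
  b <- numeric(4 * hidden_size)
  b[(hidden_size + 1):(2 * hidden_size)] <- 1  # forget-gate bias init
  list(type = "lstm",
       params = list(Wx = glorot(input_size, 4 * hidden_size),
                     Wh = glorot(hidden_size, 4 * hidden_size),
                     b = b),
       input_size = input_size, hidden_size = hidden_size,
       return_sequences = return_sequences)
}

layer_gru <- function(input_size, hidden_size, activation = c("relu", "tanh")) {
  activation <- match.arg(activation)
  # gate order: z (update), r (reset), n (candidate)
  list(type = "gru",
       params = list(Wx = glorot(input_size, 3 * hidden_size),
                     Wh = glorot(hidden_size, 3 * hidden_size),
                     b = numeric(3 * hidden_size)),
       input_size = input_size, hidden_size = hidden_size,
       activation = activation)
}

layer_dropout <- function(rate = 0.2) {
  stopifnot(rate >= 0, rate < 1)
  list(type = "dropout", params = list(), rate = rate)
}

layer_flatten <- function() list(type = "flatten", params = list())

layer_dense <- function(input_size, output_size) {
  list(type = "dense",
       params = list(W = glorot(input_size, output_size),
                     b = numeric(output_size)),
       input_size = input_size, output_size = output_size)
}

## ---- forward --------------------------------------------------------------

nn_forward <- function(layer, x, train = FALSE) {
  switch(layer$type,
    seq_reshape = {
      out <- array(x, c(nrow(x), ncol(x), 1L))
      list(out = out, cache = dim(x))
    },
    conv1d = {
      k <- layer$kernel_size
      if (layer$padding == "causal") {
        d <- dim(x)
        xp <- array(0, c(d[1], d[2] + k - 1L, d[3]))
        xp[, k:(d[2] + k - 1L), ] <- x
        x_in <- xp
      } else x_in <- x
      d <- dim(x_in)
      t_out <- d[2] - k + 1L
      if (t_out < 1) stop_bad("conv1d: input shorter than kernel")
      out <- array(0, c(d[1], t_out, layer$out_channels))
      for (j in seq_len(k)) {
        Wj <- matrix(layer$params$W[j, , ], nrow = layer$in_channels)
        for (t in seq_len(t_out))
          out[, t, ] <- out[, t, ] + slice_t(x_in, t + j - 1L) %*% Wj
      }
      out <- sweep(out, 3, layer$params$b, "+")
      list(out = out, cache = list(x_in = x_in, t_out = t_out))
    },
    relu = list(out = pmax(x, 0), cache = x > 0),
    maxpool1d = {
      d <- dim(x); p <- layer$pool_size
      t_out <- d[2] %/% p
      if (t_out < 1) stop_bad("maxpool1d: input shorter than pool size")
      out <- array(-Inf, c(d[1], t_out, d[3]))
      argmax <- array(1L, c(d[1], t_out, d[3]))
      for (j in seq_len(t_out)) {
        for (o in seq_len(p)) {
          cand <- slice_t(x, (j - 1L) * p + o)
          better <- cand > matrix(out[, j, ], nrow = d[1])
          out[, j, ][better] <- cand[better]
          argmax[, j, ][better] <- o
        }
      }
      list(out = out, cache = list(argmax = argmax, dim_in = d))
    },
    se_block = {
      d <- dim(x)
      z <- matrix(0, d[1], d[3])
      for (t in seq_len(d[2])) z <- z + slice_t(x, t)
      z <- z / d[2]
      a1 <- z %*% t(layer$params$W1)
      h1 <- pmax(a1, 0)
      a2 <- h1 %*% t(layer$params$W2)
      s <- sigmoid(a2)
      out <- x
      for (t in seq_len(d[2])) out[, t, ] <- slice_t(x, t) * s
      list(out = out, cache = list(x = x, z = z, a1 = a1, h1 = h1, s = s))
    },
    lstm = {
      d <- dim(x); B <- d[1]; T <- d[2]; h <- layer$hidden_size
      Wx <- layer$params$Wx; Wh <- layer$params$Wh; b <- layer$params$b
      hs <- matrix(0, B, h); cs <- matrix(0, B, h)
      steps <- vector("list", T)
      seq_out <- if (layer$return_sequences) array(0, c(B, T, h))
      for (t in seq_len(T)) {
        xt <- slice_t(x, t)
        a <- xt %*% Wx + hs %*% Wh + rep(b, each = B)
        i <- sigmoid(a[, 1:h, drop = FALSE])
        f <- sigmoid(a[, (h + 1):(2 * h), drop = FALSE])
        o <- sigmoid(a[, (2 * h + 1):(3 * h), drop = FALSE])
        g <- tanh(a[, (3 * h + 1):(4 * h), drop = FALSE])
        c_new <- f * cs + i * g
        tc <- tanh(c_new)
        h_new <- o * tc
        steps[[t]] <- list(xt = xt, h_prev = hs, c_prev = cs, i = i, f = f,
                           o = o, g = g, c = c_new, tc = tc)
        hs <- h_new; cs <- c_new
        if (layer$return_sequences) seq_out[, t, ] <- h_new
      }
      out <- if (layer$return_sequences) seq_out else hs
      list(out = out, cache = list(steps = steps, B = B, T = T))
    },
    gru = {
      d <- dim(x); B <- d[1]; T <- d[2]; h <- layer$hidden_size
      Wx <- layer$params$Wx; Wh <- layer$params$Wh; b <- layer$params$b
      act <- if (layer$activation == "relu") function(v) pmax(v, 0) else tanh
      hs <- matrix(0, B, h)
      steps <- vector("list", T)
      for (t in seq_len(T)) {
        xt <- slice_t(x, t)
        ax <- xt %*% Wx
        ahz <- hs %*% Wh[, 1:h, drop = FALSE]
        ahr <- hs %*% Wh[, (h + 1):(2 * h), drop = FALSE]
        z <- sigmoid(ax[, 1:h, drop = FALSE] + ahz + rep(b[1:h], each = B))
        r <- sigmoid(ax[, (h + 1):(2 * h), drop = FALSE] + ahr +
                       rep(b[(h + 1):(2 * h)], each = B))
        m <- hs %*% Wh[, (2 * h + 1):(3 * h), drop = FALSE]
        an <- ax[, (2 * h + 1):(3 * h), drop = FALSE] + r * m +
          rep(b[(2 * h + 1):(3 * h)], each = B)
        n <- act(an)
        h_new <- (1 - z) * n + z * hs
        steps[[t]] <- list(xt = xt, h_prev = hs, z = z, r = r, m = m,
                           an = an, n = n)
        hs <- h_new
      }
      list(out = hs, cache = list(steps = steps, B = B, T = T))
    },
    dropout = {
      if (!train || layer$rate == 0) return(list(out = x, cache = NULL))
      keep <- 1 - layer$rate
      mask <- array(stats::rbinom(length(x), 1L, keep) / keep,
                    dim = dim(x) %||% length(x))
      list(out = x * mask, cache = mask)
    },
    flatten = {
      d <- dim(x)
      list(out = matrix(x, d[1], prod(d[-1])), cache = d)
    },
    dense = list(out = x %*% layer$params$W + rep(layer$params$b, each = nrow(x)),
                 cache = x),
    stop_bad("unknown layer type: ", layer$type)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- backward -------------------------------------------------------------

nn_backward <- function(layer, dout, cache) {
  switch(layer$type,
    seq_reshape = list(dx = matrix(dout, cache[1], cache[2]), grads = list()),
    conv1d = {
      x_in <- cache$x_in; t_out <- cache$t_out
      k <- layer$kernel_size; d <- dim(x_in)
      dW <- array(0, dim(layer$params$W))
      db <- numeric(layer$out_channels)
      dxp <- array(0, d)
      for (t in seq_len(t_out)) {
        dt <- slice_t(dout, t)
        db <- db + colSums(dt)
        for (j in seq_len(k)) {
          xs <- slice_t(x_in, t + j - 1L)
          dW[j, , ] <- dW[j, , ] + t(xs) %*% dt
          dxp[, t + j - 1L, ] <- dxp[, t + j - 1L, ] +
            dt %*% t(matrix(layer$params$W[j, , ], nrow = layer$in_channels))
        }
      }
      dx <- if (layer$padding == "causal")
        dxp[, k:d[2], , drop = FALSE] else dxp
      list(dx = dx, grads = list(W = dW, b = db))
    },
    relu = list(dx = dout * cache, grads = list()),
    maxpool1d = {
      d <- cache$dim_in; p <- layer$pool_size
      t_out <- dim(dout)[2]
      dx <- array(0, d)
      for (j in seq_len(t_out)) {
        for (o in seq_len(p)) {
          sel <- matrix(cache$argmax[, j, ], nrow = d[1]) == o
          contrib <- matrix(dout[, j, ], nrow = d[1]) * sel
          dx[, (j - 1L) * p + o, ] <- dx[, (j - 1L) * p + o, ] + contrib
        }
      }
      list(dx = dx, grads = list())
    },
    se_block = {
      x <- cache$x; s <- cache$s; d <- dim(x)
      dx <- x  # same shape
      ds <- matrix(0, d[1], d[3])
      for (t in seq_len(d[2])) {
        dt <- slice_t(dout, t)
        dx[, t, ] <- dt * s
        ds <- ds + dt * slice_t(x, t)
      }
      da2 <- ds * s * (1 - s)
      dW2 <- t(da2) %*% cache$h1
      dh1 <- da2 %*% layer$params$W2
      da1 <- dh1 * (cache$a1 > 0)
      dW1 <- t(da1) %*% cache$z
      dz <- da1 %*% layer$params$W1
      for (t in seq_len(d[2])) dx[, t, ] <- dx[, t, ] + dz / d[2]
      list(dx = dx, grads = list(W1 = dW1, W2 = dW2))
    },
    lstm = {
      B <- cache$B; T <- cache$T; h <- layer$hidden_size
      Wx <- layer$params$Wx; Wh <- layer$params$Wh
      dWx <- array(0, dim(Wx)); dWh <- array(0, dim(Wh))
      db <- numeric(4 * h)
      dx <- array(0, c(B, T, layer$input_size))
      dh_next <- matrix(0, B, h); dc_next <- matrix(0, B, h)
      for (t in rev(seq_len(T))) {
        st <- cache$steps[[t]]
        dh <- dh_next
        if (layer$return_sequences) dh <- dh + slice_t(dout, t)
        else if (t == T) dh <- dh + dout
        do_ <- dh * st$tc
        dc <- dc_next + dh * st$o * (1 - st$tc^2)
        di <- dc * st$g
        df <- dc * st$c_prev
        dg <- dc * st$i
        da <- cbind(di * st$i * (1 - st$i),
                    df * st$f * (1 - st$f),
                    do_ * st$o * (1 - st$o),
                    dg * (1 - st$g^2))
        dWx <- dWx + t(st$xt) %*% da
        dWh <- dWh + t(st$h_prev) %*% da
        db <- db + colSums(da)
        dx[, t, ] <- da %*% t(Wx)
        dh_next <- da %*% t(Wh)
        dc_next <- dc * st$f
      }
      list(dx = dx, grads = list(Wx = dWx, Wh = dWh, b = db))
    },
    gru = {
      B <- cache$B; T <- cache$T; h <- layer$hidden_size
      Wx <- layer$params$Wx; Wh <- layer$params$Wh
      Whz <- Wh[, 1:h, drop = FALSE]
      Whr <- Wh[, (h + 1):(2 * h), drop = FALSE]
      Whn <- Wh[, (2 * h + 1):(3 * h), drop = FALSE]
      dWx <- array(0, dim(Wx)); dWh <- array(0, dim(Wh))
      db <- numeric(3 * h)
      dx <- array(0, c(B, T, layer$input_size))
      dh_next <- dout  # gradient w.r.t. final hidden state
      for (t in rev(seq_len(T))) {
        st <- cache$steps[[t]]
        dh <- dh_next
        dz <- dh * (st$h_prev - st$n)
        dn <- dh * (1 - st$z)
        dh_prev <- dh * st$z
        dan <- if (layer$activation == "relu") dn * (st$an > 0)
               else dn * (1 - st$n^2)
        dr <- dan * st$m
        dm <- dan * st$r
        dh_prev <- dh_prev + dm %*% t(Whn)
        daz <- dz * st$z * (1 - st$z)
        dar <- dr * st$r * (1 - st$r)
        da <- cbind(daz, dar, dan)
        dWx <- dWx + t(st$xt) %*% da
        dWh[, 1:h] <- dWh[, 1:h] + t(st$h_prev) %*% daz
        dWh[, (h + 1):(2 * h)] <- dWh[, (h + 1):(2 * h)] + t(st$h_prev) %*% dar
        dWh[, (2 * h + 1):(3 * h)] <- dWh[, (2 * h + 1):(3 * h)] +
          t(st$h_prev) %*% dm
        db <- db + colSums(da)
        dx[, t, ] <- da %*% t(Wx)
        dh_next <- dh_prev + daz %*% t(Whz) + dar %*% t(Whr)
      }
      list(dx = dx, grads = list(Wx = dWx, Wh = dWh, b = db))
    },
    dropout = {
      if (is.null(cache)) list(dx = dout, grads = list())
      else list(dx = dout * cache, grads = list())
    },
    flatten = list(dx = array(dout, cache), grads = list()),
    dense = list(dx = dout %*% t(layer$params$W),
                 grads = list(W = t(cache) %*% dout, b = colSums(dout))),
    stop_bad("unknown layer type: ", layer$type)
  )
}

## ---- single-block convenience wrappers (spec surface) ---------------------

#' LSTM cell forward step
#'
#' One step of the standard LSTM cell: candidate
#' `g = tanh(Wcx x + Wch h + bc)`, gates `i, f, o` through sigmoids, cell
#' update `c_t = f * c_prev + i * g`, output `h_t = o * tanh(c_t)`.
#' Weights are given per gate as in the usual textbook statement.
#'
#' @param x_t input vector (length d).
#' @param h_prev,c_prev previous hidden / cell state (length h).
#' @param params list with `Wix, Wfx, Wox, Wcx` (h x d), `Wih, Wfh, Woh, Wch`
#'   (h x h), and biases `bi, bf, bo, bc` (length h).
#' @return List `(h, c)` after the step.
#' @export
lstm_cell_forward <- function(x_t, h_prev, c_prev, params) {
  p <- params
  need <- c("Wix", "Wfx", "Wox", "Wcx", "Wih", "Wfh", "Woh", "Wch",
            "bi", "bf", "bo", "bc")
  if (!all(need %in% names(p)))
    stop_bad("params must contain: ", paste(need, collapse = ", "))
  g <- tanh(p$Wcx %*% x_t + p$Wch %*% h_prev + p$bc)
  i <- sigmoid(p$Wix %*% x_t + p$Wih %*% h_prev + p$bi)
  f <- sigmoid(p$Wfx %*% x_t + p$Wfh %*% h_prev + p$bf)
  o <- sigmoid(p$Wox %*% x_t + p$Woh %*% h_prev + p$bo)
  c_t <- f * c_prev + i * g
  h_t <- o * tanh(c_t)
  list(h = as.numeric(h_t), c = as.numeric(c_t))
}

#' 1-D convolution, ReLU and max-pooling primitives
#'
#' `conv1d_forward` computes the valid cross-correlation of a single-channel
#' signal with each kernel row plus bias (output length `L - k + 1`);
#' `relu` is the element-wise rectifier `max(0, x)`; `maxpool1d` takes the
#' maximum over non-overlapping regions of `pool_size` (a trailing
#' remainder shorter than the pool is truncated).
#'
#' @param x numeric vector.
#' @param kernels matrix (n_kernels x k) or vector (one kernel).
#' @param bias numeric vector, one per kernel (default 0).
#' @param pool_size positive integer region size.
#' @return `conv1d_forward`: matrix (n_kernels x (L-k+1)); `relu`: vector;
#'   `maxpool1d`: vector of region maxima.
#' @export
conv1d_forward <- function(x, kernels, bias = NULL) {
  if (is.null(dim(kernels))) kernels <- matrix(kernels, nrow = 1)
  k <- ncol(kernels)
  L <- length(x)
  if (L < k) stop_bad("input shorter than kernel")
  if (is.null(bias)) bias <- numeric(nrow(kernels))
  out <- matrix(0, nrow(kernels), L - k + 1L)
  for (t in seq_len(L - k + 1L))
    out[, t] <- kernels %*% x[t:(t + k - 1L)] + bias
  out
}

#' @rdname conv1d_forward
#' @export
relu <- function(x) pmax(x, 0)

#' @rdname conv1d_forward
#' @export
maxpool1d <- function(x, pool_size) {
  if (pool_size < 1) stop_bad("pool_size must be >= 1")
  if (length(x) < pool_size) stop_bad("input shorter than pool size")
  n_out <- length(x) %/% pool_size
  vapply(seq_len(n_out), function(j)
    max(x[((j - 1L) * pool_size + 1L):(j * pool_size)]), numeric(1))
}

#' Squeeze-and-excitation forward pass
#'
#' Channel attention for a `C x T` feature map: squeeze `z_c` = temporal
#' mean of channel `c`; excitation `s = sigmoid(W2 relu(W1 z))`; scale:
#' channel `c` multiplied by `s_c`. Every channel weight lies strictly in
#' (0, 1).
#'
#' @param u feature map, matrix C x T (channels in rows).
#' @param W1 matrix (C/r x C); `W2` matrix (C x C/r).
#' @param W2 see `W1`.
#' @return List `out` (recalibrated C x T map), `scale` (vector s), `z`.
#' @export
se_block_forward <- function(u, W1, W2) {
  if (!is.matrix(u)) stop_bad("u must be a C x T matrix")
  C <- nrow(u)
  if (ncol(W1) != C || nrow(W2) != C || nrow(W1) != ncol(W2))
    stop_bad("W1 must be (C/r x C) and W2 (C x C/r)")
  z <- rowMeans(u)
  s <- as.numeric(sigmoid(W2 %*% pmax(W1 %*% z, 0)))
  list(out = u * s, scale = s, z = z)
}

#' Softmax over a numeric vector
#'
#' Standard multinomial output transform `p_j = exp(y_j) / sum_k exp(y_k)`,
#' provided as a standalone function; the forecasting models all use a
#' linear regression head instead.
#'
#' @param y numeric vector.
#' @return probability vector summing to 1.
#' @export
softmax <- function(y) {
  e <- exp(y - max(y))
  e / sum(e)
}
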