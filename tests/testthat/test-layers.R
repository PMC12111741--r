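test_that("LSTM cell follows the gate algebra in closed-form cases", {
  d <- 2; h <- 3
  zeros <- list(Wix = matrix(0, h, d), Wfx = matrix(0, h, d),
                Wox = matrix(0, h, d), Wcx = matrix(0, h, d),
                Wih = matrix(0, h, h), Wfh = matrix(0, h, h),
                Woh = matrix(0, h, h), Wch = matrix(0, h, h),
                bi = numeric(h), bf = numeric(h), bo = numeric(h),
                bc = numeric(h))
  r <- lstm_cell_forward(c(1, -1), numeric(h), numeric(h), zeros)
  expect_equal(r$h, numeric(h))
  expect_equal(r$c, numeric(h))

  # zero weights, nonzero previous cell: c' = 0.5 c, h' = 0.5 tanh(0.5 c)
  cp <- c(0.4, -1.2, 2)
  r2 <- lstm_cell_forward(c(1, -1), numeric(h), cp, zeros)
  expect_equal(r2$c, 0.5 * cp, tolerance = 1e-12)
  expect_equal(r2$h, 0.5 * tanh(0.5 * cp), tolerance = 1e-12)
})

test_that("LSTM cell matches an independent scalar-loop oracle", {
  set.seed(31)
  for (i in 1:30) {
    d <- sample(1:4, 1); h <- sample(1:5, 1)
    p <- random_lstm_params(d, h)
    x <- rnorm(d); h0 <- rnorm(h); c0 <- rnorm(h)
    got <- lstm_cell_forward(x, h0, c0, p)
    want <- lstm_oracle(x, h0, c0, p)
    expect_equal(got$h, want$h, tolerance = 1e-9)
    expect_equal(got$c, want$c, tolerance = 1e-9)
  }
})

test_that("batched LSTM layer agrees with stepwise cell application", {
  set.seed(32)
  B <- 4; T <- 5; d <- 3; h <- 6
  layer <- graintemp:::layer_lstm(d, h, return_sequences = FALSE)
  x <- array(rnorm(B * T * d), c(B, T, d))
  out <- graintemp:::nn_forward(layer, x)$out

  Wx <- layer$params$Wx; Wh <- layer$params$Wh; b <- layer$params$b
  # re-package the concatenated weights as per-gate matrices for the oracle
  gate <- function(g) ((g - 1) * h + 1):(g * h)
  for (bi in seq_len(B)) {
    p <- list(Wix = t(Wx[, gate(1), drop = FALSE]), Wih = t(Wh[, gate(1), drop = FALSE]),
              Wfx = t(Wx[, gate(2), drop = FALSE]), Wfh = t(Wh[, gate(2), drop = FALSE]),
              Wox = t(Wx[, gate(3), drop = FALSE]), Woh = t(Wh[, gate(3), drop = FALSE]),
              Wcx = t(Wx[, gate(4), drop = FALSE]), Wch = t(Wh[, gate(4), drop = FALSE]),
              bi = b[gate(1)], bf = b[gate(2)], bo = b[gate(3)], bc = b[gate(4)])
    hs <- numeric(h); cs <- numeric(h)
    for (t in seq_len(T)) {
      st <- lstm_cell_forward(x[bi, t, ], hs, cs, p)
      hs <- st$h; cs <- st$c
    }
    expect_equal(as.numeric(out[bi, ]), hs, tolerance = 1e-9)
  }
})

test_that("conv, relu and maxpool primitives match hand evaluation", {
  expect_equal(as.numeric(conv1d_forward(c(5, -2, 7), 1)), c(5, -2, 7))
  expect_equal(as.numeric(conv1d_forward(1:4, c(1, -1))), c(-1, -1, -1))
  expect_equal(as.numeric(conv1d_forward(1:4, c(1, -1), bias = 10)),
               c(9, 9, 9))
  km <- rbind(c(1, 0), c(0, 1))
  expect_equal(conv1d_forward(1:4, km), rbind(1:3, 2:4))
  expect_error(conv1d_forward(c(1), c(1, 2)), "shorter")

  expect_equal(relu(c(-1, 2)), c(0, 2))
  expect_equal(maxpool1d(c(3, 1, 4, 1, 5, 9), 2), c(3, 4, 9))
  expect_equal(maxpool1d(c(3, 1, 4, 1, 5, 9, 100), 2), c(3, 4, 9))  # truncation
  expect_error(maxpool1d(c(1), 2), "shorter")
})

test_that("SE block squeezes, excites and rescales as defined", {
  C <- 4; Tn <- 6; r <- 2
  u <- matrix(rnorm(C * Tn), C, Tn)
  z0 <- se_block_forward(u, matrix(0, C / r, C), matrix(0, C, C / r))
  expect_equal(z0$scale, rep(0.5, C))
  expect_equal(z0$out, 0.5 * u)

  uc <- matrix(rep(c(1.5, -2, 0, 7), Tn), C, Tn)
  W1 <- matrix(rnorm(C / r * C), C / r, C); W2 <- matrix(rnorm(C * C / r), C, C / r)
  expect_equal(se_block_forward(uc, W1, W2)$z, c(1.5, -2, 0, 7))

  set.seed(33)
  for (i in 1:30) {
    u <- matrix(rnorm(C * Tn, sd = 2), C, Tn)
    W1 <- matrix(rnorm(C / r * C), C / r, C)
    W2 <- matrix(rnorm(C * C / r), C, C / r)
    got <- se_block_forward(u, W1, W2)
    want <- se_oracle(u, W1, W2)
    expect_equal(got$out, want$out, tolerance = 1e-9)
    expect_equal(got$scale, want$scale, tolerance = 1e-9)
    expect_true(all(got$scale > 0 & got$scale < 1))
  }
  expect_error(se_block_forward(u, matrix(0, 3, 5), W2), "W1")
})

test_that("batched SE layer agrees with the matrix-form oracle", {
  set.seed(34)
  layer <- graintemp:::layer_se_block(8, 4)
  B <- 3; T <- 5
  x <- array(rnorm(B * T * 8), c(B, T, 8))
  out <- graintemp:::nn_forward(layer, x)$out
  for (bi in seq_len(B)) {
    u <- t(matrix(x[bi, , ], T, 8))  # C x T
    want <- se_block_forward(u, layer$params$W1, layer$params$W2)$out
    expect_equal(t(matrix(out[bi, , ], T, 8)), want, tolerance = 1e-9)
  }
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(35)
  X <- matrix(rnorm(3 * 10), 3, 10)
  y <- rnorm(3)
  loss_of <- function(net) {
    mean((graintemp:::net_forward(net, X)$pred - y)^2)
  }
  for (nm in c("BP", "CNN", "TCN", "GRU", "LSTM", "CNN-SE-LSTM")) {
    net <- build_model(nm, lookback = 10, dropout = 0, seed = 77)
    fw <- graintemp:::net_forward(net, X, keep_caches = TRUE)
    grads <- graintemp:::net_backward(net, 2 * (fw$pred - y) / 3, fw$caches)
    eps <- 1e-5
    for (li in seq_along(net$layers)) {
      for (p in names(net$layers[[li]]$params)) {
        w <- net$layers[[li]]$params[[p]]
        for (k in sample(length(w), min(4, length(w)))) {
          n1 <- net; n1$layers[[li]]$params[[p]][k] <- w[k] + eps
          n2 <- net; n2$layers[[li]]$params[[p]][k] <- w[k] - eps
          num <- (loss_of(n1) - loss_of(n2)) / (2 * eps)
          ana <- grads[[li]][[p]][k]
          expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-3)
        }
      }
    }
  }
})

test_that("softmax is a probability distribution and shift-invariant", {
  p <- softmax(c(1, 2, 3))
  expect_equal(sum(p), 1)
  expect_equal(p, softmax(c(1, 2, 3) + 100), tolerance = 1e-12)
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
})
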