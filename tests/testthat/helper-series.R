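# Shared fixtures: all built in code at test time.

make_series <- function(values, cadence_hours = 24, label = "test",
                        start = "2024-01-01") {
  ts <- as.POSIXct(start, tz = "UTC") +
    (seq_along(values) - 1) * cadence_hours * 3600
  grain_series(ts, values, cadence_hours, label)
}

# A smooth seasonal daily series with a known composition.
make_seasonal_series <- function(n_days = 120, baseline = 5, amplitude = 10,
                                 period = 60, noise_sd = 0, seed = 1) {
  t <- seq_len(n_days) - 1
  v <- baseline + amplitude * sin(2 * pi * t / period)
  if (noise_sd > 0) {
    set.seed(seed)
    v <- v + rnorm(n_days, 0, noise_sd)
  }
  make_series(v)
}

# Independent O(N^2) evaluation of the forward DFT definition.
direct_dft <- function(x) {
  N <- length(x)
  vapply(0:(N - 1), function(k)
    sum(x * exp(-2i * pi * (0:(N - 1)) * k / N)), complex(1))
}

# Scalar-loop oracle of the LSTM gate algebra, one unit at a time.
lstm_oracle <- function(x_t, h_prev, c_prev, p) {
  h <- length(h_prev)
  sig <- function(v) 1 / (1 + exp(-v))
  h_out <- numeric(h); c_out <- numeric(h)
  for (u in seq_len(h)) {
    g <- tanh(sum(p$Wcx[u, ] * x_t) + sum(p$Wch[u, ] * h_prev) + p$bc[u])
    i <- sig(sum(p$Wix[u, ] * x_t) + sum(p$Wih[u, ] * h_prev) + p$bi[u])
    f <- sig(sum(p$Wfx[u, ] * x_t) + sum(p$Wfh[u, ] * h_prev) + p$bf[u])
    o <- sig(sum(p$Wox[u, ] * x_t) + sum(p$Woh[u, ] * h_prev) + p$bo[u])
    c_out[u] <- f * c_prev[u] + i * g
    h_out[u] <- o * tanh(c_out[u])
  }
  list(h = h_out, c = c_out)
}

random_lstm_params <- function(d, h) {
  m <- function(r, c) matrix(rnorm(r * c), r, c)
  list(Wix = m(h, d), Wfx = m(h, d), Wox = m(h, d), Wcx = m(h, d),
       Wih = m(h, h), Wfh = m(h, h), Woh = m(h, h), Wch = m(h, h),
       bi = rnorm(h), bf = rnorm(h), bo = rnorm(h), bc = rnorm(h))
}

# Scalar-loop oracle of the squeeze-excitation-scale chain.
se_oracle <- function(u, W1, W2) {
  C <- nrow(u); Tn <- ncol(u)
  sig <- function(v) 1 / (1 + exp(-v))
  z <- numeric(C)
  for (c in seq_len(C)) z[c] <- sum(u[c, ]) / Tn
  a1 <- numeric(nrow(W1))
  for (j in seq_len(nrow(W1))) a1[j] <- max(0, sum(W1[j, ] * z))
  s <- numeric(C)
  for (c in seq_len(C)) s[c] <- sig(sum(W2[c, ] * a1))
  out <- u
  for (c in seq_len(C)) out[c, ] <- s[c] * u[c, ]
  list(out = out, scale = s, z = z)
}
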