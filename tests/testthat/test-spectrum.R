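test_that("forward DFT matches hand-evaluated and degenerate cases", {
  s <- make_series(rep(3, 8))
  sp <- dft_forward(s)
  amp <- spectrum_amplitude(sp)
  expect_equal(amp[1], 24, tolerance = 1e-12)
  expect_true(all(amp[-1] < 1e-9))

  sp2 <- dft_forward(make_series(c(1, 0, -1, 0)))
  expect_equal(spectrum_amplitude(sp2), c(0, 2, 0, 2), tolerance = 1e-12)

  expect_error(dft_forward(inject_gaps(make_series(1:10), list(c(2, 1)))),
               "gap-free")
})

test_that("fast DFT equals the direct quadratic sum on random series", {
  set.seed(7)
  for (i in 1:30) {
    n <- sample(1:64, 1)
    s <- make_series(rnorm(n, sd = 5))
    got <- dft_forward(s)$coefficients
    want <- direct_dft(s$values)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("DFT satisfies conjugate symmetry and Parseval's identity", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(4:128, 1)
    x <- rnorm(n, sd = 3)
    sp <- dft_forward(make_series(x))
    co <- sp$coefficients
    ks <- 1:(n - 1)
    expect_equal(co[n - ks + 1], Conj(co[ks + 1]), tolerance = 1e-9)
    expect_equal(sum(x^2), sum(Mod(co)^2) / n, tolerance = 1e-9)
  }
})

test_that("inverse DFT round-trips and inverts hand spectra", {
  set.seed(9)
  s <- make_series(rnorm(50, 10, 4))
  expect_equal(dft_inverse(dft_forward(s))$values, s$values, tolerance = 1e-9)

  sp <- dft_forward(make_series(rep(0, 6)))
  sp$coefficients <- complex(real = c(6 * 2.5, rep(0, 5)))
  expect_equal(dft_inverse(sp)$values, rep(2.5, 6), tolerance = 1e-12)

  sp2 <- dft_forward(make_series(rep(0, 4)))
  sp2$coefficients <- complex(real = c(0, 2, 0, 2))
  expect_equal(dft_inverse(sp2)$values, c(1, 0, -1, 0), tolerance = 1e-12)
})

test_that("spectrum amplification scales non-DC amplitudes and keeps phases", {
  set.seed(10)
  s <- make_series(rnorm(40, 8, 2))
  sp <- dft_forward(s)

  ident <- amplify_spectrum(sp, 1.0)
  expect_equal(ident$coefficients, sp$coefficients)
  expect_equal(dft_inverse(ident)$values, s$values, tolerance = 1e-9)

  amp <- amplify_spectrum(sp, 1.2)
  expect_equal(Mod(amp$coefficients[-1]), 1.2 * Mod(sp$coefficients[-1]),
               tolerance = 1e-12)
  nz <- Mod(sp$coefficients[-1]) > 1e-9
  expect_equal(Arg(amp$coefficients[-1])[nz], Arg(sp$coefficients[-1])[nz],
               tolerance = 1e-12)
  expect_identical(amp$coefficients[1], sp$coefficients[1])
  expect_equal(mean(dft_inverse(amp)$values), mean(s$values), tolerance = 1e-9)

  # multiplicative composition on non-DC bins
  ab <- amplify_spectrum(amplify_spectrum(sp, 1.3), 1.5)
  once <- amplify_spectrum(sp, 1.3 * 1.5)
  expect_equal(ab$coefficients, once$coefficients, tolerance = 1e-12)

  dc <- amplify_spectrum(sp, 2, amplify_dc = TRUE)
  expect_equal(dc$coefficients[1], 2 * sp$coefficients[1])
  expect_error(amplify_spectrum(sp, 0), "> 0")
})

test_that("dominant periods recover planted sinusoids", {
  n <- 365
  t <- seq_len(n) - 1
  s <- make_series(sin(2 * pi * t / 365))  # daily cadence: fT = 1/day
  top <- dominant_periods(dft_forward(s), 1)
  expect_equal(top$k, 1)
  expect_equal(top$period_days, 365, tolerance = 1e-9)

  two <- make_series(3 * sin(2 * pi * 5 * t / n) + 1 * sin(2 * pi * 20 * t / n))
  top2 <- dominant_periods(dft_forward(two), 2)
  expect_equal(top2$k, c(5, 20))

  expect_error(dominant_periods(dft_forward(s), 0), ">= 1")
})

test_that("white-noise spectrum is flat: no bin dominates the median 3x", {
  set.seed(12)
  s <- make_series(rnorm(512))
  amp <- spectrum_amplitude(dft_forward(s))[2:256]
  expect_lt(max(amp), 3 * median(amp) * 2)  # generous statistical bound
  # the planted-signal contrast: a sinusoid does dominate
  sig <- make_series(rnorm(512, sd = 0.1) + sin(2 * pi * 10 * (1:512) / 512))
  amp2 <- spectrum_amplitude(dft_forward(sig))[2:256]
  expect_gt(max(amp2), 3 * median(amp2))
})

test_that("bin-to-frequency mapping is k * fT / N", {
  s <- make_series(rnorm(48), cadence_hours = 4)  # fT = 6 samples/day
  sp <- dft_forward(s)
  expect_equal(sp$sampling_frequency, 6)
  expect_equal(frequency_of(sp, 0:24), (0:24) * 6 / 48)
  expect_error(frequency_of(sp, 25), "N/2")
})
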