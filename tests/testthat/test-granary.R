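test_that("layout emits the full regular grid with stated spacings", {
  lay <- generate_layout(6, 10, 7)
  expect_equal(nrow(lay$coordinates), 420)
  expect_equal(sensor_count(lay), 420)

  one <- generate_layout(1, 1, 1)
  expect_equal(unlist(one$coordinates[1, c("x", "y", "z")], use.names = FALSE),
               c(0.5, 0.5, 0.5))

  lay2 <- generate_layout(2, 3, 4)
  co <- lay2$coordinates
  expect_equal(nrow(co), 24)
  # brute-force grid oracle
  expected <- expand.grid(row = 0:1, col = 0:2, layer = 0:3)
  expected$x <- 0.5 + expected$col * 5
  expected$y <- 0.5 + expected$row * 5
  expected$z <- 0.5 + expected$layer * 1.8
  got <- co[order(co$row, co$col, co$layer), c("row", "col", "layer", "x", "y", "z")]
  exp_o <- expected[order(expected$row, expected$col, expected$layer),
                    c("row", "col", "layer", "x", "y", "z")]
  expect_equal(unname(as.matrix(got)), unname(as.matrix(exp_o)))
  # adjacent horizontal neighbours exactly 5 m apart
  same <- co[co$row == 0 & co$layer == 0, ]
  same <- same[order(same$col), ]
  expect_equal(diff(same$x), rep(5, 2))

  expect_error(generate_layout(0, 1, 1), "positive integer")
  expect_error(generate_layout(3, 3, 3, envelope = c(10, 10, 2)), "envelope")
})

test_that("sensor_count is multiplicative in grid dimensions", {
  set.seed(11)
  for (i in 1:10) {
    d <- sample(1:8, 3, replace = TRUE)
    expect_equal(sensor_count(generate_layout(d[1], d[2], d[3])), prod(d))
  }
})

test_that("simulated field matches its closed-form signal model", {
  lay <- generate_layout(1, 1, 2)
  cfg <- simulation_config(duration_days = 10, annual_amplitude = 0,
                           daily_amplitude = 0, trend_slope = 0,
                           innovation_sd = 0, layer_gradient = 0,
                           baseline = 10)
  sims <- simulate_temperatures(lay, cfg)
  for (s in sims) expect_true(all(s$values == 10))

  # seasonal range: amplitude 17 around baseline 5 spans about -12..+22
  cfg2 <- simulation_config(duration_days = 365, cadence_hours = 24,
                            annual_amplitude = 17, baseline = 5,
                            daily_amplitude = 0, trend_slope = 0,
                            innovation_sd = 0, layer_gradient = 0,
                            layer_lag = 0)
  s <- simulate_temperatures(generate_layout(1, 1, 1), cfg2)[[1]]
  expect_equal(min(s$values), -12, tolerance = 1e-3)
  expect_equal(max(s$values), 22, tolerance = 1e-3)
})

test_that("simulation is seed-reproducible and seed-sensitive", {
  lay <- generate_layout(2, 2, 1)
  cfg <- simulation_config(duration_days = 20, seed = 42)
  a <- simulate_temperatures(lay, cfg)
  b <- simulate_temperatures(lay, cfg)
  for (i in seq_along(a)) expect_identical(a[[i]]$values, b[[i]]$values)
  cfg2 <- simulation_config(duration_days = 20, seed = 43)
  c <- simulate_temperatures(lay, cfg2)
  expect_false(identical(a[[1]]$values, c[[1]]$values))
})

test_that("noiseless simulation is exactly periodic after detrending", {
  cfg <- simulation_config(duration_days = 120, cadence_hours = 24,
                           annual_period_days = 30, annual_amplitude = 8,
                           daily_amplitude = 0, trend_slope = 0.05,
                           innovation_sd = 0)
  s <- simulate_temperatures(generate_layout(1, 1, 1), cfg)[[1]]
  P <- 30  # days = samples at daily cadence
  detrended <- s$values - 0.05 * (seq_along(s$values) - 1)
  expect_equal(detrended[1:(length(detrended) - P)],
               detrended[(P + 1):length(detrended)], tolerance = 1e-9)
})

test_that("gap injection blanks exactly the scheduled samples", {
  s <- make_series(seq_len(100))
  expect_identical(inject_gaps(s, list()), s)

  g <- inject_gaps(s, list(c(10, 5)))
  expect_equal(sum(is.na(g$values)), 5)
  expect_true(all(is.na(g$values[10:14])))
  expect_identical(g$values[-(10:14)], s$values[-(10:14)])

  expect_error(inject_gaps(s, list(c(98, 5))), "past the series end")
  expect_error(inject_gaps(s, list(c(1, 5), c(3, 2))), "overlap")
})

test_that("layer means equal a brute-force per-timestep average", {
  lay <- generate_layout(6, 10, 4)
  cfg <- simulation_config(duration_days = 10, seed = 9)
  sims <- simulate_temperatures(lay, cfg)
  layers <- attr(sims, "layer")

  lm3 <- layer_mean_series(sims, 3)
  sel <- which(layers == 3)
  expect_length(sel, 60)
  manual <- numeric(length(lm3))
  for (t in seq_along(manual)) {
    acc <- 0
    for (i in sel) acc <- acc + sims[[i]]$values[t]
    manual[t] <- acc / length(sel)
  }
  expect_equal(lm3$values, manual, tolerance = 1e-12)

  # single-sensor layer returns that sensor; constant sensors average exactly
  one <- list(make_series(rep(8, 5), label = "a"),
              make_series(rep(12, 5), label = "b"))
  expect_equal(layer_mean_series(one, 0, layers = c(0, 0))$values, rep(10, 5))
  expect_equal(layer_mean_series(one, 1, layers = c(1, 0))$values, rep(8, 5))
  expect_error(layer_mean_series(one, 5, layers = c(0, 0)), "no sensors")
})

test_that("layer mean skips missing values and is missing only when all are", {
  a <- make_series(c(1, NA, 3, NA))
  b <- make_series(c(3, 4, NA, NA))
  m <- layer_mean_series(list(a, b), 0, layers = c(0, 0))
  expect_equal(m$values, c(2, 4, 3, NA))
})
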