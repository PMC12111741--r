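# graintemp

Day-ahead forecasting of stored-grain temperature from granary sensor
records, with dual-domain (time + frequency) data augmentation for the
small-sample records typical of real warehouses.

Grain kept in bulk storage spoils — mold, insects, condensation — once the
pile warms past a safe threshold, so flat warehouses are instrumented with
temperature-measuring cables on a regular grid and operators forecast the
next day's temperature from the recent record. Those records are short and
gappy, which starves neural forecasters. This package implements a
complete pipeline for that setting, aimed at researchers in postharvest
monitoring and at anyone studying augmentation for small-sample time
series:

* **Synthetic granary simulator** — sensor-grid layouts (the canonical
  6 × 10 × 7 plan gives 420 points; 5 m / 1.8 m / 0.5 m spacings) and
  per-sensor temperature series from an additive model: annual + daily
  sinusoids, trend, per-layer offset and phase lag, AR(1) noise, optional
  gap segments. Every downstream stage is testable without proprietary
  warehouse data.
* **Dual-domain augmentation** — Gaussian jitter in the time domain
  (`e ~ N(0, 0.01²)` °C) and FFT amplitude amplification in the frequency
  domain: `X_k = Σ_n x_n e^{-2πink/N}`, every non-DC `|X_k|` scaled ×1.2
  with phases (and the series mean) preserved, then inverse-transformed.
* **Preprocessing** — z-score normalization `(x − μ)/σ` fitted on training
  data only, 80/20 chronological split, ten-day lookback windows for
  one-step-ahead prediction.
* **Model zoo built from first principles** — LSTM cell, GRU, 1-D
  convolution, max-pooling, squeeze-and-excitation channel attention
  (`s = σ(W₂ δ(W₁ z))`), dense layers; batched analytic backprop and Adam,
  all in base R, gradient-checked against numerical differentiation.
* **Ablation harness** — the ladder LSTM → CNN-LSTM → CNN-SE-LSTM →
  FTA-CNN-SE-LSTM (FTA = augmentation switched on) scored by MAE/RMSE on
  a shared, never-augmented test slice.

## Worked example

```r
library(graintemp)

# one year of daily layer-mean temperatures from the simulator
sims <- simulate_temperatures(
  generate_layout(1, 1, 1),
  simulation_config(duration_days = 365, cadence_hours = 24, seed = 1))
series <- sims[[1]]

fit <- grain_forecast(series, model = "FTA-CNN-SE-LSTM", epochs = 100, seed = 1)
print(fit)
#> Grain temperature forecast: FTA-CNN-SE-LSTM (dual-domain augmented training)
#>   series 'r00c00l00', lookback 10 days, 63 test predictions
#>   test MAE = 0.1658, RMSE = 0.1699 (normalized scale)
```

The fit reports one-step-ahead error on the held-out final 20% of the year
(63 daily predictions), on the normalized scale: an MAE of 0.17 here
corresponds to roughly 2 °C on a series whose annual swing is −12…+22 °C.
The usual methods work on the object: `summary(fit)`, `predict(fit)` (°C),
`residuals(fit)`, `plot(fit)` (predicted vs actual), `plot(fit, "loss")`.

The ablation ladder, averaged over five seeds:

```r
report <- run_ablation(series, n_seeds = 5, seed = 1, epochs = 100)
report
#> Ablation report (normalized scale, 5 seeds):
#>            model    mae   rmse  mae_sd rmse_sd
#>             LSTM 0.1648 0.1697 0.02041 0.02013
#>         CNN-LSTM ...
#>      CNN-SE-LSTM ...
#>  FTA-CNN-SE-LSTM 0.1447 0.1486 0.03593 0.03549
```

The augmented hybrid's mean MAE comes in below the plain 8-unit LSTM's —
the directional claim the harness checks; absolute values depend on the
synthetic noise level.

A thin command-line wrapper covers the same ground
(`inst/cli/graintemp.R`): subcommands `simulate`, `augment`, `train`,
`ablate`, with CSV series files (`timestamp,series_id,temperature_c`) and
an optional YAML config.

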