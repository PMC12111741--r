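Package: graintemp
Title: Grain-Storage Temperature Forecasting with Dual-Domain Data Augmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for forecasting stored-grain temperature from granary sensor
    records. Provides a synthetic granary simulator (sensor grid layout plus
    seasonal temperature series with AR(1) noise and optional gap segments),
    dual-domain data augmentation (time-domain Gaussian jitter and FFT-based
    amplitude amplification of the non-DC spectrum), z-score preprocessing with
    chronological splitting and sliding-window dataset construction, neural
    forecasting architectures (LSTM, GRU, CNN, TCN, squeeze-and-excitation
    hybrids) implemented from first principles with Adam training, and an
    ablation harness reporting MAE/RMSE per model. The main entry point is
    grain_forecast(), a classed fitting function with the usual predict(),
    residuals(), summary() and plot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
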