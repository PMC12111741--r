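#' Default run configuration
#'
#' The package-wide defaults: jitter sigma 0.01 degC with mean 0, spectrum
#' amplification factor 1.2, ten-day lookback, 80/20 chronological split,
#' 100 training epochs. Returned as the nested structure used by
#' [load_config()].
#'
#' @return nested list with sections `simulate`, `augment`, `preprocess`,
#'   `model`, `train` and a global `seed`.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    simulate = list(rows = 6L, cols = 10L, layers = 7L, duration_days = 365,
                    cadence_hours = 4, baseline = 5, annual_amplitude = 17,
                    annual_period_days = 365, daily_amplitude = 0.8,
                    trend_slope = 0, ar_coefficient = 0.8,
                    innovation_sd = 0.15, layer_gradient = 0.4, layer_lag = 5),
    augment = list(sigma = 0.01, mu = 0, amplification_factor = 1.2,
                   amplify_dc = FALSE, time_domain = TRUE, freq_domain = TRUE),
    preprocess = list(lookback = 10L, train_fraction = 0.8, daily = TRUE),
    model = list(name = "FTA-CNN-SE-LSTM", dropout = 0.2, l2 = 1e-4,
                 se_reduction = 4L, se_position = "after_conv"),
    train = list(epochs = 100L, batch_size = 32L, learning_rate = 1e-3,
                 metric_scale = "normalized")
  )
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON) configuration file, fills every unset key from
#' [default_config()], and rejects unknown keys so typos fail loudly
#' instead of being silently ignored. `NULL` or a missing file path yields
#' the full default set. Loading the same file twice gives identical
#' effective configs.
#'
#' @param path YAML/JSON file path, or `NULL` for pure defaults.
#' @return the effective nested configuration list.
#' @export
load_config <- function(path = NULL) {
  defaults <- default_config()
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop_bad("config file not found: ", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(user)) return(defaults)
  merge_config(defaults, user, path = "")
}

merge_config <- function(defaults, user, path) {
  if (!is.list(user)) stop_bad("config section '", path, "' must be a mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop_bad("unknown config key(s): ",
             paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]))
      merge_config(defaults[[k]], user[[k]], paste0(path, ".", k))
    else user[[k]]
  }
  defaults
}
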