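#' Granary sensor-grid layout
#'
#' Builds the regular grid of temperature-measuring points used in a flat
#' granary: `rows x cols x layers` sensors, a fixed horizontal spacing
#' between neighbouring cables, a fixed vertical spacing between layers, and
#' a boundary offset from the grain surface, the ground and the walls. The
#' defaults mirror common practice for flat warehouses (5 m horizontal,
#' 1.8 m vertical, 0.5 m offsets); a 6 x 10 x 7 grid gives the canonical
#' 420-point layout.
#'
#' Coordinates are in meters with the origin at the warehouse corner:
#' x along the length (columns), y along the width (rows), z the height
#' (layers), all 0-based grid indices. When an `envelope` (length, width,
#' height in meters) is supplied, every coordinate must lie strictly inside
#' it, otherwise an error is raised; without an envelope no check is made.
#'
#' @param rows,cols,layers positive integer grid dimensions.
#' @param horizontal_spacing,vertical_spacing,boundary_offset meters (> 0).
#' @param envelope optional `c(length, width, height)` in meters.
#' @return A `granary_layout`: the parameters plus a `coordinates` data frame
#'   with columns `sensor_id, row, col, layer, x, y, z`.
#' @examples
#' lay <- generate_layout(6, 10, 7)
#' nrow(lay$coordinates)  # 420
#' @export
generate_layout <- function(rows, cols, layers,
                            horizontal_spacing = 5, vertical_spacing = 1.8,
                            boundary_offset = 0.5, envelope = NULL) {
  for (nm in c("rows", "cols", "layers")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 || v != floor(v))
      stop_bad(sprintf("`%s` must be a positive integer", nm))
  }
  check_scalar_num(horizontal_spacing, "horizontal_spacing", 0, strict_lower = TRUE)
  check_scalar_num(vertical_spacing, "vertical_spacing", 0, strict_lower = TRUE)
  check_scalar_num(boundary_offset, "boundary_offset", 0, strict_lower = TRUE)

  grid <- expand.grid(layer = seq_len(layers) - 1L, row = seq_len(rows) - 1L,
                      col = seq_len(cols) - 1L)
  coords <- data.frame(
    sensor_id = sprintf("r%02dc%02dl%02d", grid$row, grid$col, grid$layer),
    row = grid$row, col = grid$col, layer = grid$layer,
    x = boundary_offset + grid$col * horizontal_spacing,
    y = boundary_offset + grid$row * horizontal_spacing,
    z = boundary_offset + grid$layer * vertical_spacing,
    stringsAsFactors = FALSE)
  coords <- coords[order(coords$row, coords$col, coords$layer), ]
  rownames(coords) <- NULL

  if (!is.null(envelope)) {
    if (length(envelope) != 3L) stop_bad("envelope must be c(length, width, height)")
    inside <- coords$x < envelope[1] & coords$y < envelope[2] &
      coords$z < envelope[3] & coords$x > 0 & coords$y > 0 & coords$z > 0
    if (!all(inside))
      stop_bad(sprintf("%d sensor positions fall outside the %gx%gx%g m envelope",
                       sum(!inside), envelope[1], envelope[2], envelope[3]))
  }

  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 layers = as.integer(layers),
                 horizontal_spacing = horizontal_spacing,
                 vertical_spacing = vertical_spacing,
                 boundary_offset = boundary_offset,
                 coordinates = coords),
            class = "granary_layout")
}

#' @export
print.granary_layout <- function(x, ...) {
  cat(sprintf("<granary_layout> %d rows x %d cols x %d layers = %d sensors\n",
              x$rows, x$cols, x$layers, sensor_count(x)))
  cat(sprintf("  spacing: %g m horizontal, %g m vertical, %g m boundary offset\n",
              x$horizontal_spacing, x$vertical_spacing, x$boundary_offset))
  invisible(x)
}

#' Number of sensors in a layout
#' @param layout a `granary_layout`.
#' @export
sensor_count <- function(layout) {
  layout$rows * layout$cols * layout$layers
}

#' Write a layout to JSON
#' @param layout a `granary_layout`.
#' @param path output path.
#' @export
write_layout_json <- function(layout, path) {
  jsonlite::write_json(
    list(rows = layout$rows, cols = layout$cols, layers = layout$layers,
         horizontal_spacing = layout$horizontal_spacing,
         vertical_spacing = layout$vertical_spacing,
         boundary_offset = layout$boundary_offset,
         coordinates = layout$coordinates),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulation configuration for synthetic granary temperatures
#'
#' Parameterizes the synthetic temperature field: a deterministic signal
#' (baseline + linear trend + annual and daily sinusoids + a per-layer
#' offset and per-layer phase lag of the annual cycle) plus an AR(1)
#' residual per sensor. Defaults emulate a north-temperate corn warehouse
#' sampled every 4 hours over one year, with a seasonal swing of roughly
#' -12 to +22 deg C.
#'
#' @param start_time first timestamp (POSIXct or string).
#' @param duration_days length of the record in days.
#' @param cadence_hours sampling interval; must divide 24.
#' @param baseline mean temperature, deg C.
#' @param annual_amplitude,annual_period_days annual sinusoid (deg C, days).
#' @param daily_amplitude daily sinusoid amplitude, deg C.
#' @param trend_slope linear drift, deg C per day.
#' @param ar_coefficient AR(1) coefficient of the residual, in [0, 1).
#' @param innovation_sd innovation standard deviation of the residual, deg C.
#' @param layer_gradient additive offset per layer index, deg C.
#' @param layer_lag phase lag of the annual cycle per layer, days.
#' @param gap_schedule list of `c(start_index, length)` pairs (1-based) of
#'   segments to blank out in every simulated series.
#' @param seed integer seed; the simulation is fully reproducible given it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(start_time = "2024-01-01",
                              duration_days = 365,
                              cadence_hours = 4,
                              baseline = 5,
                              annual_amplitude = 17,
                              annual_period_days = 365,
                              daily_amplitude = 0.8,
                              trend_slope = 0,
                              ar_coefficient = 0.8,
                              innovation_sd = 0.15,
                              layer_gradient = 0.4,
                              layer_lag = 5,
                              gap_schedule = list(),
                              seed = 1L) {
  check_scalar_num(cadence_hours, "cadence_hours", 0, strict_lower = TRUE)
  if (abs(24 / cadence_hours - round(24 / cadence_hours)) > 1e-9)
    stop_bad("cadence_hours must divide 24 evenly")
  check_scalar_num(duration_days, "duration_days", 0, strict_lower = TRUE)
  check_scalar_num(ar_coefficient, "ar_coefficient", lower = 0)
  if (ar_coefficient >= 1) stop_bad("ar_coefficient must be < 1 (stationary residual)")
  check_scalar_num(innovation_sd, "innovation_sd", lower = 0)
  check_scalar_num(annual_period_days, "annual_period_days", 0, strict_lower = TRUE)
  structure(list(
    start_time = as.POSIXct(start_time, tz = "UTC"),
    duration_days = duration_days, cadence_hours = cadence_hours,
    baseline = baseline, annual_amplitude = annual_amplitude,
    annual_period_days = annual_period_days, daily_amplitude = daily_amplitude,
    trend_slope = trend_slope, ar_coefficient = ar_coefficient,
    innovation_sd = innovation_sd, layer_gradient = layer_gradient,
    layer_lag = layer_lag, gap_schedule = gap_schedule, seed = as.integer(seed)),
    class = "simulation_config")
}

#' Simulate granary temperature series
#'
#' One series per sensor in the layout. The value at elapsed time `t` days
#' for a sensor on layer `l` (0-based) is
#' \deqn{baseline + trend \cdot t + A_a \sin(2\pi (t - l \cdot lag)/P) +
#'       A_d \sin(2\pi t) + g \cdot l + e_t}
#' with `e_t` an AR(1) process per sensor. Deterministic given the seed.
#'
#' @param layout a `granary_layout`.
#' @param config a `simulation_config`.
#' @return Named list of `grain_series`, one per sensor, plus attribute
#'   `layer` giving each sensor's 0-based layer index.
#' @export
simulate_temperatures <- function(layout, config) {
  stopifnot(inherits(layout, "granary_layout"),
            inherits(config, "simulation_config"))
  n <- round(config$duration_days * 24 / config$cadence_hours)
  if (n < 1) stop_bad("duration too short for the cadence")
  t_days <- (seq_len(n) - 1L) * config$cadence_hours / 24
  timestamps <- config$start_time + (seq_len(n) - 1L) * config$cadence_hours * 3600

  coords <- layout$coordinates
  out <- vector("list", nrow(coords))
  names(out) <- coords$sensor_id
  layer_ix <- coords$layer

  with_seed(config$seed, {
    for (i in seq_len(nrow(coords))) {
      l <- coords$layer[i]
      det <- config$baseline +
        config$trend_slope * t_days +
        config$annual_amplitude *
          sin(2 * pi * (t_days - config$layer_lag * l) / config$annual_period_days) +
        config$daily_amplitude * sin(2 * pi * t_days) +
        config$layer_gradient * l
      resid <- numeric(n)
      if (config$innovation_sd > 0) {
        innov <- stats::rnorm(n, 0, config$innovation_sd)
        resid <- as.numeric(stats::filter(innov, config$ar_coefficient,
                                          method = "recursive"))
      }
      s <- grain_series(timestamps, det + resid, config$cadence_hours,
                        label = coords$sensor_id[i])
      if (length(config$gap_schedule))
        s <- inject_gaps(s, config$gap_schedule)
      out[[i]] <- s
    }
  })
  attr(out, "layer") <- layer_ix
  out
}

#' Blank out gap segments in a series
#'
#' Replaces the values inside each `c(start_index, length)` window (1-based)
#' with `NA`, emulating sensor dropouts. Gaps must lie within the series and
#' must not overlap; all values outside the gaps are preserved bit-exactly.
#'
#' @param series a `grain_series`.
#' @param gap_schedule list of `c(start_index, length)` pairs.
#' @return The series with gaps applied.
#' @export
inject_gaps <- function(series, gap_schedule) {
  stopifnot(inherits(series, "grain_series"))
  if (!length(gap_schedule)) return(series)
  n <- length(series)
  covered <- integer(0)
  for (g in gap_schedule) {
    if (length(g) != 2L || any(g < 1) || g[1] != floor(g[1]) || g[2] != floor(g[2]))
      stop_bad("each gap must be c(start_index, length) with positive integers")
    idx <- seq.int(g[1], length.out = g[2])
    if (max(idx) > n)
      stop_bad(sprintf("gap (%d, %d) extends past the series end (n = %d)",
                       g[1], g[2], n))
    if (any(idx %in% covered)) stop_bad("gap windows overlap")
    covered <- c(covered, idx)
  }
  v <- series$values
  v[covered] <- NA_real_
  series_with_values(series, v)
}

#' Layer-average series
#'
#' Element-wise mean over all sensors of one layer, skipping missing values;
#' the result is missing only where every sensor of the layer is missing at
#' that instant. All series must share identical timestamps.
#'
#' @param series_set list of `grain_series` as returned by
#'   [simulate_temperatures()] (with a `layer` attribute), or any list of
#'   series plus an explicit `layers` vector.
#' @param layer 0-based layer index to average.
#' @param layers optional integer vector giving each series' layer.
#' @return A `grain_series` labelled `"layer-mean-<layer>"`.
#' @export
layer_mean_series <- function(series_set, layer, layers = attr(series_set, "layer")) {
  if (is.null(layers)) stop_bad("no layer assignment available")
  sel <- which(layers == layer)
  if (!length(sel)) stop_bad(sprintf("layer %s has no sensors", layer))
  ref <- series_set[[sel[1]]]
  for (i in sel[-1]) {
    if (!isTRUE(all.equal(as.numeric(series_set[[i]]$timestamps),
                          as.numeric(ref$timestamps))))
      stop_bad("all series must share identical timestamps")
  }
  mat <- vapply(sel, function(i) series_set[[i]]$values,
                numeric(length(ref)))
  mat <- matrix(mat, nrow = length(ref))
  means <- rowMeans(mat, na.rm = TRUE)
  means[!is.finite(means)] <- NA_real_
  grain_series(ref$timestamps, means, ref$cadence_hours,
               label = sprintf("layer-mean-%d", layer))
}
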