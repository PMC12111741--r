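#' Evenly sampled temperature series
#'
#' The universal currency of the pipeline: an evenly sampled temperature
#' record (degrees Celsius) with POSIXct timestamps, a fixed cadence in
#' hours, and a free-text label (a sensor id or `"layer-mean"`). Gap
#' positions are stored as `NA`.
#'
#' @param timestamps `POSIXct` vector, strictly increasing with constant
#'   spacing equal to `cadence_hours`.
#' @param values numeric vector of temperatures in deg C; `NA` marks a gap.
#' @param cadence_hours sampling interval in hours.
#' @param label free-text identifier.
#' @return An object of class `grain_series`.
#' @examples
#' ts <- seq(as.POSIXct("2024-01-01", tz = "UTC"), by = "4 hours", length.out = 6)
#' grain_series(ts, c(10, 10.2, 10.1, 9.9, 10, 10.3), cadence_hours = 4)
#' @export
grain_series <- function(timestamps, values, cadence_hours, label = "series") {
  if (!inherits(timestamps, "POSIXct"))
    timestamps <- as.POSIXct(timestamps, tz = "UTC")
  if (length(timestamps) != length(values))
    stop_bad("timestamps and values must have equal length")
  check_scalar_num(cadence_hours, "cadence_hours", lower = 0, strict_lower = TRUE)
  if (length(timestamps) >= 2L) {
    d <- diff(as.numeric(timestamps))
    if (any(d <= 0)) stop_bad("timestamps must be strictly increasing")
    if (any(abs(d - cadence_hours * 3600) > 1e-6))
      stop_bad("timestamp spacing must equal cadence_hours everywhere")
  }
  structure(
    list(timestamps = timestamps, values = as.numeric(values),
         cadence_hours = as.numeric(cadence_hours), label = as.character(label)),
    class = "grain_series"
  )
}

#' @export
length.grain_series <- function(x) length(x$values)

#' @export
print.grain_series <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<grain_series> '%s': %d samples @ %g h cadence\n",
              x$label, n, x$cadence_hours))
  if (n > 0) {
    cat(sprintf("  span: %s .. %s\n", format(x$timestamps[1]),
                format(x$timestamps[n])))
    v <- x$values[!is.na(x$values)]
    if (length(v))
      cat(sprintf("  range: [%.3f, %.3f] degC, %d missing\n",
                  min(v), max(v), sum(is.na(x$values))))
  }
  invisible(x)
}

#' @export
as.data.frame.grain_series <- function(x, ...) {
  data.frame(timestamp = x$timestamps, series_id = x$label,
             temperature_c = x$values, stringsAsFactors = FALSE)
}

# Replace the values of a series, keeping timestamps/cadence (internal).
series_with_values <- function(series, values, label = series$label) {
  grain_series(series$timestamps, values, series$cadence_hours, label)
}

has_gaps <- function(series) anyNA(series$values)

require_gap_free <- function(series, what = "operation") {
  if (has_gaps(series))
    stop_bad(sprintf("%s requires a gap-free series (found %d missing values)",
                     what, sum(is.na(series$values))))
  invisible(series)
}

#' Read / write temperature series CSV
#'
#' Schema: header `timestamp,series_id,temperature_c`; ISO-8601 UTC
#' timestamps; an empty temperature field marks a missing value. A file may
#' hold several series (one per `series_id`); `read_series_csv` returns a
#' single `grain_series` when the file has one id, otherwise a named list.
#' Temperatures are serialized at full precision so a write/read round trip
#' is value-exact.
#'
#' @param path file path.
#' @param series a `grain_series` or list of them (for writing).
#' @return `read_series_csv`: a `grain_series` or named list of them.
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) stop_bad("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "character"))
  need <- c("timestamp", "series_id", "temperature_c")
  if (!identical(names(df), need))
    stop_bad("CSV header must be exactly: ", paste(need, collapse = ","))
  vals <- suppressWarnings(as.numeric(df$temperature_c))
  bad <- which(!is.na(df$temperature_c) & nzchar(df$temperature_c) & is.na(vals))
  if (length(bad))
    stop_bad(sprintf("malformed temperature at line %d: '%s'",
                     bad[1] + 1L, df$temperature_c[bad[1]]))
  vals[!nzchar(df$temperature_c)] <- NA_real_
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%d"))
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    stop_bad(sprintf("malformed timestamp at line %d: '%s'",
                     bad + 1L, df$timestamp[bad]))
  }
  out <- lapply(split(seq_len(nrow(df)), df$series_id), function(ix) {
    tsi <- ts[ix]
    if (is.unsorted(tsi, strictly = TRUE)) {
      ln <- ix[which(diff(as.numeric(tsi)) <= 0)[1] + 1L]
      stop_bad(sprintf("non-monotone timestamps (line %d)", ln + 1L))
    }
    cad <- if (length(tsi) >= 2) diff(as.numeric(tsi))[1] / 3600 else 4
    grain_series(tsi, vals[ix], cad, label = df$series_id[ix[1]])
  })
  if (length(out) == 1L) out[[1]] else out
}

#' @rdname read_series_csv
#' @export
write_series_csv <- function(series, path) {
  if (inherits(series, "grain_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    data.frame(
      timestamp = strftime(s$timestamps, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      series_id = s$label,
      temperature_c = ifelse(is.na(s$values), "",
                             formatC(s$values, digits = 17, format = "g")),
      stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
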