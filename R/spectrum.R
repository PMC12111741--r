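#' Discrete Fourier spectrum of a temperature series
#'
#' Complex DFT coefficients `X_k`, `k = 0..N-1`, under the unnormalized
#' forward convention
#' \deqn{X_k = \sum_{n=0}^{N-1} x_n e^{-2\pi i nk/N}}
#' with the matching `1/N`-scaled inverse. `sampling_frequency` is in
#' samples per day, so bin `k` (for `k <= N/2`) maps to frequency
#' `k * fT / N` cycles per day.
#'
#' @param series a gap-free `grain_series`.
#' @return A `grain_spectrum`: `coefficients` (complex), `n_samples`,
#'   `sampling_frequency` (samples/day), `timestamps` and `cadence_hours`
#'   retained for inversion, `label`.
#' @examples
#' s <- grain_series(seq(as.POSIXct("2024-01-01", tz="UTC"), by = "6 hours",
#'                       length.out = 4), c(1, 0, -1, 0), 6)
#' Mod(dft_forward(s)$coefficients)  # 0 2 0 2
#' @export
dft_forward <- function(series) {
  stopifnot(inherits(series, "grain_series"))
  require_gap_free(series, "dft_forward")
  n <- length(series)
  if (n < 1) stop_bad("series must have length >= 1")
  structure(list(
    coefficients = stats::fft(series$values),
    n_samples = n,
    sampling_frequency = 24 / series$cadence_hours,
    timestamps = series$timestamps,
    cadence_hours = series$cadence_hours,
    label = series$label),
    class = "grain_spectrum")
}

#' @export
print.grain_spectrum <- function(x, ...) {
  cat(sprintf("<grain_spectrum> '%s': N = %d, fT = %g samples/day\n",
              x$label, x$n_samples, x$sampling_frequency))
  invisible(x)
}

#' Amplitude and phase views of a spectrum
#' @param spectrum a `grain_spectrum`.
#' @return numeric vector, one value per bin `k = 0..N-1`.
#' @export
spectrum_amplitude <- function(spectrum) Mod(spectrum$coefficients)

#' @rdname spectrum_amplitude
#' @export
spectrum_phase <- function(spectrum) Arg(spectrum$coefficients)

#' Frequency of a DFT bin
#'
#' Maps bin index `k` (0-based, `k <= N/2`) to its frequency in cycles per
#' day: `f_k = k * fT / N`.
#'
#' @param spectrum a `grain_spectrum`.
#' @param k 0-based bin index (vectorized).
#' @export
frequency_of <- function(spectrum, k) {
  if (any(k < 0) || any(k > spectrum$n_samples / 2))
    stop_bad("k must satisfy 0 <= k <= N/2")
  k * spectrum$sampling_frequency / spectrum$n_samples
}

#' Inverse DFT back to a temperature series
#'
#' `1/N`-scaled inverse of [dft_forward()]. When the coefficients carry the
#' conjugate symmetry of a real signal the (numerically tiny) imaginary
#' parts are dropped; otherwise an error is raised.
#'
#' @param spectrum a `grain_spectrum`.
#' @return A `grain_series`.
#' @export
dft_inverse <- function(spectrum) {
  stopifnot(inherits(spectrum, "grain_spectrum"))
  x <- stats::fft(spectrum$coefficients, inverse = TRUE) / spectrum$n_samples
  scale <- max(Mod(spectrum$coefficients), 1)
  if (max(abs(Im(x))) > 1e-6 * scale)
    stop_bad("spectrum is not conjugate-symmetric: inverse is not real")
  grain_series(spectrum$timestamps, Re(x), spectrum$cadence_hours,
               label = spectrum$label)
}

#' Amplify the non-DC spectrum
#'
#' Multiplies every coefficient except the DC bin (`k = 0`) by
#' `amplification_factor`, scaling each bin's amplitude while leaving its
#' phase untouched; conjugate symmetry is preserved, so the inverse stays
#' real. The DC bin — which carries the series mean — is only scaled when
#' `amplify_dc = TRUE`.
#'
#' @param spectrum a `grain_spectrum`.
#' @param amplification_factor positive multiplier (default 1.2).
#' @param amplify_dc also scale the DC bin? Default `FALSE`.
#' @return The amplified `grain_spectrum`.
#' @export
amplify_spectrum <- function(spectrum, amplification_factor = 1.2,
                             amplify_dc = FALSE) {
  stopifnot(inherits(spectrum, "grain_spectrum"))
  check_scalar_num(amplification_factor, "amplification_factor", 0,
                   strict_lower = TRUE)
  co <- spectrum$coefficients * amplification_factor
  if (!amplify_dc) co[1] <- spectrum$coefficients[1]
  spectrum$coefficients <- co
  spectrum
}

#' Dominant periods of a series' spectrum
#'
#' Ranks the non-DC bins `k = 1..floor(N/2)` by amplitude and reports the
#' `top_n` strongest as periods in days (`period = 1 / f_k`). Ties are
#' broken toward the lower bin index (longer period).
#'
#' @param spectrum a `grain_spectrum` with `N >= 2`.
#' @param top_n how many components to report.
#' @return data frame `k, frequency_per_day, period_days, amplitude`,
#'   ordered by decreasing amplitude.
#' @export
dominant_periods <- function(spectrum, top_n = 3) {
  stopifnot(inherits(spectrum, "grain_spectrum"))
  if (top_n < 1) stop_bad("top_n must be >= 1")
  n <- spectrum$n_samples
  if (n < 2) stop_bad("need N >= 2 for period analysis")
  ks <- seq_len(floor(n / 2))
  amp <- Mod(spectrum$coefficients[ks + 1L])
  ord <- order(-amp, ks)
  sel <- ord[seq_len(min(top_n, length(ks)))]
  f <- frequency_of(spectrum, ks[sel])
  data.frame(k = ks[sel], frequency_per_day = f, period_days = 1 / f,
             amplitude = amp[sel])
}

#' Export a spectrum as diagnostics CSV
#'
#' Columns `k,frequency_per_day,amplitude,phase_rad` for bins `k <= N/2`.
#'
#' @param spectrum a `grain_spectrum`.
#' @param path output path.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  ks <- 0:floor(spectrum$n_samples / 2)
  utils::write.csv(data.frame(
    k = ks,
    frequency_per_day = ks * spectrum$sampling_frequency / spectrum$n_samples,
    amplitude = Mod(spectrum$coefficients[ks + 1L]),
    phase_rad = Arg(spectrum$coefficients[ks + 1L])),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
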