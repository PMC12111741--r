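#' Time-domain augmentation: Gaussian jitter
#'
#' Adds i.i.d. Gaussian perturbations `e_i ~ N(mu, sigma^2)` to every value
#' of a gap-free series. The defaults (`mu = 0`, `sigma = 0.01` deg C)
#' emulate small measurement errors without disturbing the signal's core
#' characteristics; the perturbation is applied to raw temperatures before
#' any normalization. Reproducible given the seed; the input is untouched.
#'
#' @param series a gap-free `grain_series`.
#' @param sigma standard deviation of the jitter, deg C (>= 0).
#' @param mu mean of the jitter, deg C.
#' @param seed integer seed.
#' @return A new `grain_series` of the same length and timestamps.
#' @export
add_gaussian_noise <- function(series, sigma = 0.01, mu = 0, seed = 1L) {
  stopifnot(inherits(series, "grain_series"))
  require_gap_free(series, "add_gaussian_noise")
  check_scalar_num(sigma, "sigma", lower = 0)
  check_scalar_num(mu, "mu")
  noise <- with_seed(seed, stats::rnorm(length(series), mean = mu, sd = sigma))
  series_with_values(series, series$values + noise,
                     label = paste0(series$label, "+noise"))
}

#' Frequency-domain augmentation of a series
#'
#' The dual-domain augmentation pipeline: Gaussian jitter in the time
#' domain, then an FFT into the frequency domain, amplification of the
#' non-DC amplitude spectrum by `amplification_factor` (default 1.2, phases
#' preserved, series mean preserved), and the inverse FFT back to the time
#' domain. Output is real-valued with the same length and timestamps as the
#' input. With `sigma = 0` and `amplification_factor = 1` the pipeline is
#' the identity up to float tolerance.
#'
#' @inheritParams add_gaussian_noise
#' @param amplification_factor positive non-DC amplitude multiplier.
#' @param amplify_dc also scale the DC bin? Default `FALSE`.
#' @return A new `grain_series`.
#' @export
frequency_augment <- function(series, sigma = 0.01, mu = 0,
                              amplification_factor = 1.2, amplify_dc = FALSE,
                              seed = 1L) {
  stopifnot(inherits(series, "grain_series"))
  require_gap_free(series, "frequency_augment")
  jittered <- if (sigma > 0 || mu != 0)
    add_gaussian_noise(series, sigma = sigma, mu = mu, seed = seed)
  else series
  spec <- dft_forward(jittered)
  spec <- amplify_spectrum(spec, amplification_factor, amplify_dc)
  out <- dft_inverse(spec)
  series_with_values(series, out$values,
                     label = paste0(series$label, "+freqaug"))
}

#' Build the augmented training pool
#'
#' Returns the list of training variants derived from one gap-free slice:
#' the original, a noise-jittered copy, and a frequency-augmented copy
#' (noise + FFT amplitude amplification). Each variant has the same length
#' and timestamps; downstream the variants are windowed separately and
#' their windows concatenated as extra training samples. Either stage can
#' be disabled.
#'
#' @inheritParams frequency_augment
#' @param time_domain include the Gaussian-jitter variant?
#' @param freq_domain include the frequency-augmented variant?
#' @return List of `grain_series`; the first element is always the
#'   unmodified input.
#' @export
augment_training_set <- function(series, sigma = 0.01, mu = 0,
                                 amplification_factor = 1.2,
                                 amplify_dc = FALSE, seed = 1L,
                                 time_domain = TRUE, freq_domain = TRUE) {
  stopifnot(inherits(series, "grain_series"))
  require_gap_free(series, "augment_training_set")
  out <- list(series)
  if (time_domain)
    out <- c(out, list(add_gaussian_noise(series, sigma = sigma, mu = mu,
                                          seed = derive_seed(seed, "jitter"))))
  if (freq_domain)
    out <- c(out, list(frequency_augment(series, sigma = sigma, mu = mu,
                                         amplification_factor = amplification_factor,
                                         amplify_dc = amplify_dc,
                                         seed = derive_seed(seed, "freqaug"))))
  out
}
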