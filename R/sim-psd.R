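#' Simulate a neural power spectrum
#'
#' Builds a spectrum directly in the frequency domain as
#' `log10(power) = offset - log10(knee + f^exponent) + sum of Gaussians +
#' white log-noise`. With `knee = 0` this reduces to the pure power-law
#' ("fixed") form `offset - exponent * log10(f)`. Peaks are Gaussian in
#' log-power over linear frequency, parameterized by center frequency `cf`
#' (Hz), height `pw` (log10 power units above the aperiodic component), and
#' bandwidth `bw` (Hz, equal to two Gaussian standard deviations).
#'
#' @param freq_range Length-2 numeric, spectrum support in Hz (> 0).
#' @param freq_res Frequency resolution in Hz.
#' @param offset Aperiodic offset (log10 power at the reference).
#' @param exponent Aperiodic exponent chi.
#' @param knee Knee parameter k (>= 0; 0 = no knee).
#' @param peaks A data frame / tibble with columns `cf`, `pw`, `bw` (one row
#'   per peak), or `NULL` for no peaks.
#' @param noise_sd Standard deviation of white noise added in log10 power
#'   units (default 0.005).
#' @param seed Optional integer seed for the noise.
#' @return An [aper_psd] (linear power scale).
#' @examples
#' ps <- sim_power_spectrum(c(1, 50), 0.5, exponent = 1,
#'                          peaks = data.frame(cf = 10, pw = 0.5, bw = 2),
#'                          noise_sd = 0, seed = 1)
#' @export
sim_power_spectrum <- function(freq_range = c(1, 50), freq_res = 0.5,
                               offset = 0, exponent = 1, knee = 0,
                               peaks = NULL, noise_sd = 0.005, seed = NULL) {
  if (length(freq_range) != 2L || any(freq_range <= 0) ||
      freq_range[2L] <= freq_range[1L]) {
    stop_invalid("`freq_range` must be an increasing positive Hz pair")
  }
  check_scalar_num(freq_res, "freq_res", lower = 0, strict_lower = TRUE)
  check_scalar_num(exponent, "exponent", lower = 0)
  check_scalar_num(knee, "knee", lower = 0)
  check_scalar_num(noise_sd, "noise_sd", lower = 0)
  freqs <- seq(freq_range[1L], freq_range[2L], by = freq_res)
  logp <- offset - log10(knee + freqs^exponent)
  if (!is.null(peaks) && nrow(as.data.frame(peaks)) > 0) {
    peaks <- as.data.frame(peaks)
    stopifnot(all(c("cf", "pw", "bw") %in% names(peaks)))
    for (i in seq_len(nrow(peaks))) {
      cf <- peaks$cf[i]; pw <- peaks$pw[i]; bw <- peaks$bw[i]
      if (cf < freq_range[1L] || cf > freq_range[2L]) {
        stop_invalid("peak cf %g Hz outside freq_range [%g, %g]",
                     cf, freq_range[1L], freq_range[2L])
      }
      if (bw <= 0 || pw < 0) stop_invalid("peak needs bw > 0 and pw >= 0")
      logp <- logp + pw * exp(-(freqs - cf)^2 / (2 * (bw / 2)^2))
    }
  }
  if (noise_sd > 0) {
    logp <- logp + with_seed(seed, rnorm(length(freqs), sd = noise_sd))
  }
  aper_psd(freqs, 10^logp)
}

#' Sample a peak center frequency from a probability table
#'
#' Draws an integer center frequency from 3-34 Hz according to a
#' per-frequency probability table (normalized internally). The table
#' mimics the empirical occurrence probability of oscillatory peaks at each
#' frequency; the default is uniform.
#'
#' @param prob_table Nonnegative weights for frequencies 3..34 Hz (length
#'   32), or `NULL` for uniform.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Integer frequencies in Hz (vector of length `n`).
#' @export
sample_peak_cf <- function(prob_table = NULL, n = 1, seed = NULL) {
  freqs <- 3:34
  if (is.null(prob_table)) prob_table <- rep(1, length(freqs))
  if (length(prob_table) != length(freqs)) {
    stop_invalid("`prob_table` must have %d entries (3-34 Hz)", length(freqs))
  }
  if (any(!is.finite(prob_table)) || any(prob_table < 0)) {
    stop_invalid("`prob_table` entries must be finite and nonnegative")
  }
  if (sum(prob_table) == 0) stop_invalid("`prob_table` must not be all zero")
  with_seed(seed,
            sample(freqs, n, replace = TRUE, prob = prob_table / sum(prob_table)))
}

#' Grids used for simulated-spectrum experiments
#'
#' The standard parameter grids for simulated power spectra: aperiodic
#' exponents 0.5-3.0 in 0.5 steps, peak powers
#' \{0.15, 0.25, 0.5, 1.0, 1.5\}, and bandwidths \{1.0, 1.5, 2.0, 2.5\},
#' each value equiprobable.
#'
#' @return A named list of numeric vectors: `exponent`, `peak_pw`, `peak_bw`.
#' @export
psd_sim_grids <- function() {
  list(exponent = seq(0.5, 3.0, by = 0.5),
       peak_pw = c(0.15, 0.25, 0.5, 1.0, 1.5),
       peak_bw = c(1.0, 1.5, 2.0, 2.5))
}

#' Simulate a batch of combined power spectra
#'
#' Draws `n` spectra with aperiodic exponent, one peak (cf from the 3-34 Hz
#' table, pw and bw from the standard grids), and white log-noise, recording
#' ground truth per row.
#'
#' @param n Number of spectra.
#' @param seed Master seed.
#' @param freq_range,freq_res Spectrum support and resolution.
#' @param noise_sd Log10 noise standard deviation.
#' @param cf_table Optional peak-frequency probability table (see
#'   [sample_peak_cf()]).
#' @param knee Knee parameter applied to every spectrum (default 0).
#' @return A tibble with ground-truth columns (`exponent`, `knee`, `cf`,
#'   `pw`, `bw`, `seed`) and a `spectrum` list-column of [aper_psd].
#' @export
sim_psd_set <- function(n, seed = 0L, freq_range = c(1, 50), freq_res = 0.5,
                        noise_sd = 0.005, cf_table = NULL, knee = 0) {
  check_scalar_num(n, "n", lower = 1)
  grids <- psd_sim_grids()
  params <- with_seed(seed, tibble::tibble(
    exponent = sample(grids$exponent, n, replace = TRUE),
    cf = as.numeric(sample_peak_cf(cf_table, n)),
    pw = sample(grids$peak_pw, n, replace = TRUE),
    bw = sample(grids$peak_bw, n, replace = TRUE)
  ))
  params$knee <- knee
  params$seed <- vapply(seq_len(n), function(i) derive_seed(seed, i), 1L)
  params$spectrum <- purrr::pmap(params, function(exponent, cf, pw, bw, knee,
                                                  seed, ...) {
    sim_power_spectrum(freq_range, freq_res, offset = 0, exponent = exponent,
                       knee = knee,
                       peaks = data.frame(cf = cf, pw = pw, bw = bw),
                       noise_sd = noise_sd, seed = seed)
  })
  tibble::as_tibble(params[c("exponent", "knee", "cf", "pw", "bw", "seed",
                             "spectrum")])
}
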