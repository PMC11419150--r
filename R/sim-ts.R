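#' Simulate a power-law (colored noise) time series
#'
#' Generates aperiodic activity with a 1/f^chi power spectrum by spectral
#' rotation: a white-noise series is transformed to the frequency domain, its
#' amplitudes are rotated about a 1 Hz anchor so the power spectrum follows
#' f^(-exponent), and the result is returned to the time domain. The DC bin
#' is zeroed. The returned signal is normalized to zero mean and unit
#' variance.
#'
#' @param n_samples Number of samples (>= 16).
#' @param fs Sampling rate in Hz.
#' @param exponent Aperiodic exponent chi >= 0: 0 gives white noise, 1 pink,
#'   2 brown.
#' @param seed Optional integer seed; the simulation is fully reproducible
#'   given the seed.
#' @param f_rotation Anchor frequency (Hz) about which amplitudes are
#'   rotated. Default 1 Hz, the lower bound of the standard fitting range.
#' @return An [aper_ts].
#' @examples
#' x <- sim_powerlaw(7500, fs = 250, exponent = 1, seed = 1)
#' @export
sim_powerlaw <- function(n_samples, fs, exponent, seed = NULL, f_rotation = 1) {
  check_scalar_num(n_samples, "n_samples", lower = 16)
  check_scalar_num(fs, "fs", lower = 0, strict_lower = TRUE)
  check_scalar_num(exponent, "exponent", lower = 0)
  n <- as.integer(n_samples)
  x <- with_seed(seed, rnorm(n))
  if (exponent > 0) {
    f <- seq(0, n - 1) / n * fs
    f[f > fs / 2] <- fs - f[f > fs / 2]        # mirrored (negative) frequencies
    scale <- rep(0, n)
    nz <- f > 0
    scale[nz] <- (f[nz] / f_rotation)^(-exponent / 2)
    x <- Re(fft(fft(x) * scale, inverse = TRUE)) / n
  }
  aper_ts(zscore(x), fs)
}

#' Simulate aperiodic activity with a spectral knee (synaptic model)
#'
#' A physiologically inspired generator: a rate-collapsed Poisson train of
#' post-synaptic events (1000 independent sources firing at 2 events/s each)
#' is convolved with a causal single-exponential decay kernel with time
#' constant `tau_d` (instantaneous rise). The resulting power spectrum is
#' Lorentzian: flat at low frequencies, bending near the knee frequency
#' 1/(2 * pi * tau_d), and decaying with exponent 2 above it.
#'
#' @param n_samples Number of samples.
#' @param fs Sampling rate (Hz).
#' @param tau_d Synaptic decay time constant in seconds (> 0).
#' @param seed Optional integer seed.
#' @param n_sources,rate_per_source Poisson-train constants of the collapsed
#'   event train; defaults follow the standard published model.
#' @return An [aper_ts], normalized to zero mean and unit variance.
#' @examples
#' x <- sim_synaptic_knee(7500, fs = 500, tau_d = 0.015, seed = 1)
#' @export
sim_synaptic_knee <- function(n_samples, fs, tau_d, seed = NULL,
                              n_sources = 1000, rate_per_source = 2) {
  check_scalar_num(n_samples, "n_samples", lower = 16)
  check_scalar_num(fs, "fs", lower = 0, strict_lower = TRUE)
  check_scalar_num(tau_d, "tau_d", lower = 0, strict_lower = TRUE)
  n <- as.integer(n_samples)
  kern_len <- max(2L, as.integer(ceiling(7 * tau_d * fs)))
  kernel <- exp(-seq(0, kern_len - 1) / (tau_d * fs))
  # extra leading samples so the convolution transient is discarded
  n_tot <- n + kern_len
  events <- with_seed(seed, rpois(n_tot, n_sources * rate_per_source / fs))
  n_fft <- nextn(n_tot + kern_len - 1, 2)
  conv <- Re(fft(fft(c(events, rep(0, n_fft - n_tot))) *
                   fft(c(kernel, rep(0, n_fft - kern_len))), inverse = TRUE)) / n_fft
  x <- conv[(kern_len + 1):(kern_len + n)]
  aper_ts(zscore(x), fs)
}

#' Simulate a (possibly bursty) oscillation
#'
#' A sinusoidal oscillation at center frequency `freq`. With
#' `burst_prob < 1`, each whole cycle is independently present with that
#' probability and silent (zero) otherwise. Nonzero `bandwidth` broadens the
#' spectral peak by modulating the instantaneous frequency with a smoothed
#' random walk whose spread maps to the requested width (bandwidth is the
#' 2-standard-deviation width of the spectral peak).
#'
#' @param n_samples Number of samples.
#' @param fs Sampling rate (Hz); `freq` must be below Nyquist.
#' @param freq Center frequency in Hz.
#' @param burst_prob Per-cycle presence probability in \[0, 1\]. Default 1
#'   (continuous oscillation).
#' @param bandwidth Spectral peak width proxy in Hz (>= 0; 0 = pure tone).
#' @param phase_continuous If `TRUE` (default) the oscillation's phase keeps
#'   advancing through silent cycles, so bursts are phase-aligned to a single
#'   underlying oscillator; if `FALSE` each present cycle restarts at phase 0.
#' @param seed Optional integer seed.
#' @return An [aper_ts]; zero mean unless all cycles are absent (then all
#'   zeros).
#' @examples
#' x <- sim_oscillation(7500, fs = 250, freq = 10, burst_prob = 0.5, seed = 2)
#' @export
sim_oscillation <- function(n_samples, fs, freq, burst_prob = 1,
                            bandwidth = 0, phase_continuous = TRUE,
                            seed = NULL) {
  check_scalar_num(n_samples, "n_samples", lower = 16)
  check_scalar_num(fs, "fs", lower = 0, strict_lower = TRUE)
  check_scalar_num(freq, "freq", lower = 0, strict_lower = TRUE)
  check_scalar_num(burst_prob, "burst_prob", lower = 0, upper = 1)
  check_scalar_num(bandwidth, "bandwidth", lower = 0)
  if (freq >= fs / 2) {
    stop_invalid("`freq` (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 freq, fs / 2)
  }
  n <- as.integer(n_samples)
  with_seed(seed, {
    inst_freq <- rep(freq, n)
    if (bandwidth > 0) {
      # smoothed random walk in instantaneous frequency; sd = bandwidth / 2
      dev <- cumsum(rnorm(n))
      win <- max(3L, as.integer(round(0.25 * fs)))
      dev <- as.numeric(stats::filter(dev, rep(1 / win, win), sides = 2))
      dev[is.na(dev)] <- 0
      s <- sd(dev)
      if (s > 0) dev <- dev / s * (bandwidth / 2)
      inst_freq <- pmax(0.1, inst_freq + dev)
    }
    phase <- cumsum(2 * pi * inst_freq / fs)
    phase <- phase - phase[1L]
    cycle <- floor(phase / (2 * pi))
    n_cycles <- max(cycle) + 1
    present <- if (burst_prob >= 1) {
      rep(TRUE, n_cycles)
    } else if (burst_prob <= 0) {
      rep(FALSE, n_cycles)
    } else {
      as.logical(rbinom(n_cycles, 1L, burst_prob))
    }
    mask <- present[cycle + 1L]
    if (!phase_continuous) {
      # restart each present cycle at phase zero
      phase <- phase - 2 * pi * cycle
    }
    x <- sin(phase)
    x[!mask] <- 0
    if (any(mask)) x <- x - mean(x)
    aper_ts(x, fs)
  })
}

#' Additively combine aperiodic and periodic components
#'
#' Each component is scaled to unit variance, then summed with the periodic
#' component weighted by `sqrt(rel_power)`, so `rel_power` is the variance of
#' the periodic component relative to the aperiodic component. With
#' `rel_power = 0` the normalized aperiodic component is returned exactly.
#'
#' @param aperiodic_ts,periodic_ts Two [aper_ts] of equal length and
#'   sampling rate.
#' @param rel_power Relative power (variance ratio) of the periodic
#'   component (>= 0).
#' @return An [aper_ts]. For uncorrelated components its variance is
#'   approximately `1 + rel_power`.
#' @export
combine_signals <- function(aperiodic_ts, periodic_ts, rel_power) {
  aperiodic_ts <- as_aper_ts(aperiodic_ts)
  periodic_ts <- as_aper_ts(periodic_ts)
  check_scalar_num(rel_power, "rel_power", lower = 0)
  if (n_samples(aperiodic_ts) != n_samples(periodic_ts)) {
    stop_invalid("component lengths differ (%d vs %d)",
                 n_samples(aperiodic_ts), n_samples(periodic_ts))
  }
  if (aperiodic_ts$fs != periodic_ts$fs) {
    stop_invalid("component sampling rates differ (%g vs %g Hz)",
                 aperiodic_ts$fs, periodic_ts$fs)
  }
  ap <- zscore(aperiodic_ts$samples)
  if (rel_power == 0) return(aper_ts(ap, aperiodic_ts$fs))
  aper_ts(ap + sqrt(rel_power) * zscore(periodic_ts$samples), aperiodic_ts$fs)
}
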