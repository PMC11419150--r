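#' Irregular-resampling auto-spectral analysis (IRASA)
#'
#' Separates a signal's power spectrum into an aperiodic (scale-free)
#' component and a periodic residual. For each resampling factor `h` the
#' signal is resampled up by `h` and down by `1/h` (rational-factor
#' polyphase resampling); the Welch spectra of the pair, evaluated on the
#' original frequency grid, are combined by geometric mean. Scale-free
#' content is invariant to this construction while spectral peaks are
#' displaced, so the median of the geometric means across the factor set
#' estimates the aperiodic spectrum; the periodic residual is the original
#' PSD minus this estimate.
#'
#' @param ts An [aper_ts] (or numeric vector with `fs`).
#' @param frange Frequency range (Hz) retained in the output.
#' @param hset Resampling factors, all > 1 (default 1.1-1.95 in 0.05 steps).
#' @param seg_len,overlap Welch settings (see [compute_psd()]).
#' @param fs Sampling rate when `ts` is a bare vector.
#' @return An object of class `irasa_decomp`: a list with `freqs`,
#'   `psd` (original), `aperiodic`, `periodic` (residual), and `hset`.
#' @examples
#' dec <- irasa(sim_powerlaw(7500, 250, 1, seed = 1))
#' fit_aperiodic(aper_psd(dec$freqs, dec$aperiodic))$exponent
#' @export
irasa <- function(ts, frange = c(1, 50), hset = seq(1.1, 1.95, by = 0.05),
                  seg_len = 2, overlap = 0.5, fs = NULL) {
  ts <- as_aper_ts(ts, fs)
  if (any(hset <= 1)) stop_invalid("all resampling factors must be > 1")
  orig <- compute_psd(ts, seg_len = seg_len, overlap = overlap)
  orig <- trim_psd(orig, frange)
  geo <- matrix(NA_real_, nrow = nrow(orig), ncol = length(hset))
  for (j in seq_along(hset)) {
    h <- hset[j]
    # rational approximation p/q of h (hset in 0.05 steps is exact at q=20)
    q <- 20L
    p <- as.integer(round(h * q))
    up <- signal::resample(ts$samples, p, q)
    dn <- signal::resample(ts$samples, q, p)
    ps_up <- compute_psd(aper_ts(up, ts$fs * p / q), seg_len, overlap)
    ps_dn <- compute_psd(aper_ts(dn, ts$fs * q / p), seg_len, overlap)
    pu <- approx(ps_up$freq, ps_up$power, xout = orig$freq, rule = 2)$y
    pd <- approx(ps_dn$freq, ps_dn$power, xout = orig$freq, rule = 2)$y
    geo[, j] <- sqrt(pu * pd)
  }
  aperiodic <- apply(geo, 1L, median)
  structure(list(freqs = orig$freq, psd = orig$power,
                 aperiodic = aperiodic,
                 periodic = orig$power - aperiodic,
                 hset = hset),
            class = "irasa_decomp")
}

#' @export
print.irasa_decomp <- function(x, ...) {
  cat(sprintf("<irasa_decomp> %d bins (%.3g-%.3g Hz), %d resampling factors\n",
              length(x$freqs), min(x$freqs), max(x$freqs), length(x$hset)))
  invisible(x)
}

#' Fit the aperiodic exponent from an IRASA decomposition
#'
#' Convenience wrapper: fits the aperiodic model ([fit_aperiodic()]) to the
#' isolated aperiodic spectrum.
#'
#' @param decomp An `irasa_decomp` from [irasa()].
#' @param frange Fit range in Hz (defaults to the decomposition's support).
#' @param mode `"fixed"` or `"knee"`.
#' @return A one-row tibble: `offset`, `knee`, `exponent`, `mode`.
#' @export
irasa_fit <- function(decomp, frange = NULL, mode = c("fixed", "knee")) {
  stopifnot(inherits(decomp, "irasa_decomp"))
  if (is.null(frange)) frange <- range(decomp$freqs)
  keep <- decomp$aperiodic > 0
  fit_aperiodic(aper_psd(decomp$freqs[keep], decomp$aperiodic[keep]),
                frange = frange, mode = mode)
}

#' @export
autoplot.irasa_decomp <- function(object, ...) {
  df <- tibble::tibble(freq = object$freqs, original = object$psd,
                       aperiodic = object$aperiodic)
  long <- tidyr::pivot_longer(df, -"freq", names_to = "component",
                              values_to = "power")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$freq, y = .data$power,
                                     color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Power (a.u.)")
}
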