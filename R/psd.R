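#' Welch power spectral density estimate
#'
#' Hann-tapered, mean-detrended, 50%-overlapping segment-averaged
#' periodogram. One-sided density scaling, so the integral of the PSD over
#' frequency approximates the signal variance. The DC bin is dropped.
#'
#' @param ts An [aper_ts] (or numeric vector with `fs`).
#' @param seg_len Segment length in seconds (default 2, giving 0.5 Hz
#'   resolution).
#' @param overlap Segment overlap proportion in \[0, 1) (default 0.5).
#' @param fs Sampling rate when `ts` is a bare vector.
#' @return An [aper_psd].
#' @examples
#' ps <- compute_psd(sim_powerlaw(5000, 250, 1, seed = 1))
#' @export
compute_psd <- function(ts, seg_len = 2, overlap = 0.5, fs = NULL) {
  ts <- as_aper_ts(ts, fs)
  check_scalar_num(seg_len, "seg_len", lower = 0, strict_lower = TRUE)
  check_scalar_num(overlap, "overlap", lower = 0, upper = 1)
  if (overlap >= 1) stop_invalid("`overlap` must be < 1")
  x <- ts$samples
  nper <- as.integer(round(seg_len * ts$fs))
  if (nper > length(x)) {
    stop_invalid("segment (%d samples) longer than the signal (%d)",
                 nper, length(x))
  }
  step <- max(1L, as.integer(round(nper * (1 - overlap))))
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nper - 1) / nper)  # periodic Hann
  scale <- 1 / (ts$fs * sum(w^2))
  half <- nper %/% 2L
  acc <- numeric(half + 1L)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(fft(seg))^2 * scale
    acc <- acc + p[1:(half + 1L)]
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist for even nper)
  dbl <- rep(2, half + 1L)
  dbl[1L] <- 1
  if (nper %% 2L == 0L) dbl[half + 1L] <- 1
  psd <- psd * dbl
  freqs <- (0:half) * ts$fs / nper
  aper_psd(freqs[-1L], psd[-1L])
}

#' Normalized spectral entropy
#'
#' Shannon entropy of the power-normalized spectrum, divided by
#' `log(n_bins)` so a flat spectrum scores 1 and a single-bin spectrum 0.
#'
#' @param ps An [aper_psd].
#' @return Entropy in \[0, 1\] (double).
#' @export
spectral_entropy <- function(ps) {
  p <- ps$power
  if (any(p < 0)) stop_invalid("spectral powers must be nonnegative")
  tot <- sum(p)
  if (tot == 0) stop_invalid("all-zero spectrum has no entropy")
  p <- p[p > 0] / tot
  -sum(p * log(p)) / log(length(ps$power))
}
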