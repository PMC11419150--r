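# Time-domain aperiodic measures. Defaults follow the standard evaluation
# settings: autocorrelation max_lag 250 / step 1; decay-time max_lag 1500 /
# step 2 / level 0.5; Hurst and DFA over 10 log-spaced scales 0.1-2.0 s
# (DFA degree 1); Higuchi kmax 10; Lempel-Ziv unnormalized; ApEn/SampEn
# order 2 with r = 0.2 sd; permutation entropy order 3, delay 1.

# Biased (divide-by-n) autocorrelation via FFT.
acf_biased <- function(x, max_lag) {
  n <- length(x)
  if (sd(x) == 0) stop_degenerate("autocorrelation of a constant signal is undefined")
  x <- x - mean(x)
  nfft <- nextn(2L * n, 2)
  sp <- Mod(fft(c(x, rep(0, nfft - n))))^2
  ac <- Re(fft(sp, inverse = TRUE))[1:(max_lag + 1L)] / nfft
  ac / ac[1L]
}

#' Autocorrelation function over a set of lags
#'
#' The correlation of the signal with itself at increasing time lags, using
#' the biased (divide-by-n) estimator.
#'
#' @param ts An [aper_ts] (or numeric vector with `fs`).
#' @param max_lag Maximum lag in samples (< signal length).
#' @param lag_step Lag step in samples.
#' @param fs Sampling rate when `ts` is a bare vector.
#' @return A tibble with columns `lag` (samples), `time` (s), `corr`.
#' @export
ts_autocorr <- function(ts, max_lag = 250, lag_step = 1, fs = NULL) {
  ts <- as_aper_ts(ts, fs)
  check_scalar_num(max_lag, "max_lag", lower = 1)
  check_scalar_num(lag_step, "lag_step", lower = 1)
  if (max_lag >= n_samples(ts)) {
    stop_invalid("max_lag (%d) must be below the signal length (%d)",
                 max_lag, n_samples(ts))
  }
  ac <- acf_biased(ts$samples, as.integer(max_lag))
  lags <- seq(0L, as.integer(max_lag), by = as.integer(lag_step))
  tibble::tibble(lag = lags, time = lags / ts$fs, corr = ac[lags + 1L])
}

#' Autocorrelation decay time
#'
#' The smallest time lag at which the autocorrelation has decayed to (or
#' below) `level`. If the autocorrelation never reaches `level` within
#' `max_lag`, the result is censored at `max_lag` (in seconds) and carries
#' attribute `censored = TRUE`.
#'
#' @inheritParams ts_autocorr
#' @param level Correlation threshold in (0, 1).
#' @return Decay time in seconds (double), with attribute `censored`.
#' @export
ts_ac_decay_time <- function(ts, max_lag = 1500, lag_step = 2, level = 0.5,
                             fs = NULL) {
  ts <- as_aper_ts(ts, fs)
  check_scalar_num(level, "level", lower = 0, upper = 1)
  if (level <= 0 || level >= 1) stop_invalid("`level` must be in (0, 1)")
  ac <- ts_autocorr(ts, max_lag = max_lag, lag_step = lag_step)
  hit <- which(ac$corr <= level & ac$lag > 0)
  if (length(hit) == 0L) {
    return(structure(max_lag / ts$fs, censored = TRUE))
  }
  structure(ac$time[hit[1L]], censored = FALSE)
}

#' Hurst exponent by rescaled-range analysis
#'
#' Computes the rescaled range R/S over non-overlapping windows at
#' log-spaced scales (per-window mean detrending) and returns the log-log
#' slope of mean R/S versus window length.
#'
#' @inheritParams ts_autocorr
#' @param n_scales Number of log-spaced scales.
#' @param min_scale,max_scale Scale bounds in seconds.
#' @return The Hurst exponent H (double).
#' @export
ts_hurst <- function(ts, n_scales = 10, min_scale = 0.1, max_scale = 2.0,
                     fs = NULL) {
  ts <- as_aper_ts(ts, fs)
  x <- ts$samples
  if (sd(x) == 0) stop_degenerate("rescaled range of a constant signal is undefined")
  if (max_scale * ts$fs > length(x)) {
    stop_invalid("max_scale (%g s) exceeds the signal duration", max_scale)
  }
  wins <- log_spaced_scales(min_scale, max_scale, n_scales, ts$fs)
  rs <- vapply(wins, function(w) {
    n_win <- length(x) %/% w
    vals <- vapply(seq_len(n_win), function(i) {
      seg <- x[((i - 1) * w + 1):(i * w)]
      s <- sd(seg)
      if (s == 0) return(NA_real_)
      z <- cumsum(seg - mean(seg))
      (max(z) - min(z)) / s
    }, 1.0)
    mean(vals, na.rm = TRUE)
  }, 1.0)
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 2L) stop_degenerate("too few valid scales for R/S fit")
  ols_slope(log(wins[ok]), log(rs[ok]))
}

#' Detrended fluctuation analysis
#'
#' The profile is the cumulative sum of the mean-centered signal; within
#' non-overlapping windows at log-spaced scales the profile is detrended by
#' a least-squares polynomial of degree `order`, and the fluctuation at each
#' scale is the RMS of the residuals. The DFA exponent alpha is the log-log
#' slope of fluctuation versus scale.
#'
#' @inheritParams ts_hurst
#' @param order Detrending polynomial degree (default 1, linear).
#' @return The DFA exponent alpha (double).
#' @export
ts_dfa <- function(ts, n_scales = 10, min_scale = 0.1, max_scale = 2.0,
                   order = 1, fs = NULL) {
  ts <- as_aper_ts(ts, fs)
  x <- ts$samples
  if (sd(x) == 0) stop_degenerate("DFA of a constant signal is undefined")
  check_scalar_num(order, "order", lower = 0)
  if (max_scale * ts$fs > length(x)) {
    stop_invalid("max_scale (%g s) exceeds the signal duration", max_scale)
  }
  profile <- cumsum(x - mean(x))
  wins <- log_spaced_scales(min_scale, max_scale, n_scales, ts$fs)
  flucts <- vapply(wins, function(w) {
    n_win <- length(profile) %/% w
    p <- matrix(profile[seq_len(n_win * w)], nrow = w)
    t0 <- seq_len(w)
    des <- vapply(0:order, function(k) t0^k, numeric(w))
    qr_des <- qr(des)
    res <- p - des %*% qr.coef(qr_des, p)
    sqrt(mean(res^2))
  }, 1.0)
  ok <- is.finite(flucts) & flucts > 0
  if (sum(ok) < 2L) stop_degenerate("zero fluctuation: DFA undefined")
  ols_slope(log(wins[ok]), log(flucts[ok]))
}

#' Fractal dimension of a time series
#'
#' Three estimators of the curve dimension in \[1, 2\]:
#' * `higuchi`: slope of log mean curve length versus log(1/k) for
#'   k = 1..kmax;
#' * `katz`: `log10(n) / (log10(n) + log10(d / L))` with `L` the total
#'   absolute path length, `d` the maximum absolute excursion from the first
#'   sample, and `n` the number of steps;
#' * `petrosian`: `log10(n) / (log10(n) + log10(n / (n + 0.4 * Nd)))` with
#'   `Nd` the number of sign changes of the first difference.
#'
#' @inheritParams ts_autocorr
#' @param method One of `"higuchi"`, `"katz"`, `"petrosian"`.
#' @param kmax Maximum segment skip for Higuchi (default 10).
#' @return The fractal dimension D (double).
#' @export
ts_fractal_dim <- function(ts, method = c("higuchi", "katz", "petrosian"),
                           kmax = 10, fs = NULL) {
  ts <- as_aper_ts(ts, fs)
  method <- match.arg(method)
  x <- ts$samples
  if (sd(x) == 0) stop_degenerate("fractal dimension of a constant signal is undefined")
  n <- length(x)
  switch(method,
    higuchi = {
      check_scalar_num(kmax, "kmax", lower = 2)
      if (n < 3 * kmax) stop_invalid("signal too short for Higuchi with kmax = %d", kmax)
      lk <- higuchi_lengths_cpp(x, as.integer(kmax))
      k <- seq_len(kmax)
      ols_slope(log(1 / k), log(lk))
    },
    katz = {
      L <- sum(abs(diff(x)))
      d <- max(abs(x - x[1L]))
      if (L == 0 || d == 0) stop_degenerate("Katz dimension undefined for flat signal")
      nn <- n - 1
      log10(nn) / (log10(nn) + log10(d / L))
    },
    petrosian = {
      dx <- diff(x)
      nd <- sum(diff(sign(dx[dx != 0])) != 0)
      log10(n) / (log10(n) + log10(n / (n + 0.4 * nd)))
    })
}

#' Hjorth parameters
#'
#' Activity (variance), mobility (standard-deviation ratio of the first
#' difference to the signal), and complexity (mobility of the first
#' difference over mobility of the signal).
#'
#' @inheritParams ts_autocorr
#' @return A named double vector `c(activity, mobility, complexity)`.
#' @export
ts_hjorth <- function(ts, fs = NULL) {
  ts <- as_aper_ts(ts, fs)
  x <- ts$samples
  v0 <- var(x)
  if (v0 == 0) stop_degenerate("Hjorth parameters of a constant signal are undefined")
  d1 <- diff(x)
  d2 <- diff(d1)
  v1 <- var(d1)
  v2 <- var(d2)
  mob <- sqrt(v1 / v0)
  c(activity = v0, mobility = mob, complexity = sqrt(v2 / v1) / mob)
}

#' Lempel-Ziv complexity
#'
#' Binarizes the signal at its median and counts the number of phrases in
#' the LZ76 parsing. With `normalize = TRUE` the count is divided by
#' `n / log2(n)`.
#'
#' @inheritParams ts_autocorr
#' @param normalize Divide by the random-sequence asymptote? Default `FALSE`.
#' @return The (possibly normalized) complexity (double).
#' @export
ts_lempel_ziv <- function(ts, normalize = FALSE, fs = NULL) {
  ts <- as_aper_ts(ts, fs)
  x <- ts$samples
  b <- as.integer(x > median(x))
  cc <- lz76_cpp(b)
  if (normalize) cc / (length(x) / log2(length(x))) else as.numeric(cc)
}

#' Approximate and sample entropy
#'
#' Regularity statistics over embedded templates of length `order` with
#' Chebyshev tolerance `r_frac * sd(signal)`. Sample entropy excludes
#' self-matches; approximate entropy includes them. A sample-entropy
#' computation with zero template matches is censored (returns `Inf` with
#' attribute `censored = TRUE`).
#'
#' @inheritParams ts_autocorr
#' @param method `"sample"` or `"approximate"`.
#' @param order Template length m (default 2).
#' @param r_frac Tolerance as a multiple of the signal standard deviation
#'   (default 0.2).
#' @return A nonnegative double (with attribute `censored` for sample
#'   entropy).
#' @export
ts_regularity_entropy <- function(ts, method = c("sample", "approximate"),
                                  order = 2, r_frac = 0.2, fs = NULL) {
  ts <- as_aper_ts(ts, fs)
  method <- match.arg(method)
  check_scalar_num(order, "order", lower = 1)
  check_scalar_num(r_frac, "r_frac", lower = 0, strict_lower = TRUE)
  x <- ts$samples
  if (length(x) <= order + 1) stop_invalid("signal too short for order %d", order)
  s <- sd(x)
  if (s == 0) return(structure(0, censored = FALSE)) # constant: fully regular
  r <- r_frac * s
  if (method == "sample") {
    ab <- sampen_counts_cpp(x, as.integer(order), r)
    if (ab[2L] == 0 || ab[1L] == 0) {
      return(structure(Inf, censored = TRUE))
    }
    structure(-log(ab[1L] / ab[2L]), censored = FALSE)
  } else {
    structure(apen_cpp(x, as.integer(order), r), censored = FALSE)
  }
}

#' Permutation entropy
#'
#' Shannon entropy of the ordinal-pattern (motif) distribution of embedded
#' segments, normalized by `log(order!)` to \[0, 1\]. Ties within a segment
#' are broken by temporal order (earlier samples rank lower). The weighted
#' variant weights each motif occurrence by the variance of its segment.
#'
#' @inheritParams ts_autocorr
#' @param order Motif length (default 3).
#' @param delay Embedding delay in samples (default 1).
#' @param weighted Weight motifs by segment variance? Default `FALSE`.
#' @return Normalized entropy in \[0, 1\] (double).
#' @export
ts_permutation_entropy <- function(ts, order = 3, delay = 1,
                                   weighted = FALSE, fs = NULL) {
  ts <- as_aper_ts(ts, fs)
  check_scalar_num(order, "order", lower = 2)
  check_scalar_num(delay, "delay", lower = 1)
  x <- ts$samples
  m <- as.integer(order); d <- as.integer(delay)
  n_vec <- length(x) - (m - 1L) * d
  if (n_vec < 1L) stop_invalid("signal too short for order %d, delay %d", m, d)
  seg <- vapply(seq_len(m), function(k) x[seq_len(n_vec) + (k - 1L) * d],
                numeric(n_vec))
  # stable ranks: ties broken by temporal order within the segment
  code <- rep(0, n_vec)
  for (k in seq_len(m)) {
    rk <- rep(0L, n_vec)
    for (j in seq_len(m)) {
      if (j == k) next
      rk <- rk + if (j < k) (seg[, j] <= seg[, k]) else (seg[, j] < seg[, k])
    }
    code <- code + rk * m^(k - 1)
  }
  w <- if (weighted) {
    mu <- rowMeans(seg)
    rowMeans((seg - mu)^2)
  } else {
    rep(1, n_vec)
  }
  if (sum(w) == 0) return(0)
  p <- tapply(w, code, sum) / sum(w)
  p <- p[p > 0]
  h <- -sum(p * log(p))
  h / log(factorial(m))
}
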