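#' Direct spectral line fits of the aperiodic exponent
#'
#' Fits the aperiodic exponent directly to a power spectrum, with four
#' estimators:
#' * `ols` — ordinary least squares on log10(power) vs log10(freq);
#' * `rlm` — Huber robust linear model in the same space;
#' * `ransac` — random sample consensus line fit (inlier threshold scaled by
#'   the median absolute deviation of an initial OLS fit's residuals; 100
#'   iterations; internally seeded for determinism);
#' * `exp` — nonlinear least-squares fit (Levenberg-Marquardt), in semi-log
#'   space (log10 power vs linear frequency), of the exponential 1/f form
#'   `offset - log10(knee + f^exponent)`; the reported exponent is the
#'   fitted exponent parameter. Unlike the log-log line fits this form can
#'   bend, which gives it freedom that overlying peaks readily exploit.
#'
#' An optional frequency band (e.g. the alpha band, 7-14 Hz) can be excluded
#' from fitting to avoid oscillatory peaks.
#'
#' @param ps An [aper_psd].
#' @param frange Length-2 fit range in Hz (default `c(1, 50)`).
#' @param method One of `"ols"`, `"rlm"`, `"ransac"`, `"exp"`.
#' @param exclusion Optional length-2 Hz band removed before fitting
#'   (`NULL` = none).
#' @param ransac_seed,ransac_iter RANSAC determinism/effort settings.
#' @return A one-row tibble: `method`, `offset`, `exponent`, `error` (mean
#'   absolute log10 residual), `n_bins`.
#' @examples
#' ps <- sim_power_spectrum(exponent = 2, noise_sd = 0)
#' fit_spectral_line(ps, method = "ols")$exponent
#' @export
fit_spectral_line <- function(ps, frange = c(1, 50),
                              method = c("ols", "rlm", "ransac", "exp"),
                              exclusion = NULL,
                              ransac_seed = 42L, ransac_iter = 100L) {
  method <- match.arg(method)
  sub <- trim_psd(ps, frange)
  if (!is.null(exclusion)) {
    stopifnot(length(exclusion) == 2L)
    sub <- sub[!(sub$freq >= exclusion[1L] & sub$freq <= exclusion[2L]), ]
  }
  if (nrow(sub) < 4L) stop_invalid("fewer than 4 frequency bins left to fit")
  if (any(sub$power <= 0)) stop_invalid("log fit requires positive powers")
  f <- sub$freq
  lx <- log10(f)
  ly <- log10(sub$power)
  fit <- switch(method,
    ols = {
      co <- lm.fit(cbind(1, lx), ly)$coefficients
      list(offset = co[1L], exponent = -co[2L],
           pred = co[1L] + co[2L] * lx)
    },
    rlm = {
      m <- MASS::rlm(ly ~ lx, maxit = 50)
      co <- coef(m)
      list(offset = co[1L], exponent = -co[2L],
           pred = co[1L] + co[2L] * lx)
    },
    ransac = ransac_line(lx, ly, seed = ransac_seed, n_iter = ransac_iter),
    exp = {
      df <- data.frame(f = f, ly = ly)
      slope0 <- max(0.1, -(ly[length(ly)] - ly[1L]) /
                      (lx[length(lx)] - lx[1L]))
      m <- minpack.lm::nlsLM(
        ly ~ a - log10(k + f^chi), data = df,
        start = list(a = ly[1L], k = 0, chi = slope0),
        lower = c(-Inf, 0, 0), upper = c(Inf, Inf, 10),
        control = minpack.lm::nls.lm.control(maxiter = 200))
      co <- coef(m)
      list(offset = unname(co["a"]), exponent = unname(co["chi"]),
           pred = predict(m))
    })
  tibble::tibble(method = method,
                 offset = unname(fit$offset),
                 exponent = unname(fit$exponent),
                 error = mean(abs(ly - fit$pred)),
                 n_bins = length(f))
}

# RANSAC line fit in (x, y): minimal 2-point samples, MAD-scaled inlier
# threshold, consensus refit by OLS on the best inlier set.
ransac_line <- function(x, y, seed = 42L, n_iter = 100L) {
  n <- length(x)
  co0 <- lm.fit(cbind(1, x), y)$coefficients
  res0 <- y - (co0[1L] + co0[2L] * x)
  thresh <- max(2.5 * mad(res0), 1e-12)
  best_inliers <- rep(TRUE, n)
  best_count <- -1L
  with_seed(seed, {
    for (i in seq_len(n_iter)) {
      idx <- sample.int(n, 2L)
      dx <- x[idx[2L]] - x[idx[1L]]
      if (dx == 0) next
      slope <- (y[idx[2L]] - y[idx[1L]]) / dx
      inter <- y[idx[1L]] - slope * x[idx[1L]]
      inl <- abs(y - (inter + slope * x)) <= thresh
      if (sum(inl) > best_count) {
        best_count <- sum(inl)
        best_inliers <- inl
      }
    }
  })
  if (sum(best_inliers) < 2L) best_inliers <- rep(TRUE, n)
  co <- lm.fit(cbind(1, x[best_inliers]), y[best_inliers])$coefficients
  list(offset = co[1L], exponent = -co[2L], pred = co[1L] + co[2L] * x)
}
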