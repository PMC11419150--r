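test_that("Welch PSD satisfies Parseval and locates tones", {
  ps <- compute_psd(fix_white(n = 7500))
  expect_lt(abs(sum(ps$power) * (ps$freq[2] - ps$freq[1]) - 1), 0.05)
  pt <- compute_psd(fix_sine(n = 7500, freq = 10))
  expect_equal(pt$freq[which.max(pt$power)], 10)
  # chi = 1 signal: log-log slope ~ -1 (regression oracle)
  expect_lt(abs(ols_psd_exponent(fix_pink(n = 7500)) - 1), 0.15)
  expect_error(compute_psd(fix_white(n = 100), seg_len = 2),
               class = "aperiodica_invalid_argument")
})

test_that("all line-fit methods recover a noiseless power law exactly", {
  ps <- sim_power_spectrum(c(1, 50), 0.5, offset = 0, exponent = 2,
                           noise_sd = 0)
  expect_equal(fit_spectral_line(ps, method = "ols")$exponent, 2,
               tolerance = 1e-10)
  for (m in c("rlm", "ransac", "exp")) {
    expect_equal(fit_spectral_line(ps, method = m)$exponent, 2,
                 tolerance = 0.02)
  }
})

test_that("alpha exclusion reduces the OLS error under an alpha peak", {
  errs <- purrr::map_dfr(1:20, function(i) {
    ps <- sim_power_spectrum(c(1, 50), 0.5, exponent = 1.5,
                             peaks = data.frame(cf = 10, pw = 1, bw = 2),
                             noise_sd = 0.005, seed = 400 + i)
    tibble::tibble(
      plain = abs(fit_spectral_line(ps, method = "ols")$exponent - 1.5),
      excl = abs(fit_spectral_line(ps, method = "ols",
                                   exclusion = c(7, 14))$exponent - 1.5))
  })
  expect_lte(median(errs$excl), median(errs$plain))
})

test_that("RANSAC ignores a displaced band of outlier bins", {
  ps <- sim_power_spectrum(c(1, 50), 0.5, offset = 0, exponent = 2,
                           noise_sd = 0)
  bad <- ps$freq >= 20 & ps$freq <= 24
  ps$power[bad] <- ps$power[bad] * 10   # +1 log10 unit
  expect_lt(abs(fit_spectral_line(ps, method = "ransac")$exponent - 2),
            0.05)
})

test_that("too few bins raises an invalid-argument error", {
  ps <- sim_power_spectrum(c(1, 50), 0.5, exponent = 1, noise_sd = 0)
  expect_error(fit_spectral_line(ps, frange = c(1, 2)),
               class = "aperiodica_invalid_argument")
})

test_that("spectral parameterization recovers in-model spectra", {
  # noiseless aperiodic-only: near machine precision, no peaks
  ps <- sim_power_spectrum(c(1, 50), 0.5, offset = 0, exponent = 1.5,
                           noise_sd = 0)
  g <- glance(specparam(ps))
  expect_lt(abs(g$exponent - 1.5), 1e-3)
  expect_equal(g$n_peaks, 0)
  expect_gt(g$r_squared, 0.999)
  # one peak with small noise: cf within 0.5 Hz, exponent error < 0.05
  ps2 <- sim_power_spectrum(c(1, 50), 0.5, exponent = 1,
                            peaks = data.frame(cf = 10, pw = 0.5, bw = 2),
                            noise_sd = 0.005, seed = 7)
  m2 <- specparam(ps2)
  expect_lt(abs(glance(m2)$exponent - 1), 0.05)
  pk <- tidy(m2)
  expect_gte(nrow(pk), 1)
  expect_lt(abs(pk$cf[which.max(pk$pw)] - 10), 0.5)
})

test_that("knee-mode parameterization recovers knee spectra within 5%", {
  ps <- sim_power_spectrum(c(1, 100), 0.5, offset = 1, exponent = 2,
                           knee = 100,
                           peaks = data.frame(cf = 10, pw = 0.5, bw = 2),
                           noise_sd = 0.005, seed = 11)
  g <- glance(specparam(ps, c(1, 100), mode = "knee", max_n_peaks = 12,
                        min_peak_height = 0.1))
  expect_lt(abs(g$exponent - 2) / 2, 0.05)
  expect_lt(abs(g$knee - 100) / 100, 0.25)
})

test_that("aperiodic-only fits match the full model on clean spectra", {
  ps <- sim_power_spectrum(c(1, 50), 0.5, offset = 0.5, exponent = 1.2,
                           noise_sd = 0)
  ap <- fit_aperiodic(ps)
  expect_equal(ap$exponent, 1.2, tolerance = 1e-8)
  expect_equal(ap$offset, 0.5, tolerance = 1e-8)
  # fixed-mode fit of a knee spectrum underestimates the exponent
  psk <- sim_power_spectrum(c(1, 100), 0.5, exponent = 2, knee = 100,
                            noise_sd = 0)
  expect_lt(fit_aperiodic(psk, c(1, 100))$exponent, 2)
  # knee = 0 knee-mode fit agrees with fixed-mode fit
  apk <- fit_aperiodic(ps, mode = "knee")
  expect_lt(abs(apk$exponent - 1.2), 0.01)
})

test_that("dominant peak power picks the largest in-band peak", {
  ps <- sim_power_spectrum(
    c(1, 50), 0.5, exponent = 1,
    peaks = data.frame(cf = c(10, 12), pw = c(0.3, 0.6), bw = c(2, 2)),
    noise_sd = 0.002, seed = 3)
  m <- specparam(ps)
  expect_lt(abs(dominant_peak_power(m, c(7, 14)) - 0.6), 0.15)
  expect_equal(dominant_peak_power(m, c(30, 40)), 0)
})

test_that("IRASA passes through scale-free spectra and isolates peaks", {
  x <- sim_powerlaw(15000, 500, 1.5, seed = 21)
  dec <- irasa(x)
  expect_lt(abs(irasa_fit(dec)$exponent -
                  fit_aperiodic(aper_psd(dec$freqs, dec$psd))$exponent),
            0.05)
  cmb <- combine_signals(x, sim_oscillation(15000, 500, 10, seed = 22), 1)
  dec2 <- irasa(cmb)
  expect_equal(dec2$freqs[which.max(dec2$periodic)], 10, tolerance = 0.51)
  expect_lt(abs(irasa_fit(dec2)$exponent - 1.5), 0.1)
  expect_error(irasa(x, hset = c(0.9, 1.1)),
               class = "aperiodica_invalid_argument")
})

test_that("spectral entropy spans flat to concentrated spectra", {
  flat <- aper_psd(1:100, rep(2, 100))
  expect_equal(spectral_entropy(flat), 1, tolerance = 1e-12)
  point <- aper_psd(1:100, c(rep(0, 50), 5, rep(0, 49)))
  expect_equal(spectral_entropy(point), 0, tolerance = 1e-12)
  expect_gt(spectral_entropy(compute_psd(fix_white())),
            spectral_entropy(compute_psd(fix_brown())))
  expect_error(spectral_entropy(aper_psd(1:10, rep(0, 10))),
               class = "aperiodica_invalid_argument")
})
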