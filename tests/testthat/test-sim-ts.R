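test_that("power-law simulation recovers the requested exponent", {
  # white noise: slope ~ 0; pink: ~1; exponent recovery across a grid
  expect_lt(abs(ols_psd_exponent(sim_powerlaw(7500, 250, 0, seed = 1))), 0.05)
  for (chi in c(0.5, 1, 2, 3)) {
    fitted <- mean(vapply(1:5, function(i) {
      ols_psd_exponent(sim_powerlaw(7500, 250, chi, seed = 100 * chi + i))
    }, 1.0))
    expect_lt(abs(fitted - chi), 0.1)
  }
})

test_that("differencing a brown-noise signal yields a white spectrum", {
  x <- sim_powerlaw(7500, 250, 2, seed = 42)
  dx <- aper_ts(diff(x$samples), x$fs)
  expect_lt(abs(ols_psd_exponent(dx, frange = c(1, 30))), 0.25)
})

test_that("simulated signals are z-scored and reproducible", {
  x <- sim_powerlaw(1000, 250, 1.5, seed = 9)
  expect_equal(mean(x$samples), 0, tolerance = 1e-12)
  expect_equal(sd(x$samples), 1, tolerance = 1e-12)
  y <- sim_powerlaw(1000, 250, 1.5, seed = 9)
  expect_identical(x$samples, y$samples)
  z <- sim_powerlaw(1000, 250, 1.5, seed = 10)
  expect_false(identical(x$samples, z$samples))
})

test_that("power-law simulation validates its arguments", {
  expect_error(sim_powerlaw(8, 250, 1), class = "aperiodica_invalid_argument")
  expect_error(sim_powerlaw(1000, -1, 1), class = "aperiodica_invalid_argument")
  expect_error(sim_powerlaw(1000, 250, -0.5),
               class = "aperiodica_invalid_argument")
})

test_that("synaptic knee signals have a Lorentzian spectrum", {
  # high-frequency slope ~ -2 above the knee for tau = 0.015 (knee ~10.6 Hz)
  x <- sim_synaptic_knee(15000, 500, 0.015, seed = 5)
  ps <- compute_psd(x)
  hi <- ps$freq >= 30 & ps$freq <= 100
  slope <- unname(coef(lm(log10(ps$power[hi]) ~ log10(ps$freq[hi])))[2])
  expect_lt(abs(slope + 2), 0.35)
  # every grid value yields a valid normalized signal
  for (tau in c(0.005, 0.015, 0.030, 0.050, 0.075)) {
    y <- sim_synaptic_knee(5000, 500, tau, seed = 1)
    expect_s3_class(y, "aper_ts")
    expect_equal(sd(y$samples), 1, tolerance = 1e-12)
  }
  expect_error(sim_synaptic_knee(5000, 500, 0),
               class = "aperiodica_invalid_argument")
})

test_that("fitted knee frequency decreases across the tau grid", {
  taus <- c(0.005, 0.015, 0.030, 0.050, 0.075)
  knee_freq <- vapply(taus, function(tau) {
    x <- sim_synaptic_knee(15000, 500, tau, seed = 77)
    g <- glance(specparam(compute_psd(x), c(1, 100), mode = "knee",
                          max_n_peaks = 12, min_peak_height = 0.1))
    g$knee^(1 / g$exponent)
  }, 1.0)
  expect_true(all(diff(knee_freq) < 0))
  # tau = 0.015 places the knee near 1 / (2 pi tau) ~ 10.6 Hz
  expect_lt(abs(knee_freq[2] - 1 / (2 * pi * 0.015)), 3)
})

test_that("oscillation simulation honors frequency and burst probability", {
  o <- sim_oscillation(7500, 250, 10, seed = 1)
  ps <- compute_psd(o)
  expect_equal(ps$freq[which.max(ps$power)], 10, tolerance = 0.51)
  # burst_prob 0: silent signal
  z <- sim_oscillation(7500, 250, 10, burst_prob = 0, seed = 1)
  expect_true(all(z$samples == 0))
  # burst_prob 0.5 on a long signal: about half the cycles present
  b <- sim_oscillation(75000, 250, 10, burst_prob = 0.5, seed = 3)
  frac <- var(b$samples) / var(o$samples)
  expect_lt(abs(frac - 0.5), 0.1)   # binomial sd at 3000 cycles ~ 0.01
  expect_error(sim_oscillation(1000, 250, 130),
               class = "aperiodica_invalid_argument")
})

test_that("bandwidth jitter broadens the spectral peak", {
  narrow <- compute_psd(sim_oscillation(75000, 250, 10, seed = 4))
  broad <- compute_psd(sim_oscillation(75000, 250, 10, bandwidth = 2,
                                       seed = 4))
  width_at <- function(ps) {
    pk <- max(ps$power)
    sum(ps$power >= pk / 10)
  }
  expect_gt(width_at(broad), width_at(narrow))
})

test_that("combining signals obeys the variance contract", {
  ap <- fix_pink()
  per <- fix_sine()
  expect_identical(combine_signals(ap, per, 0)$samples, zs <- {
    s <- ap$samples
    (s - mean(s)) / sd(s)
  })
  for (rp in c(0.5, 1, 2)) {
    cmb <- combine_signals(ap, per, rp)
    expect_lt(abs(var(cmb$samples) - (1 + rp)), 0.15 * (1 + rp))
  }
  # spectral peak power grows monotonically with rel_power
  peak_power <- vapply(c(0, 0.5, 1, 2), function(rp) {
    ps <- compute_psd(combine_signals(ap, per, rp))
    ps$power[which.min(abs(ps$freq - 10))]
  }, 1.0)
  expect_true(all(diff(peak_power) > 0))
  expect_error(combine_signals(ap, aper_ts(per$samples[1:100], 250), 1),
               class = "aperiodica_invalid_argument")
  expect_error(combine_signals(ap, aper_ts(per$samples, 500), 1),
               class = "aperiodica_invalid_argument")
})

test_that("parameter sweeps have the documented shape and determinism", {
  base <- sim_spec(duration = 2, fs = 250, seed = 3)
  sw <- sim_param_sweep("exponent", seq(0, 3, by = 0.5), 50, base)
  expect_equal(nrow(sw), 350)
  sw_f <- sim_param_sweep("freq", 5:35, 1, base)
  expect_equal(nrow(sw_f), 31)
  expect_true(all(sw_f$rel_power == 1))
  expect_equal(nrow(sim_param_sweep("exponent", numeric(), 5, base)), 0)
  expect_error(sim_param_sweep("wiggle", 1:3, 1, base),
               class = "aperiodica_invalid_argument")
  # per-row seeds: regenerating one row reproduces it
  i <- 37
  spec_i <- sim_spec(duration = 2, fs = 250, exponent = sw$value[i],
                     seed = sw$seed[i])
  expect_identical(simulate_spec(spec_i)$samples, sw$signal[[i]]$samples)
})

test_that("the comparison set has the documented composition", {
  cs <- sim_comparison_set(100, frac_aperiodic = 0.3, seed = 21,
                           duration = 2)
  expect_equal(sum(cs$kind == "aperiodic"), 30)
  expect_equal(sum(cs$kind == "combined"), 70)
  expect_true(all(is.na(cs$freq[cs$kind == "aperiodic"])))
  expect_true(all(cs$freq[cs$kind == "combined"] %in% 5:35))
  expect_true(all(cs$exponent %in% seq(0, 2.5, by = 0.1)))
  expect_true(all(abs(cs$rel_power[cs$kind == "combined"] -
                        round(cs$rel_power[cs$kind == "combined"], 1)) < 1e-9))
  # pure aperiodic when frac = 1
  cs1 <- sim_comparison_set(10, frac_aperiodic = 1, seed = 2, duration = 2)
  expect_true(all(cs1$kind == "aperiodic"))
  # determinism
  a <- sim_comparison_set(10, seed = 5, duration = 2)
  b <- sim_comparison_set(10, seed = 5, duration = 2)
  expect_identical(purrr::map(a$signal, "samples"),
                   purrr::map(b$signal, "samples"))
  expect_error(sim_comparison_set(0), class = "aperiodica_invalid_argument")
})
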