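test_that("autocorrelation is 1 at lag 0 and periodic for a sinusoid", {
  s <- fix_sine(n = 5000, fs = 250, freq = 10)
  ac <- ts_autocorr(s, max_lag = 250)
  expect_equal(ac$corr[1], 1, tolerance = 1e-12)
  expect_true(all(ac$corr >= -1 - 1e-9 & ac$corr <= 1 + 1e-9))
  # one full period at fs = 250 and 10 Hz is 25 samples
  expect_gt(ac$corr[ac$lag == 25], 0.95)
  # white noise: all nonzero lags small
  acw <- ts_autocorr(fix_white(), max_lag = 250)
  expect_lt(max(abs(acw$corr[acw$lag > 0])), 3 / sqrt(5000))
  expect_error(ts_autocorr(aper_ts(rep(1, 1000) + 0 * 1:1000, 250)),
               class = "aperiodica_degenerate_input")
})

test_that("mean autocorrelation increases with the aperiodic exponent", {
  mean_ac <- vapply(c(0, 1, 2), function(chi) {
    mean(vapply(1:5, function(i) {
      ac <- ts_autocorr(sim_powerlaw(5000, 250, chi, seed = 30 * chi + i))
      mean(ac$corr[ac$lag > 0])
    }, 1.0))
  }, 1.0)
  expect_true(all(diff(mean_ac) > 0))
})

test_that("autocorrelation decay time behaves at the extremes", {
  # white noise decays within one lag step
  v <- ts_ac_decay_time(fix_white())
  expect_false(attr(v, "censored"))
  expect_lte(as.numeric(v), 2 * 2 / 250)
  # a signal whose correlation never reaches the level within max_lag is
  # censored at max_lag (steep noise still correlated at a short horizon)
  slow <- sim_powerlaw(7500, 250, 2.8, seed = 808)
  vs <- ts_ac_decay_time(slow, max_lag = 40)
  expect_true(attr(vs, "censored"))
  expect_equal(as.numeric(vs), 40 / 250)
  # steeper exponent, longer decay (median over realizations)
  med_decay <- vapply(c(0.5, 2.5), function(chi) {
    median(vapply(1:7, function(i) {
      as.numeric(ts_ac_decay_time(sim_powerlaw(7500, 250, chi,
                                               seed = 50 * chi + i)))
    }, 1.0))
  }, 1.0)
  expect_gt(med_decay[2], med_decay[1])
})

test_that("Hurst exponent separates white noise from a random walk", {
  expect_lt(abs(ts_hurst(fix_white(n = 7500)) - 0.5), 0.12)
  walk <- aper_ts(cumsum(with_seed <- rnorm(7500)), 250)
  expect_gt(ts_hurst(walk), 0.85)
  h <- vapply(c(0, 0.5, 1), function(chi) {
    mean(vapply(1:5, function(i) {
      ts_hurst(sim_powerlaw(7500, 250, chi, seed = 70 * chi + i))
    }, 1.0))
  }, 1.0)
  expect_true(all(diff(h) > 0))
  expect_error(ts_hurst(aper_ts(rep(2, 1000) * 1, 250)),
               class = "aperiodica_degenerate_input")
})

test_that("DFA matches the colored-noise expectation", {
  # white noise alpha ~ 0.5, brown ~ 1.5
  expect_lt(abs(ts_dfa(fix_white(n = 7500)) - 0.5), 0.1)
  expect_lt(abs(ts_dfa(fix_brown(n = 7500)) - 1.5), 0.15)
  # affine invariance is exact
  x <- fix_pink()
  y <- aper_ts(3.7 * x$samples - 11, x$fs)
  expect_equal(ts_dfa(x), ts_dfa(y), tolerance = 1e-10)
})

test_that("fractal dimensions are correct on canonical inputs", {
  # Katz dimension of a strictly linear ramp is exactly 1
  ramp <- aper_ts(seq(0, 1, length.out = 1000), 250)
  expect_equal(ts_fractal_dim(ramp, "katz"), 1, tolerance = 1e-12)
  # Higuchi dimension of white noise ~ 2
  hig <- mean(vapply(1:5, function(i) {
    ts_fractal_dim(sim_powerlaw(5000, 250, 0, seed = 200 + i), "higuchi")
  }, 1.0))
  expect_lt(abs(hig - 2), 0.05)
  # all three decrease as the exponent increases
  for (meth in c("higuchi", "katz", "petrosian")) {
    d <- vapply(c(0, 1, 2), function(chi) {
      mean(vapply(1:5, function(i) {
        ts_fractal_dim(sim_powerlaw(5000, 250, chi, seed = 90 * chi + i),
                       meth)
      }, 1.0))
    }, 1.0)
    expect_true(all(diff(d) < 0), label = paste(meth, "monotone"))
  }
  expect_error(ts_fractal_dim(aper_ts(rep(0, 100) * 1, 250), "katz"),
               class = "aperiodica_degenerate_input")
})

test_that("Hjorth parameters obey their identities", {
  s <- fix_sine()
  h <- ts_hjorth(s)
  expect_equal(unname(h["complexity"]), 1, tolerance = 1e-3)
  # homogeneity: scaling by c multiplies activity by c^2 only
  x <- fix_pink()
  h1 <- ts_hjorth(x)
  h2 <- ts_hjorth(aper_ts(5 * x$samples, x$fs))
  expect_equal(unname(h2["activity"]), 25 * unname(h1["activity"]))
  expect_equal(unname(h2["mobility"]), unname(h1["mobility"]))
  expect_equal(unname(h2["complexity"]), unname(h1["complexity"]))
  # white noise is more complex than a sinusoid
  expect_gt(unname(ts_hjorth(fix_white())["complexity"]),
            unname(h["complexity"]))
})

test_that("Lempel-Ziv complexity ranks signal irregularity", {
  # constant signal: minimal phrase count
  flat <- aper_ts(c(0, rep(1, 999)) * 1.0, 250)
  expect_lte(ts_lempel_ziv(flat), 3)
  # alternating pattern is maximally compressible
  alt <- aper_ts(rep(c(-1, 1), 500) + seq(0, 0.001, length.out = 1000), 250)
  expect_lt(ts_lempel_ziv(alt, normalize = TRUE), 0.2)
  # white noise: normalized complexity ~ 1
  lz <- mean(vapply(1:5, function(i) {
    ts_lempel_ziv(sim_powerlaw(5000, 250, 0, seed = 300 + i),
                  normalize = TRUE)
  }, 1.0))
  expect_lt(abs(lz - 1), 0.1)
})

test_that("regularity entropies separate order from noise", {
  s <- fix_sine(n = 4000)
  noise <- fix_white(n = 4000)
  se_sine <- as.numeric(ts_regularity_entropy(s, "sample"))
  se_noise <- as.numeric(ts_regularity_entropy(noise, "sample"))
  expect_lt(se_sine, se_noise / 4)
  ae_sine <- as.numeric(ts_regularity_entropy(s, "approximate"))
  ae_noise <- as.numeric(ts_regularity_entropy(noise, "approximate"))
  expect_lt(ae_sine, ae_noise)
  expect_gte(ae_sine, 0)
  # affine invariance when the tolerance co-scales with sd
  x <- fix_pink(n = 3000)
  y <- aper_ts(4 * x$samples + 2, x$fs)
  expect_equal(as.numeric(ts_regularity_entropy(x, "sample")),
               as.numeric(ts_regularity_entropy(y, "sample")),
               tolerance = 1e-10)
})

test_that("permutation entropy spans ramp to noise", {
  ramp <- aper_ts(seq_len(1000) * 1.0, 250)
  expect_equal(ts_permutation_entropy(ramp), 0, tolerance = 1e-12)
  pe <- ts_permutation_entropy(fix_white(n = 7500))
  expect_gt(pe, 0.99)
  expect_lte(pe, 1)
  # weighted equals unweighted when all segments have equal variance
  s <- aper_ts(rep(c(-1, 1), 500) * 1.0, 250)
  expect_equal(ts_permutation_entropy(s, weighted = TRUE),
               ts_permutation_entropy(s, weighted = FALSE),
               tolerance = 1e-12)
})

test_that("the orientation pattern holds across the exponent grid", {
  # medians across chi: decay/hurst/dfa increase; fractal dim, LZ and
  # entropies decrease (5 realizations per chi, shortened signals)
  chis <- c(0, 1, 2, 3)
  res <- purrr::map_dfr(chis, function(chi) {
    purrr::map_dfr(1:5, function(i) {
      x <- sim_powerlaw(5000, 250, chi, seed = 1000 + 17 * chi + i)
      tibble::tibble(
        chi = chi,
        decay = as.numeric(ts_ac_decay_time(x)),
        hurst = ts_hurst(x),
        dfa = ts_dfa(x),
        higuchi = ts_fractal_dim(x, "higuchi"),
        lz = ts_lempel_ziv(x, normalize = TRUE),
        sampen = as.numeric(ts_regularity_entropy(x, "sample")),
        pe = ts_permutation_entropy(x))
    })
  })
  med <- dplyr::summarise(dplyr::group_by(res, chi),
                          dplyr::across(dplyr::everything(), median))
  expect_true(all(diff(med$decay) >= 0))
  expect_true(all(diff(med$hurst) > 0 | med$chi[-1] > 1)) # saturates high
  expect_true(all(diff(med$dfa) > 0))
  expect_true(all(diff(med$higuchi) < 0))
  expect_true(all(diff(med$lz) < 0))
  expect_true(all(diff(med$sampen) < 0))
  expect_true(all(diff(med$pe) < 0))
})
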