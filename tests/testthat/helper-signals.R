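# Shared fixtures: short signals built in code with fixed seeds.

fix_white <- function(n = 5000, fs = 250, seed = 101) {
  sim_powerlaw(n, fs, 0, seed = seed)
}

fix_pink <- function(n = 5000, fs = 250, seed = 102) {
  sim_powerlaw(n, fs, 1, seed = seed)
}

fix_brown <- function(n = 5000, fs = 250, seed = 103) {
  sim_powerlaw(n, fs, 2, seed = seed)
}

fix_sine <- function(n = 5000, fs = 250, freq = 10) {
  aper_ts(sin(2 * pi * freq * seq_len(n) / fs), fs)
}

# OLS log-log slope of the Welch PSD over a range: the independent
# exponent oracle used throughout.
ols_psd_exponent <- function(ts, frange = c(1, 50)) {
  ps <- compute_psd(ts)
  keep <- ps$freq >= frange[1] & ps$freq <= frange[2]
  -unname(coef(lm(log10(ps$power[keep]) ~ log10(ps$freq[keep])))[2])
}
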