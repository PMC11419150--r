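#' Simulation specification
#'
#' A complete, seedable description of one simulated signal: the aperiodic
#' component (power-law exponent, or synaptic decay time for knee signals),
#' an optional periodic component, duration and sampling rate.
#'
#' @param duration Signal duration in seconds (default 30, the standard
#'   evaluation length).
#' @param fs Sampling rate in Hz (default 250, the rate used for time-domain
#'   evaluations; frequency-domain evaluations conventionally use 500).
#' @param exponent Aperiodic exponent chi (ignored when `tau_d` is set).
#' @param tau_d Synaptic decay time in seconds; when finite, the aperiodic
#'   component is a knee signal from [sim_synaptic_knee()].
#' @param freq Oscillation center frequency (Hz); `NA` for no periodic
#'   component.
#' @param rel_power Oscillation variance relative to the aperiodic component.
#' @param bandwidth Oscillation spectral width proxy (Hz).
#' @param burst_prob Per-cycle presence probability.
#' @param seed Integer seed.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(duration = 30, fs = 250, exponent = 1, tau_d = NA_real_,
                     freq = NA_real_, rel_power = NA_real_, bandwidth = 0,
                     burst_prob = 1, seed = 0L) {
  n <- duration * fs
  if (!isTRUE(all.equal(n, round(n))) || n <= 0) {
    stop_invalid("duration * fs must be a positive integer sample count")
  }
  structure(list(duration = duration, fs = fs, exponent = exponent,
                 tau_d = tau_d, freq = freq, rel_power = rel_power,
                 bandwidth = bandwidth, burst_prob = burst_prob,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Realize a simulation specification as a time series
#'
#' @param spec A [sim_spec()].
#' @return An [aper_ts], deterministic given the spec (including its seed).
#' @export
simulate_spec <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  n <- as.integer(round(spec$duration * spec$fs))
  ap <- if (is.finite(spec$tau_d)) {
    sim_synaptic_knee(n, spec$fs, spec$tau_d, seed = spec$seed)
  } else {
    sim_powerlaw(n, spec$fs, spec$exponent, seed = spec$seed)
  }
  has_osc <- is.finite(spec$freq) && is.finite(spec$rel_power) &&
    spec$rel_power > 0 && spec$burst_prob > 0
  if (!has_osc) return(ap)
  per <- sim_oscillation(n, spec$fs, spec$freq, burst_prob = spec$burst_prob,
                         bandwidth = spec$bandwidth,
                         seed = derive_seed(spec$seed, 1L))
  combine_signals(ap, per, spec$rel_power)
}

sweep_params <- c("exponent", "tau_d", "freq", "rel_power", "bandwidth",
                  "burst_prob")

#' Generate a single-parameter simulation sweep
#'
#' Varies one simulation parameter over a grid, generating `n_per_value`
#' independent realizations per grid value. Seeds are derived from
#' `base$seed` by counter, so any row can be regenerated independently.
#' When a periodic parameter other than `rel_power` is varied and the base
#' spec has no relative power set, it defaults to 1.
#'
#' @param varying One of `"exponent"`, `"tau_d"`, `"freq"`, `"rel_power"`,
#'   `"bandwidth"`, `"burst_prob"`.
#' @param grid Numeric vector of parameter values.
#' @param n_per_value Realizations per grid value (the standard protocol
#'   uses 50).
#' @param base A [sim_spec()] providing all non-varying parameters.
#' @return A tibble with one row per signal: the ground-truth columns
#'   (`exponent`, `tau_d`, `freq`, `rel_power`, `bandwidth`, `burst_prob`),
#'   `varying`, `value`, `seed`, and a `signal` list-column of [aper_ts].
#' @examples
#' sw <- sim_param_sweep("exponent", c(0, 1, 2), n_per_value = 2,
#'                       base = sim_spec(duration = 2, fs = 250, seed = 1))
#' @export
sim_param_sweep <- function(varying, grid, n_per_value,
                            base = sim_spec()) {
  if (!is.character(varying) || length(varying) != 1L ||
      !varying %in% sweep_params) {
    stop_invalid("`varying` must be one of: %s",
                 paste(sweep_params, collapse = ", "))
  }
  stopifnot(inherits(base, "sim_spec"))
  check_scalar_num(n_per_value, "n_per_value", lower = 1)
  if (length(grid) == 0L) {
    return(empty_sweep_tbl())
  }
  df <- tidyr::expand_grid(value = as.numeric(grid),
                           rep = seq_len(n_per_value))
  df$row <- seq_len(nrow(df))
  specs <- purrr::pmap(df, function(value, rep, row) {
    spec <- base
    spec[[varying]] <- value
    if (varying %in% c("freq", "bandwidth", "burst_prob") &&
        !is.finite(spec$rel_power)) {
      spec$rel_power <- 1
    }
    if (varying %in% c("rel_power", "freq", "bandwidth", "burst_prob") &&
        !is.finite(spec$freq)) {
      spec$freq <- 10
    }
    spec$seed <- derive_seed(base$seed, row)
    spec
  })
  tibble::tibble(
    id = seq_len(nrow(df)),
    varying = varying,
    value = df$value,
    exponent = purrr::map_dbl(specs, "exponent"),
    tau_d = purrr::map_dbl(specs, "tau_d"),
    freq = purrr::map_dbl(specs, "freq"),
    rel_power = purrr::map_dbl(specs, "rel_power"),
    bandwidth = purrr::map_dbl(specs, "bandwidth"),
    burst_prob = purrr::map_dbl(specs, "burst_prob"),
    seed = purrr::map_int(specs, "seed"),
    signal = purrr::map(specs, simulate_spec)
  )
}

empty_sweep_tbl <- function() {
  tibble::tibble(id = integer(), varying = character(), value = double(),
                 exponent = double(), tau_d = double(), freq = double(),
                 rel_power = double(), bandwidth = double(),
                 burst_prob = double(), seed = integer(), signal = list())
}

#' Generate the mixed aperiodic/combined comparison set
#'
#' The standard method-comparison protocol: `n_total` signals, a fraction
#' `frac_aperiodic` of them purely aperiodic with exponents drawn uniformly
#' from \{0, 0.1, ..., 2.5\}, the remainder combined signals drawing the
#' aperiodic component the same way plus a continuous sinusoid with center
#' frequency uniform over \{5, 6, ..., 35\} Hz and relative power uniform
#' over \{0.1, 0.2, ..., 1.0\}.
#'
#' @param n_total Number of signals (> 0); the full protocol uses 1000.
#' @param frac_aperiodic Fraction of aperiodic-only signals (default 0.3).
#' @param seed Master seed; per-signal seeds are derived by counter.
#' @param duration,fs Signal duration (s) and sampling rate (Hz).
#' @return A tibble with columns `id`, `kind` (`"aperiodic"`/`"combined"`),
#'   ground truth (`exponent`, `freq`, `rel_power`), `seed`, and `signal`
#'   (list of [aper_ts]).
#' @examples
#' cs <- sim_comparison_set(10, seed = 1, duration = 2)
#' table(cs$kind)
#' @export
sim_comparison_set <- function(n_total, frac_aperiodic = 0.3, seed = 0L,
                               duration = 30, fs = 250) {
  check_scalar_num(n_total, "n_total", lower = 1)
  check_scalar_num(frac_aperiodic, "frac_aperiodic", lower = 0, upper = 1)
  n_total <- as.integer(n_total)
  n_ap <- as.integer(round(n_total * frac_aperiodic))
  kind <- c(rep("aperiodic", n_ap), rep("combined", n_total - n_ap))
  params <- with_seed(seed, {
    tibble::tibble(
      exponent = sample(seq(0, 2.5, by = 0.1), n_total, replace = TRUE),
      freq = ifelse(kind == "combined",
                    sample(5:35, n_total, replace = TRUE), NA_real_),
      rel_power = ifelse(kind == "combined",
                         sample(seq(0.1, 1.0, by = 0.1), n_total,
                                replace = TRUE), NA_real_)
    )
  })
  specs <- purrr::pmap(
    list(params$exponent, params$freq, params$rel_power, seq_len(n_total)),
    function(chi, cf, pw, i) {
      sim_spec(duration = duration, fs = fs, exponent = chi, freq = cf,
               rel_power = pw, seed = derive_seed(seed, i))
    })
  tibble::tibble(
    id = seq_len(n_total),
    kind = kind,
    exponent = params$exponent,
    freq = params$freq,
    rel_power = params$rel_power,
    seed = purrr::map_int(specs, "seed"),
    signal = purrr::map(specs, simulate_spec)
  )
}
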