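# Named measure registry: each entry computes one scalar measure from an
# aper_ts, returning value + censored flag + the settings used.

measure_registry <- function() {
  list(
    ac_decay = function(ts) {
      max_lag <- min(1500, n_samples(ts) - 2L)   # clamp for short signals
      v <- ts_ac_decay_time(ts, max_lag = max_lag)
      list(value = as.numeric(v), censored = isTRUE(attr(v, "censored")),
           settings = list(max_lag = max_lag, lag_step = 2, level = 0.5))
    },
    dfa = function(ts) {
      list(value = ts_dfa(ts), censored = FALSE,
           settings = list(n_scales = 10, min_scale = 0.1, max_scale = 2.0,
                           order = 1))
    },
    hurst = function(ts) {
      list(value = ts_hurst(ts), censored = FALSE,
           settings = list(n_scales = 10, min_scale = 0.1, max_scale = 2.0))
    },
    higuchi = function(ts) {
      list(value = ts_fractal_dim(ts, "higuchi", kmax = 10),
           censored = FALSE, settings = list(kmax = 10))
    },
    katz = function(ts) {
      list(value = ts_fractal_dim(ts, "katz"), censored = FALSE,
           settings = list())
    },
    petrosian = function(ts) {
      list(value = ts_fractal_dim(ts, "petrosian"), censored = FALSE,
           settings = list())
    },
    hjorth_activity = function(ts) {
      list(value = unname(ts_hjorth(ts)["activity"]), censored = FALSE,
           settings = list())
    },
    hjorth_mobility = function(ts) {
      list(value = unname(ts_hjorth(ts)["mobility"]), censored = FALSE,
           settings = list())
    },
    hjorth_complexity = function(ts) {
      list(value = unname(ts_hjorth(ts)["complexity"]), censored = FALSE,
           settings = list())
    },
    lempel_ziv = function(ts) {
      list(value = ts_lempel_ziv(ts, normalize = FALSE), censored = FALSE,
           settings = list(normalize = FALSE))
    },
    sample_entropy = function(ts) {
      v <- ts_regularity_entropy(ts, "sample", order = 2, r_frac = 0.2)
      list(value = as.numeric(v), censored = isTRUE(attr(v, "censored")),
           settings = list(order = 2, r_frac = 0.2))
    },
    approx_entropy = function(ts) {
      v <- ts_regularity_entropy(ts, "approximate", order = 2, r_frac = 0.2)
      list(value = as.numeric(v), censored = FALSE,
           settings = list(order = 2, r_frac = 0.2))
    },
    perm_entropy = function(ts) {
      list(value = ts_permutation_entropy(ts, order = 3, delay = 1),
           censored = FALSE, settings = list(order = 3, delay = 1))
    },
    wperm_entropy = function(ts) {
      list(value = ts_permutation_entropy(ts, order = 3, delay = 1,
                                          weighted = TRUE),
           censored = FALSE,
           settings = list(order = 3, delay = 1, weighted = TRUE))
    },
    spectral_entropy = function(ts) {
      list(value = spectral_entropy(compute_psd(ts)), censored = FALSE,
           settings = list(seg_len = 2, overlap = 0.5))
    },
    spectral_exponent = function(ts) {
      m <- specparam(compute_psd(ts), frange = c(1, min(50, ts$fs / 2 - 1)))
      list(value = unname(m$aperiodic["exponent"]),
           censored = !m$success,
           settings = list(method = "specparam", mode = "fixed",
                           frange = c(1, min(50, ts$fs / 2 - 1))))
    }
  )
}

#' Names of the available scalar measures
#'
#' @return Character vector of measure names accepted by
#'   [compute_measures()] and [run_sweep()].
#' @export
measure_names <- function() names(measure_registry())

#' The featured measure set
#'
#' The prioritized subset used throughout the method comparisons: one or two
#' representatives per measure family (autocorrelation decay, DFA, Hurst,
#' Higuchi and Katz fractal dimensions, Hjorth complexity, Lempel-Ziv,
#' sample entropy, permutation entropy) plus the spectrally fitted aperiodic
#' exponent.
#'
#' @return Character vector of measure names.
#' @export
featured_measures <- function() {
  c("ac_decay", "dfa", "hurst", "higuchi", "katz", "hjorth_complexity",
    "lempel_ziv", "sample_entropy", "perm_entropy", "spectral_exponent")
}

#' Compute a battery of measures on one signal
#'
#' @param ts An [aper_ts] (or numeric vector with `fs`).
#' @param measures Character vector of measure names (see
#'   [measure_names()]).
#' @param fs Sampling rate when `ts` is a bare vector.
#' @return A tibble with one row per measure: `name`, `value`, `censored`,
#'   `settings` (JSON string of the settings used). A measure that fails on
#'   a degenerate input is reported with `value = NA` and `censored = TRUE`,
#'   never dropped.
#' @examples
#' compute_measures(sim_powerlaw(2000, 250, 1, seed = 1),
#'                  measures = c("dfa", "higuchi"))
#' @export
compute_measures <- function(ts, measures = featured_measures(), fs = NULL) {
  ts <- as_aper_ts(ts, fs)
  reg <- measure_registry()
  if (length(measures) == 0L) stop_invalid("`measures` must be nonempty")
  unknown <- setdiff(measures, names(reg))
  if (length(unknown)) {
    stop_invalid("unknown measure(s): %s", paste(unknown, collapse = ", "))
  }
  rows <- purrr::map(measures, function(nm) {
    res <- tryCatch(reg[[nm]](ts), aperiodica_degenerate_input = function(e) {
      list(value = NA_real_, censored = TRUE, settings = list())
    })
    tibble::tibble(name = nm, value = res$value, censored = res$censored,
                   settings = as.character(
                     jsonlite::toJSON(res$settings, auto_unbox = TRUE)))
  })
  dplyr::bind_rows(rows)
}
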