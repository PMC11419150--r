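# Internal validation and numeric helpers.

stop_invalid <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "aperiodica_invalid_argument")
}

stop_degenerate <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "aperiodica_degenerate_input")
}

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("`%s` must be a single finite number", name)
  }
  if (strict_lower && x <= lower) {
    stop_invalid("`%s` must be > %s (got %s)", name, lower, x)
  }
  if (x < lower || x > upper) {
    stop_invalid("`%s` must be in [%s, %s] (got %s)", name, lower, upper, x)
  }
  invisible(x)
}

# Scale to zero mean, unit variance. Constant inputs are a degenerate case
# for every downstream measure, so they error here rather than dividing by 0.
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    stop_degenerate("cannot normalize a constant (zero-variance) signal")
  }
  (x - mean(x)) / s
}

# Derive a per-item 32-bit seed from a master seed by counter, so any subset
# of a batch can be regenerated without generating the whole batch.
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) %% 2147483647 + 7919 * as.numeric(counter)) %%
               2147483647)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

log_spaced_scales <- function(min_scale, max_scale, n_scales, fs) {
  scales <- exp(seq(log(min_scale), log(max_scale), length.out = n_scales))
  win <- unique(pmax(4L, as.integer(round(scales * fs))))
  win
}

ols_slope <- function(x, y) {
  fit <- lm.fit(cbind(1, x), y)
  unname(fit$coefficients[2L])
}
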