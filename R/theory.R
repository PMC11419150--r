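#' Analytic expected values of measures on colored noise
#'
#' Encodes the known analytic relationships between the aperiodic exponent
#' chi of a colored-noise signal and the values of fluctuation / fractal
#' measures:
#' * DFA alpha: under the `standard` convention `alpha = (chi + 1) / 2`
#'   (white noise 0.5, brown noise 1.5). The `printed` convention is the
#'   literal form `alpha = (-chi + 1) / 2` that circulates in parts of the
#'   literature written for the slope b = -chi; with chi defined positive
#'   the two conventions agree only at chi = 0, and simulation matches the
#'   `standard` form (see the methods vignette).
#' * Fractal dimension from alpha: `FD = 3 - alpha`.
#' * Fractal dimension from chi: `D = (5 - chi) / 2`, derived in the
#'   fractional-Brownian-motion regime and therefore restricted to
#'   chi in \[1, 3\].
#'
#' @param measure `"dfa_alpha"` or `"fractal_dimension"`.
#' @param exponent Aperiodic exponent chi.
#' @param convention `"standard"` (sign-corrected; default) or `"printed"`
#'   (literal literature form). Only affects `dfa_alpha`.
#' @return Expected measure value (double).
#' @examples
#' expected_measure("dfa_alpha", 0)              # 0.5 either convention
#' expected_measure("fractal_dimension", 1)      # 2.0
#' @export
expected_measure <- function(measure = c("dfa_alpha", "fractal_dimension"),
                             exponent,
                             convention = c("standard", "printed")) {
  measure <- match.arg(measure)
  convention <- match.arg(convention)
  check_scalar_num(exponent, "exponent")
  if (measure == "dfa_alpha") {
    if (exponent < 0 || exponent > 3) {
      rlang::abort(sprintf(
        "dfa_alpha relation is defined for chi in [0, 3]; got %g", exponent),
        class = "aperiodica_out_of_range")
    }
    if (convention == "standard") (exponent + 1) / 2 else (-exponent + 1) / 2
  } else {
    if (exponent < 1 || exponent > 3) {
      rlang::abort(sprintf(
        "fractal dimension relation D = (5 - chi)/2 is defined for chi in [1, 3]; got %g",
        exponent), class = "aperiodica_out_of_range")
    }
    (5 - exponent) / 2
  }
}

#' Fractal dimension implied by a DFA alpha value
#'
#' The relation `FD = 3 - alpha`, valid for alpha in \[0.5, 2\] (composition
#' with `alpha = (chi + 1) / 2` under the standard convention reproduces
#' `D = (5 - chi) / 2`).
#'
#' @param alpha DFA exponent.
#' @return Expected fractal dimension (double).
#' @export
fd_from_alpha <- function(alpha) {
  check_scalar_num(alpha, "alpha")
  3 - alpha
}
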