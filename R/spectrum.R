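#' Construct a power spectrum
#'
#' Frequency/power pairs on a linear power scale; the universal input of the
#' frequency-domain measures. Stored as a tibble with columns `freq` (Hz) and
#' `power` (a.u.), carrying class `aper_psd`.
#'
#' @param freq Strictly increasing frequencies (Hz).
#' @param power Spectral power values (a.u., linear scale), same length as
#'   `freq`, all positive where log-fitting applies.
#' @return A tibble of class `aper_psd` with columns `freq`, `power`.
#' @export
aper_psd <- function(freq, power) {
  if (length(freq) != length(power)) {
    stop_invalid("`freq` and `power` must have equal length")
  }
  if (length(freq) < 2L) stop_invalid("a spectrum needs at least 2 bins")
  if (any(!is.finite(freq)) || any(!is.finite(power))) {
    stop_invalid("frequencies and powers must be finite")
  }
  if (any(diff(freq) <= 0)) stop_invalid("`freq` must be strictly increasing")
  out <- tibble::tibble(freq = as.numeric(freq), power = as.numeric(power))
  class(out) <- c("aper_psd", class(out))
  out
}

trim_psd <- function(ps, frange) {
  keep <- ps$freq >= frange[1L] & ps$freq <= frange[2L]
  ps[keep, , drop = FALSE]
}

#' @export
autoplot.aper_psd <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$freq, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Power (a.u.)")
}

#' Read and write two-column spectrum files
#'
#' Plain text, two whitespace- or comma-separated columns: frequency (Hz) and
#' linear power. A header line is detected and skipped.
#'
#' @param path File path.
#' @return `read_spectrum()` returns an `aper_psd`; `write_spectrum()`
#'   returns `path` invisibly.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_invalid("empty spectrum file: %s", path)
  first <- strsplit(trimws(lines[1L]), "[,\\s]+", perl = TRUE)[[1L]]
  if (anyNA(suppressWarnings(as.numeric(first)))) lines <- lines[-1L]
  parts <- strsplit(trimws(lines), "[,\\s]+", perl = TRUE)
  ok <- lengths(parts) >= 2L
  if (!all(ok)) {
    rlang::abort(sprintf("malformed spectrum line %d in %s", which(!ok)[1L], path),
                 class = "aperiodica_parse_error")
  }
  freq <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  power <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(freq) || anyNA(power)) {
    bad <- which(is.na(freq) | is.na(power))[1L]
    rlang::abort(sprintf("non-numeric spectrum value at line %d of %s", bad, path),
                 class = "aperiodica_parse_error")
  }
  aper_psd(freq, power)
}

#' @rdname read_spectrum
#' @param ps An `aper_psd` to write.
#' @export
write_spectrum <- function(ps, path) {
  writeLines(c("freq power",
               paste(formatC(ps$freq, format = "g", digits = 17),
                     formatC(ps$power, format = "g", digits = 17))), path)
  invisible(path)
}
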