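#' Construct a uniformly sampled single-channel time series
#'
#' The basic container for simulated or loaded signals: a numeric vector of
#' samples together with its sampling rate. All time-domain measures take an
#' `aper_ts` (or, interchangeably, a plain numeric vector plus `fs`).
#'
#' @param samples Numeric vector of signal values (arbitrary units). All
#'   values must be finite and there must be at least two of them.
#' @param fs Sampling rate in Hz (> 0).
#'
#' @return An object of class `aper_ts`: a list with elements `samples` and
#'   `fs`.
#' @examples
#' x <- aper_ts(sin(2 * pi * 10 * seq(0, 1, by = 1 / 250)), fs = 250)
#' n_samples(x)
#' @export
aper_ts <- function(samples, fs) {
  if (!is.numeric(samples) || length(samples) < 2L) {
    stop_invalid("`samples` must be a numeric vector of length >= 2")
  }
  if (!all(is.finite(samples))) {
    stop_invalid("`samples` must be finite (found NA/NaN/Inf)")
  }
  check_scalar_num(fs, "fs", lower = 0, strict_lower = TRUE)
  structure(list(samples = as.numeric(samples), fs = as.numeric(fs)),
            class = "aper_ts")
}

#' Coerce to a time series
#'
#' @param x An `aper_ts`, or a numeric vector (then `fs` is required).
#' @param fs Sampling rate in Hz, used when `x` is a bare numeric vector.
#' @return An `aper_ts`.
#' @export
as_aper_ts <- function(x, fs = NULL) {
  if (inherits(x, "aper_ts")) return(x)
  if (is.numeric(x)) {
    if (is.null(fs)) stop_invalid("`fs` is required for a bare numeric vector")
    return(aper_ts(x, fs))
  }
  stop_invalid("cannot coerce object of class <%s> to aper_ts",
               paste(class(x), collapse = "/"))
}

#' @rdname aper_ts
#' @param x An `aper_ts`.
#' @export
n_samples <- function(x) length(x$samples)

#' @export
print.aper_ts <- function(x, ...) {
  cat(sprintf("<aper_ts> %d samples @ %g Hz (%.3g s)\n",
              n_samples(x), x$fs, n_samples(x) / x$fs))
  invisible(x)
}

#' @export
as.data.frame.aper_ts <- function(x, ...) {
  data.frame(time = seq_along(x$samples) / x$fs - 1 / x$fs, value = x$samples)
}

#' @export
autoplot.aper_ts <- function(object, ...) {
  df <- as.data.frame(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "Amplitude (a.u.)")
}

#' Read and write delimited time-series files
#'
#' The on-disk format is plain text: a header line `fs=<Hz>` followed by one
#' sample per line.
#'
#' @param path File path.
#' @param fs_override Optional sampling rate (Hz) used when the file lacks an
#'   `fs=` header (or to override it).
#' @return `read_timeseries()` returns an `aper_ts`; `write_timeseries()`
#'   returns `path` invisibly.
#' @export
read_timeseries <- function(path, fs_override = NULL) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_invalid("empty time-series file: %s", path)
  fs <- fs_override
  if (grepl("^\\s*fs\\s*=", lines[1L])) {
    fs_file <- suppressWarnings(as.numeric(sub("^\\s*fs\\s*=", "", lines[1L])))
    if (!is.finite(fs_file)) stop_invalid("unparseable fs header: %s", lines[1L])
    if (is.null(fs)) fs <- fs_file
    lines <- lines[-1L]
  }
  if (is.null(fs)) {
    rlang::abort(sprintf("no `fs=` header in %s and no fs_override given", path),
                 class = "aperiodica_missing_metadata")
  }
  samples <- suppressWarnings(as.numeric(lines))
  if (anyNA(samples)) {
    bad <- which(is.na(samples))[1L]
    rlang::abort(sprintf("non-numeric sample at line %d of %s", bad, path),
                 class = "aperiodica_parse_error")
  }
  aper_ts(samples, fs)
}

#' @rdname read_timeseries
#' @param ts An `aper_ts` to write.
#' @export
write_timeseries <- function(ts, path) {
  ts <- as_aper_ts(ts)
  writeLines(c(sprintf("fs=%.10g", ts$fs),
               formatC(ts$samples, format = "g", digits = 17)), path)
  invisible(path)
}
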