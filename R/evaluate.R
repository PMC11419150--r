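#' Run a measure battery over a simulation set
#'
#' Applies the named measures to every signal of a simulation tibble (from
#' [sim_param_sweep()] or [sim_comparison_set()]), returning the
#' ground-truth columns plus one column per measure. Failures and censored
#' values are flagged in the `censored` list-column, never dropped silently.
#'
#' @param signals A tibble with a `signal` list-column of [aper_ts] (plus
#'   any ground-truth columns, which are carried through).
#' @param measures Character vector of measure names (see
#'   [measure_names()]).
#' @param progress Print a dot every 25 signals? Default `FALSE`.
#' @return A `sweep_table` tibble: the input minus `signal`, plus one
#'   numeric column per measure and a `censored` list-column of character
#'   vectors naming each row's censored measures.
#' @export
run_sweep <- function(signals, measures = featured_measures(),
                      progress = FALSE) {
  if (!is.data.frame(signals) || !"signal" %in% names(signals) ||
      nrow(signals) == 0L) {
    stop_invalid("`signals` must be a nonempty tibble with a `signal` column")
  }
  if (length(measures) == 0L) stop_invalid("`measures` must be nonempty")
  res <- purrr::imap(signals$signal, function(ts, i) {
    if (progress && i %% 25L == 0L) cat(".")
    compute_measures(ts, measures)
  })
  if (progress) cat("\n")
  vals <- purrr::map(res, function(m) setNames(as.list(m$value), m$name))
  out <- dplyr::bind_cols(
    signals[setdiff(names(signals), "signal")],
    dplyr::bind_rows(purrr::map(vals, tibble::as_tibble))
  )
  out$censored <- purrr::map(res, function(m) m$name[m$censored])
  class(out) <- c("sweep_table", class(out))
  out
}

#' Error statistics for an estimator against ground truth
#'
#' Errors are `estimate - truth`. When a reference error distribution is
#' supplied, the absolute errors of the two estimators are compared with a
#' two-sample Welch t-test and Cohen's d.
#'
#' @param estimates,truth Equal-length numeric vectors (n >= 2).
#' @param reference_errors Optional numeric vector of a reference method's
#'   errors (not absolute; taken absolute internally).
#' @return A one-row tibble: `n`, `mean_error`, `sd_error`,
#'   `mean_abs_error`, and (when a reference is given) `t`, `p`, `cohens_d`
#'   comparing absolute errors. Zero-variance comparisons are flagged
#'   (`degenerate = TRUE`) with `cohens_d` an infinite-effect sentinel when
#'   means differ.
#' @export
error_stats <- function(estimates, truth, reference_errors = NULL) {
  if (length(estimates) != length(truth)) {
    stop_invalid("`estimates` and `truth` lengths differ")
  }
  if (length(estimates) < 2L) stop_invalid("need at least 2 observations")
  err <- estimates - truth
  out <- tibble::tibble(n = length(err), mean_error = mean(err),
                        sd_error = sd(err), mean_abs_error = mean(abs(err)))
  if (!is.null(reference_errors)) {
    a <- abs(err)
    b <- abs(reference_errors)
    sp <- sqrt((var(a) * (length(a) - 1) + var(b) * (length(b) - 1)) /
                 (length(a) + length(b) - 2))
    if (sp == 0) {
      d <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
      out$t <- NA_real_
      out$p <- NA_real_
      out$cohens_d <- d
      out$degenerate <- TRUE
    } else {
      tt <- t.test(a, b)
      out$t <- unname(tt$statistic)
      out$p <- tt$p.value
      out$cohens_d <- (mean(a) - mean(b)) / sp
      out$degenerate <- FALSE
    }
  }
  out
}

#' Pairwise Spearman correlation matrix over a sweep table
#'
#' Correlates every pair of measure columns with Spearman's rank
#' correlation, excluding non-finite values pairwise. Entries with a
#' constant column are flagged (`r = NA`, `flag = "constant"`).
#'
#' @param table A `sweep_table` (or any data frame).
#' @param columns Character vector of column names to correlate.
#' @return A `corr_matrix`: a tibble with one row per ordered pair
#'   (`measure1`, `measure2`, `r`, `n`, `flag`); the square matrix is
#'   available via [as.matrix()].
#' @export
spearman_matrix <- function(table, columns = NULL) {
  if (is.null(columns)) {
    columns <- intersect(measure_names(), names(table))
  }
  missing_cols <- setdiff(columns, names(table))
  if (length(missing_cols)) {
    stop_invalid("columns not in table: %s", paste(missing_cols, collapse = ", "))
  }
  pairs <- tidyr::expand_grid(measure1 = columns, measure2 = columns)
  res <- purrr::pmap(pairs, function(measure1, measure2) {
    x <- table[[measure1]]
    y <- table[[measure2]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < 3L) {
      return(tibble::tibble(r = NA_real_, n = n, flag = "too_few"))
    }
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      return(tibble::tibble(r = NA_real_, n = n, flag = "constant"))
    }
    tibble::tibble(r = cor(x[ok], y[ok], method = "spearman"), n = n,
                   flag = NA_character_)
  })
  out <- dplyr::bind_cols(pairs, dplyr::bind_rows(res))
  class(out) <- c("corr_matrix", class(out))
  out
}

#' @export
as.matrix.corr_matrix <- function(x, ...) {
  cols <- unique(x$measure1)
  m <- matrix(NA_real_, length(cols), length(cols),
              dimnames = list(cols, cols))
  for (i in seq_len(nrow(x))) {
    m[x$measure1[i], x$measure2[i]] <- x$r[i]
  }
  m
}

#' @export
autoplot.corr_matrix <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$measure1,
                                       y = .data$measure2,
                                       fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 2.5) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Bootstrap confidence interval for a Spearman correlation
#'
#' Paired case resampling: rows of `(x, y)` are resampled with replacement
#' `n_resamples` times; the CI is the percentile interval of the resampled
#' correlations and the p-value is the two-sided empirical probability of
#' the resampled distribution crossing zero.
#'
#' @param x,y Numeric vectors (n >= 10).
#' @param n_resamples Number of bootstrap resamples (default 5000).
#' @param ci Confidence level in percent (default 95).
#' @param seed Optional seed for reproducibility.
#' @return A one-row tibble: `r`, `ci_lo`, `ci_hi`, `p`, `n`,
#'   `n_resamples`.
#' @export
bootstrap_corr <- function(x, y, n_resamples = 5000, ci = 95, seed = NULL) {
  if (length(x) != length(y)) stop_invalid("`x` and `y` lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10L) stop_invalid("need n >= 10 for the bootstrap (got %d)", n)
  r <- cor(x, y, method = "spearman")
  boots <- with_seed(seed, vapply(seq_len(n_resamples), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    suppressWarnings(cor(x[idx], y[idx], method = "spearman"))
  }, 1.0))
  boots <- boots[is.finite(boots)]
  alpha <- (100 - ci) / 200
  qs <- quantile(boots, c(alpha, 1 - alpha), names = FALSE)
  p <- 2 * min(mean(boots <= 0), mean(boots >= 0))
  tibble::tibble(r = r, ci_lo = qs[1L], ci_hi = qs[2L], p = min(p, 1),
                 n = n, n_resamples = n_resamples)
}

#' Bootstrap test for a difference between two correlations
#'
#' Resamples cases jointly and computes the distribution of
#' `cor(x, y1) - cor(x, y2)` (Spearman); the p-value is the two-sided
#' empirical probability that the difference distribution crosses zero.
#'
#' @param x,y1,y2 Aligned numeric vectors.
#' @inheritParams bootstrap_corr
#' @return A one-row tibble: `r1`, `r2`, `diff`, `ci_lo`, `ci_hi`, `p`.
#' @export
bootstrap_corr_diff <- function(x, y1, y2, n_resamples = 5000, ci = 95,
                                seed = NULL) {
  if (length(x) != length(y1) || length(x) != length(y2)) {
    stop_invalid("`x`, `y1`, `y2` lengths differ")
  }
  ok <- is.finite(x) & is.finite(y1) & is.finite(y2)
  x <- x[ok]; y1 <- y1[ok]; y2 <- y2[ok]
  n <- length(x)
  if (n < 10L) stop_invalid("need n >= 10 for the bootstrap (got %d)", n)
  diffs <- with_seed(seed, vapply(seq_len(n_resamples), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    suppressWarnings(cor(x[idx], y1[idx], method = "spearman") -
                       cor(x[idx], y2[idx], method = "spearman"))
  }, 1.0))
  diffs <- diffs[is.finite(diffs)]
  alpha <- (100 - ci) / 200
  qs <- quantile(diffs, c(alpha, 1 - alpha), names = FALSE)
  p <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
  tibble::tibble(r1 = cor(x, y1, method = "spearman"),
                 r2 = cor(x, y2, method = "spearman"),
                 diff = cor(x, y1, method = "spearman") -
                   cor(x, y2, method = "spearman"),
                 ci_lo = qs[1L], ci_hi = qs[2L], p = min(p, 1))
}

#' Semi-partial correlation
#'
#' Spearman correlation between `target` and the residual of `measure`
#' after linearly regressing out `control` (from the measure only).
#'
#' @param target,measure,control Aligned numeric vectors (n >= 4).
#' @return A one-row tibble: `r`, `full_r` (unadjusted correlation), `n`,
#'   `flag` (`NA`, `"constant_control"`, or `"degenerate_residual"`; in the
#'   degenerate case `r` is a 0 sentinel).
#' @export
semipartial_corr <- function(target, measure, control) {
  if (length(target) != length(measure) ||
      length(target) != length(control)) {
    stop_invalid("input lengths differ")
  }
  ok <- is.finite(target) & is.finite(measure) & is.finite(control)
  target <- target[ok]; measure <- measure[ok]; control <- control[ok]
  if (length(target) < 4L) stop_invalid("need n >= 4")
  full_r <- cor(target, measure, method = "spearman")
  if (sd(control) == 0) {
    return(tibble::tibble(r = full_r, full_r = full_r, n = length(target),
                          flag = "constant_control"))
  }
  res <- resid(lm(measure ~ control))
  if (sd(res) < 1e-12) {
    return(tibble::tibble(r = 0, full_r = full_r, n = length(target),
                          flag = "degenerate_residual"))
  }
  tibble::tibble(r = cor(target, res, method = "spearman"),
                 full_r = full_r, n = length(target), flag = NA_character_)
}
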