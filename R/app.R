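# Experiment configuration and reproducible end-to-end runs.

#' Experiment configuration
#'
#' A flat, plain-text-serializable configuration for a reproducible
#' experiment run: the experiment name, its scale, a master seed, an output
#' directory, and parameter overrides.
#'
#' @param experiment One of `"comparison"` (mixed aperiodic/combined
#'   comparison set + correlation matrices), `"spectral_fits"` (simulated
#'   spectra + fitting-method error statistics), `"time_sweep"` (exponent
#'   sweep + time-domain measure battery).
#' @param scale `"desk"` (reduced problem sizes) or `"full"` (the complete
#'   protocol sizes).
#' @param seed Master seed (integer).
#' @param out_dir Output directory; created if needed.
#' @param ... Named scalar overrides stored in the config (e.g. `n_total`).
#' @return A list of class `aper_config`.
#' @export
aper_config <- function(experiment = c("comparison", "spectral_fits",
                                       "time_sweep"),
                        scale = c("desk", "full"), seed = 0L,
                        out_dir = tempfile("aper_run_"), ...) {
  experiment <- match.arg(experiment)
  scale <- match.arg(scale)
  extra <- list(...)
  if (length(extra) && is.null(names(extra))) {
    stop_invalid("extra config entries must be named")
  }
  structure(c(list(experiment = experiment, scale = scale,
                   seed = as.integer(seed), out_dir = out_dir), extra),
            class = "aper_config")
}

#' Write / read a configuration as plain text
#'
#' `key = value` lines; round-trips exactly.
#'
#' @param config An [aper_config()].
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns an `aper_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "aper_config"))
  lines <- vapply(names(config), function(k) {
    sprintf("%s = %s", k, as.character(config[[k]]))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- lapply(kv, function(p) {
    v <- p[[2L]]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  cfg <- setNames(vals, trimws(keys))
  cfg$seed <- as.integer(cfg$seed)
  do.call(aper_config, cfg)
}

experiment_sizes <- function(experiment, scale) {
  switch(experiment,
    comparison = list(desk = list(n_total = 250, duration = 30),
                      full = list(n_total = 1000, duration = 30))[[scale]],
    spectral_fits = list(desk = list(n_spectra = 100),
                         full = list(n_spectra = 1000))[[scale]],
    time_sweep = list(desk = list(n_per_value = 5, duration = 10),
                      full = list(n_per_value = 50, duration = 30))[[scale]])
}

#' Run a configured experiment end to end
#'
#' Simulates the experiment's inputs, computes its measures and statistics,
#' and writes delimited text tables to `config$out_dir`, together with the
#' resolved configuration (`config.txt`) so every output is traceable to
#' its seed and parameters. Deterministic given the seed.
#'
#' @param config An [aper_config()].
#' @return (Invisibly) a named list of the written file paths.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "aper_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sizes <- experiment_sizes(config$experiment, config$scale)
  sizes <- modifyList(sizes, config[intersect(names(config), names(sizes))])
  files <- list(config = file.path(config$out_dir, "config.txt"))
  write_config(config, files$config)
  write_tbl <- function(df, name) {
    path <- file.path(config$out_dir, paste0(name, ".tsv"))
    df <- dplyr::mutate(df, dplyr::across(
      dplyr::where(is.list), ~ vapply(.x, paste, "", collapse = ",")))
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    path
  }
  if (config$experiment == "comparison") {
    cs <- sim_comparison_set(sizes$n_total, seed = config$seed,
                             duration = sizes$duration)
    sw <- run_sweep(cs, featured_measures())
    files$sweep <- write_tbl(sw, "sweep")
    cm_ap <- spearman_matrix(dplyr::filter(sw, .data$kind == "aperiodic"),
                             featured_measures())
    cm_cb <- spearman_matrix(dplyr::filter(sw, .data$kind == "combined"),
                             featured_measures())
    files$corr_aperiodic <- write_tbl(cm_ap, "corr_aperiodic")
    files$corr_combined <- write_tbl(cm_cb, "corr_combined")
    cb <- dplyr::filter(sw, .data$kind == "combined")
    pp <- purrr::map_dfr(featured_measures(), function(m) {
      ok <- is.finite(cb[[m]]) & is.finite(cb$rel_power)
      tibble::tibble(measure = m,
                     r = cor(cb[[m]][ok], cb$rel_power[ok],
                             method = "spearman"),
                     n = sum(ok))
    })
    files$peak_power_corr <- write_tbl(pp, "peak_power_corr")
  } else if (config$experiment == "spectral_fits") {
    set <- sim_psd_set(sizes$n_spectra, seed = config$seed)
    ests <- fit_psd_battery(set)
    files$estimates <- write_tbl(ests, "estimates")
    stats <- dplyr::group_by(ests, .data$method)
    stats <- dplyr::group_modify(stats, function(df, key) {
      error_stats(df$exponent_hat, df$exponent)
    })
    files$error_stats <- write_tbl(dplyr::ungroup(stats), "error_stats")
  } else {
    sw_sig <- sim_param_sweep("exponent", seq(0, 3, by = 0.5),
                              sizes$n_per_value,
                              base = sim_spec(duration = sizes$duration,
                                              seed = config$seed))
    sw <- run_sweep(sw_sig, setdiff(featured_measures(), "spectral_exponent"))
    files$sweep <- write_tbl(sw, "sweep")
    med <- dplyr::summarise(
      dplyr::group_by(sw, .data$value),
      dplyr::across(dplyr::where(is.numeric) &
                      !dplyr::any_of(c("id", "seed")), median))
    files$medians <- write_tbl(med, "medians")
  }
  invisible(files)
}

# Apply every direct fitting method (with and without alpha exclusion) plus
# specparam to each spectrum of a simulated-spectrum tibble.
fit_psd_battery <- function(set, frange = c(1, 50),
                            exclusion = c(7, 14)) {
  line_methods <- c("ols", "rlm", "ransac", "exp")
  purrr::map_dfr(seq_len(nrow(set)), function(i) {
    ps <- set$spectrum[[i]]
    base <- set[i, setdiff(names(set), "spectrum")]
    rows <- purrr::map_dfr(line_methods, function(m) {
      dplyr::bind_rows(
        tibble::tibble(method = m,
                       exponent_hat = fit_spectral_line(
                         ps, frange, m)$exponent),
        tibble::tibble(method = paste0(m, "_excl"),
                       exponent_hat = fit_spectral_line(
                         ps, frange, m, exclusion = exclusion)$exponent))
    })
    sp <- specparam(ps, frange)
    rows <- dplyr::bind_rows(
      rows, tibble::tibble(method = "specparam",
                           exponent_hat = unname(sp$aperiodic["exponent"])))
    dplyr::bind_cols(base[rep(1, nrow(rows)), ], rows)
  })
}
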