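#' Write per-step metrics as CSV
#'
#' Plain comma-separated file with the fixed header
#' `t,n_ants,density,v_avg,flow`, dot decimals, no index column.
#'
#' @param x An `atm_run` object or a metrics data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(x, path) {
  m <- if (inherits(x, "atm_run")) x$metrics else x
  stopifnot(all(c("t", "n_ants", "density", "v_avg", "flow") %in% names(m)))
  utils::write.csv(m[, c("t", "n_ants", "density", "v_avg", "flow")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-step metrics CSV
#'
#' @param path File written by [write_metrics_csv()].
#' @return A metrics data.frame.
#' @export
read_metrics_csv <- function(path) {
  m <- utils::read.csv(path)
  stopifnot(all(c("t", "n_ants", "density", "v_avg", "flow") %in% names(m)))
  m
}

#' Write a fundamental diagram as CSV
#'
#' Columns `bin_center, mean_v, mean_flow, count`.
#'
#' @param fd A fundamental diagram from [bin_fundamental_diagram()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fd_csv <- function(fd, path) {
  utils::write.csv(as.data.frame(fd)[, c("bin_center", "mean_v",
                                         "mean_flow", "count")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a parameter-sweep table as CSV
#'
#' @param sweep A sweep data.frame from [sweep_evaporation()] or
#'   [sweep_emission()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(sweep, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run summary as JSON
#'
#' Writes the full parameter echo, seed, config hash, termination reason
#' and step count, so every number in the metrics CSV is regenerable from
#' the summary alone.
#'
#' @param run An `atm_run` object.
#' @param path Output file path.
#' @return The summary list, invisibly.
#' @export
write_run_summary <- function(run, path) {
  p <- run$params
  summary <- list(
    params = p[setdiff(names(p), "seed")],
    seed = if (is.null(p$seed)) NA_integer_ else p$seed,
    config_hash = config_hash(p),
    termination = run$termination,
    truncated = run$truncated,
    steps = run$steps,
    n_ants_final = length(run$final$positions),
    final_density = length(run$final$positions) / p$L
  )
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(summary)
}

#' MD5 hash of a canonical JSON rendering of a configuration
#'
#' @param config A named list (e.g. an [atm_params()] object).
#' @return A length-1 character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config[order(names(config))], tmp,
                       auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Read a flat JSON run configuration
#'
#' A configuration is a single flat JSON object holding any subset of the
#' [atm_params()] fields plus the measurement knobs (`bin_width`,
#' `smooth_window`, `burn_in`, `gap_threshold`, `re_grid`, `tau_grid`).
#' Missing model fields take the [atm_params()] defaults.
#'
#' @param path Path to the JSON file.
#' @return A named list of class `atm_config` with elements `params` (an
#'   `atm_params` object) and `measurement` (the remaining knobs).
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  param_fields <- c("L", "re", "tau", "sigma_sat", "vmin", "a", "P",
                    "inflow", "seed", "max_steps", "deposit")
  pf <- raw[intersect(names(raw), param_fields)]
  params <- do.call(atm_params, pf)
  measurement <- raw[setdiff(names(raw), param_fields)]
  structure(list(params = params, measurement = measurement),
            class = "atm_config")
}

#' Write a flat JSON run configuration
#'
#' Inverse of [read_run_config()]: parameters and measurement knobs are
#' flattened into one JSON object that round-trips losslessly.
#'
#' @param config An `atm_config` object, or a list with `params` and
#'   optionally `measurement`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  p <- config$params
  flat <- c(p[!vapply(p, is.null, logical(1))], config$measurement)
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
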