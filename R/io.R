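#' Write a trajectory to CSV
#'
#' RFC-4180 CSV with header `t, A_b, A_c, A_o, AR, ARR, R, ABC`, UTF-8,
#' '.' decimal separator.  Identical runs (same configuration and
#' seed) produce byte-identical files.
#'
#' @param trajectory An `ssa_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "ssa_trajectory"))
  write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}

#' Write per-cell ensemble results to CSV
#'
#' One row per cell: `cell, seed, R_init, k_bp, AR, ARR, R_free, ABC`.
#'
#' @param ensemble A `mabsim_ensemble`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "mabsim_ensemble"))
  cols <- c("cell", "seed", "R_init", "k_bp", "AR", "ARR", "R_free",
            "ABC")
  write.csv(ensemble$cells[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Write an event log to CSV
#'
#' @param trajectory An `ssa_trajectory` run with
#'   `keep_event_log = TRUE`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_log_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "ssa_trajectory"))
  if (is.null(trajectory$event_log))
    .stop("trajectory has no event log", "mabsim_parameter_error")
  log <- trajectory$event_log
  log$channel <- .channel_names[log$channel]
  write.csv(log, path, row.names = FALSE)
  invisible(path)
}

dist_to_list <- function(d) unclass(d)

list_to_dist <- function(x) {
  switch(x$kind,
    fixed = dist_fixed(x$value),
    normal = dist_normal(x$mean, x$cv_percent),
    two_point = dist_two_point(x$low, x$high, x$p_high),
    log10_normal = dist_log10_normal(x$mean_exponent, x$sd_exponent),
    .stop(paste("unknown distribution kind", x$kind),
          "mabsim_config_error"))
}

#' Write an ensemble summary (with provenance) to JSON
#'
#' The JSON block mirrors the mean/SD/CV% summary table, keyed by
#' population (`R_init`, `AR`, `ARR`, `TotalA`), and records full
#' provenance: every rate constant, the heterogeneity distributions,
#' the per-cell seeds, the master seed and the package version.
#' Numbers are written at full precision so the summary re-reads
#' exactly.
#'
#' @param ensemble A `mabsim_ensemble`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "mabsim_ensemble"))
  s <- ensemble$summary
  summary_block <- lapply(as.list(s), function(col)
    list(mean = col[1], SD = col[2], `CV%` = col[3]))
  payload <- list(
    schema = "mabsim/summary/1",
    package_version = as.character(packageVersion("mabsim")),
    summary = summary_block,
    n_cells = ensemble$spec$n_cells,
    t_end = ensemble$spec$t_end,
    A_s = ensemble$spec$A_s,
    master_seed = ensemble$spec$master_seed,
    base_rates = as.list(unclass(ensemble$spec$base_rates)),
    receptor_dist = dist_to_list(ensemble$spec$receptor_dist),
    kbp_dist = dist_to_list(ensemble$spec$kbp_dist),
    cell_seeds = ensemble$cells$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Re-read a summary JSON
#'
#' @param path File written by [write_summary_json()].
#' @return List with the summary reconstructed as the same data frame
#'   shape produced by [ensemble_summary()], plus the provenance
#'   fields.
#' @export
read_summary_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$schema, "mabsim/summary/1"))
    .stop("not a mabsim summary file", "mabsim_config_error")
  s <- data.frame(row.names = c("mean", "SD", "CV%"))
  for (nm in names(x$summary)) {
    col <- x$summary[[nm]]
    s[[nm]] <- vapply(c("mean", "SD", "CV%"), function(k) {
      v <- col[[k]]
      if (is.null(v) || length(v) != 1L) NA_real_ else as.numeric(v)
    }, numeric(1), USE.NAMES = FALSE)
  }
  x$summary <- s
  x
}

#' Run configuration files
#'
#' A `run_config` captures everything needed to reproduce a run in a
#' small YAML document with a versioned `schema` field: scenario name,
#' binding preset and rate overrides, ensemble settings, recording
#' options, seed and output directory.  [read_run_config()] validates
#' the schema and round-trips losslessly with [write_run_config()].
#'
#' @param scenario `"labeling"`, `"post_labeling"` or `"ensemble"`.
#' @param preset Rate or ensemble preset name (see [preset_rates()],
#'   [preset_ensemble()]).
#' @param seed Integer seed.
#' @param t_end Horizon override (s); NULL keeps the preset default.
#' @param n_cells Ensemble size override.
#' @param R0,A_s Initial condition overrides.
#' @param rate_overrides Named list of explicit rate-constant values.
#' @param keep_event_log Record per-event history?
#' @param out_dir Output directory for [write_outputs()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(scenario = "labeling", preset = "similar",
                       seed = 1, t_end = NULL, n_cells = 25,
                       R0 = 100000, A_s = 3000,
                       rate_overrides = list(),
                       keep_event_log = FALSE, out_dir = ".") {
  if (!scenario %in% c("labeling", "post_labeling", "ensemble"))
    .stop("scenario must be labeling, post_labeling or ensemble",
          "mabsim_config_error")
  structure(list(schema = "mabsim/config/1", scenario = scenario,
                 preset = preset, seed = as.integer(seed),
                 t_end = if (is.null(t_end)) NULL else as.numeric(t_end),
                 n_cells = as.integer(n_cells),
                 R0 = as.numeric(R0), A_s = as.numeric(A_s),
                 rate_overrides = rate_overrides,
                 keep_event_log = isTRUE(keep_event_log),
                 out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!identical(x$schema, "mabsim/config/1"))
    .stop("unsupported or missing config schema", "mabsim_config_error")
  cfg <- run_config(scenario = x$scenario, preset = x$preset,
                    seed = x$seed, t_end = x$t_end,
                    n_cells = if (is.null(x$n_cells)) 25 else x$n_cells,
                    R0 = x$R0, A_s = x$A_s,
                    rate_overrides = if (is.null(x$rate_overrides))
                      list() else x$rate_overrides,
                    keep_event_log = x$keep_event_log,
                    out_dir = x$out_dir)
  cfg
}

config_rates <- function(config) {
  base <- preset_rates(config$preset)
  k <- unclass(base)
  if (length(config$rate_overrides)) {
    ov <- unlist(config$rate_overrides)
    bad <- setdiff(names(ov), .channel_names)
    if (length(bad))
      .stop(paste("unknown rate override:", paste(bad, collapse = ", ")),
            "mabsim_config_error")
    k[names(ov)] <- ov
  }
  validate_rate_constants(k)
}

#' Execute a run configuration and write its outputs
#'
#' Dispatches on the configured scenario, runs it with the configured
#' seed, and writes the output files into `config$out_dir`:
#' trajectory CSV (plus optional event-log CSV) for single runs, or
#' per-cell CSV and summary JSON for ensembles.  A short log of
#' parameters, event counts and wall time is printed via [message()].
#'
#' @param config A [run_config()].
#' @param quiet Suppress log messages?
#' @return Named character vector of the files written, invisibly.
#' @export
write_outputs <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  t0 <- proc.time()[["elapsed"]]
  files <- character(0)
  rates <- config_rates(config)

  if (config$scenario == "ensemble") {
    spec <- preset_ensemble(config$preset, n_cells = config$n_cells,
                            master_seed = config$seed)
    if (!is.null(config$t_end)) spec$t_end <- config$t_end
    say(sprintf("ensemble '%s': %d cells, t_end = %g s, seed %d",
                config$preset, spec$n_cells, spec$t_end, config$seed))
    res <- run_ensemble(spec)
    files["cells"] <- file.path(config$out_dir, "cells.csv")
    write_ensemble_csv(res, files["cells"])
    files["summary"] <- file.path(config$out_dir, "summary.json")
    write_summary_json(res, files["summary"])
  } else {
    t_end <- config$t_end
    if (config$scenario == "labeling") {
      if (is.null(t_end)) t_end <- 30
      sc <- labeling_scenario(R0 = config$R0, A_s = config$A_s,
                              rates = rates, t_end = t_end)
      policy <- recording_policy(seq(0, t_end, length.out = 300),
                                 keep_event_log = config$keep_event_log)
    } else {
      if (is.null(t_end)) t_end <- 3e4
      lab <- run_scenario(labeling_scenario(R0 = config$R0,
                                            A_s = config$A_s,
                                            rates = rates),
                          seed = config$seed)
      sc <- post_labeling_scenario(lab$final_state, rates,
                                   t_end = t_end)
      policy <- recording_policy(log_time_grid(1e-6, t_end),
                                 keep_event_log = config$keep_event_log)
    }
    say(sprintf("%s run: t_end = %g s, seed %d", config$scenario,
                t_end, config$seed))
    traj <- run_scenario(sc, policy = policy, seed = config$seed)
    say(sprintf("  %g events%s", traj$event_count,
                if (traj$truncated) " (TRUNCATED at event cap)" else ""))
    files["trajectory"] <- file.path(config$out_dir, "trajectory.csv")
    write_trajectory_csv(traj, files["trajectory"])
    if (config$keep_event_log) {
      files["events"] <- file.path(config$out_dir, "events.csv")
      write_event_log_csv(traj, files["events"])
    }
  }
  say(sprintf("  wall time %.2f s; outputs in %s",
              proc.time()[["elapsed"]] - t0,
              normalizePath(config$out_dir)))
  invisible(files)
}
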