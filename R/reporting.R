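#' Histogram of inter-event intervals
#'
#' Log-spaced histogram of the waiting times recorded in an event log.
#' The interval distribution is diagnostic of which reaction group is
#' active: fast diffusion/adsorption churn produces microsecond
#' intervals, while late post-labeling dynamics are dominated by slow
#' dissociation with intervals around seconds.
#'
#' @param event_log Data frame with columns `t`, `channel`, `tau`
#'   (from a run with `keep_event_log = TRUE`).
#' @param bins_per_decade Number of logarithmic bins per decade.
#' @param time_window Optional `c(t_min, t_max)`: only events with
#'   `t` inside the window are counted (for early/late comparisons).
#' @param by_channel Also tabulate counts per channel?
#' @return An object of class `interval_histogram`: list with `edges`
#'   (strictly increasing bin edges, s), `counts` (length
#'   `length(edges) - 1`, summing to the number of events used),
#'   `n_events`, and optionally `channel_counts`.
#' @export
interval_histogram <- function(event_log, bins_per_decade = 10,
                               time_window = NULL, by_channel = FALSE) {
  if (is.null(event_log) || !is.data.frame(event_log) ||
      nrow(event_log) == 0L)
    .stop("event log is empty; run with keep_event_log = TRUE",
          "mabsim_parameter_error")
  stopifnot(all(c("t", "channel", "tau") %in% names(event_log)),
            bins_per_decade >= 1)
  ev <- event_log
  if (!is.null(time_window)) {
    stopifnot(length(time_window) == 2L, time_window[1] < time_window[2])
    ev <- ev[ev$t >= time_window[1] & ev$t <= time_window[2], ,
             drop = FALSE]
    if (nrow(ev) == 0L)
      .stop("no events inside the requested time window",
            "mabsim_parameter_error")
  }
  tau <- ev$tau
  lo <- floor(log10(min(tau)) * bins_per_decade) / bins_per_decade
  hi <- ceiling(log10(max(tau)) * bins_per_decade) / bins_per_decade
  if (hi <= lo) hi <- lo + 1 / bins_per_decade
  edges <- 10^seq(lo, hi, by = 1 / bins_per_decade)
  idx <- findInterval(tau, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  out <- list(edges = edges, counts = counts, n_events = nrow(ev),
              time_window = time_window)
  if (by_channel)
    out$channel_counts <- table(factor(ev$channel, levels = 1:10,
                                       labels = .channel_names))
  structure(out, class = "interval_histogram")
}

#' @export
print.interval_histogram <- function(x, ...) {
  cat(sprintf("interval_histogram: %d events in %d log bins over [%.3g, %.3g] s\n",
              x$n_events, length(x$counts), min(x$edges), max(x$edges)))
  mode_bin <- which.max(x$counts)
  cat(sprintf("  modal interval decade: %.3g-%.3g s (%d events)\n",
              x$edges[mode_bin], x$edges[mode_bin + 1],
              x$counts[mode_bin]))
  invisible(x)
}

#' Modal inter-event interval
#'
#' @param hist An [interval_histogram()].
#' @return Geometric midpoint (s) of the most populated bin.
#' @export
modal_interval <- function(hist) {
  stopifnot(inherits(hist, "interval_histogram"))
  i <- which.max(hist$counts)
  sqrt(hist$edges[i] * hist$edges[i + 1])
}

#' Detect when a trajectory reaches its plateau
#'
#' Returns the earliest snapshot time from which every named field
#' stays within `rel_tol` of its settled value throughout the
#' following observation window of `window` seconds.  The settled
#' value of a field is the mean of its trailing window of snapshots --
#' a robust plateau estimate; a single stochastic end-point would
#' off-centre the tolerance band.  Returns `NA` if no such time
#' exists.
#'
#' @param trajectory An `ssa_trajectory`, or a data frame with a `t`
#'   column and the named fields.
#' @param fields Character vector of population names to test.
#' @param window Minimum observed span after the detected time (s).
#' @param rel_tol Relative tolerance around the final value.
#' @return Time of equilibration (s), or `NA_real_`.
#' @export
#' @examples
#' tr <- data.frame(t = 0:10, x = c(5, 3, 2, rep(1, 8)))
#' detect_equilibrium(tr, "x", window = 3, rel_tol = 0.05)  # 3
detect_equilibrium <- function(trajectory, fields = c("A_b", "A_c"),
                               window = 5, rel_tol = 0.05) {
  df <- if (inherits(trajectory, "ssa_trajectory"))
    as.data.frame(trajectory) else trajectory
  stopifnot(is.data.frame(df), "t" %in% names(df),
            all(fields %in% names(df)), nrow(df) >= 2L,
            window >= 0, rel_tol > 0)
  times <- df$t
  if (max(times) - min(times) < window)
    .stop("trajectory shorter than the observation window",
          "mabsim_parameter_error")
  ok <- rep(TRUE, nrow(df))
  tail_win <- times >= max(times) - window
  for (f in fields) {
    v <- df[[f]]
    fin <- mean(v[tail_win])
    band <- rel_tol * abs(fin)
    ok <- ok & (abs(v - fin) <= band)
  }
  # earliest i whose full observation window [t_i, t_i + window] stays
  # inside the band for every field
  for (i in which(times <= max(times) - window)) {
    in_win <- times >= times[i] & times <= times[i] + window
    if (all(ok[in_win])) return(times[i])
  }
  NA_real_
}
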