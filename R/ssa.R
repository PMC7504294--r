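#' Waiting time to the next reaction
#'
#' In the direct method the time to the next event is exponential with
#' rate equal to the total propensity: `tau = ln(1/u1) / total`, with
#' `u1` uniform on (0, 1].
#'
#' @param total_propensity Sum of all channel propensities (1/s);
#'   must be positive (a zero total means the state is absorbing).
#' @param u1 Uniform variate(s) in (0, 1].
#' @return Waiting time(s) in seconds.
#' @export
#' @examples
#' sample_waiting_time(2, exp(-1))  # 0.5 s
sample_waiting_time <- function(total_propensity, u1) {
  if (!is.numeric(total_propensity) || length(total_propensity) != 1L ||
      !is.finite(total_propensity) || total_propensity <= 0)
    .stop("total propensity is not positive: absorbing state",
          "mabsim_absorbing")
  if (any(u1 <= 0) || any(u1 > 1))
    .stop("u1 must lie in (0, 1]; the engine resamples exact zeros",
          "mabsim_parameter_error")
  -log(u1) / total_propensity
}

#' Select the reacting channel
#'
#' Partitions (0, 1) into segments of length `alpha_j / sum(alpha)` and
#' returns the index of the segment containing `u2`: the smallest `j`
#' whose cumulative propensity exceeds `u2 * sum(alpha)`.  Channels
#' with zero propensity occupy zero-length segments and are never
#' selected.
#'
#' @param alpha Propensity vector (non-negative, at least one positive).
#' @param u2 Uniform variate(s) in \[0, 1).
#' @return Integer index (1-based) into `alpha`; vectorised over `u2`.
#' @export
#' @examples
#' select_channel(c(1, 1, 0), 0.25)  # 1
#' select_channel(c(1, 1, 0), 0.75)  # 2
select_channel <- function(alpha, u2) {
  if (any(alpha < 0) || !any(alpha > 0))
    .stop("propensities all zero: absorbing state", "mabsim_absorbing")
  if (any(u2 < 0) || any(u2 >= 1))
    .stop("u2 must lie in [0, 1)", "mabsim_parameter_error")
  cum <- cumsum(alpha)
  # smallest j with cum[j] > u2 * total  ==  #\{cum <= target\} + 1
  j <- findInterval(u2 * cum[length(cum)], cum) + 1L
  # rounding guard: never fire a zero-propensity channel
  bad <- j > length(alpha) | alpha[pmin(j, length(alpha))] == 0
  if (any(bad)) j[bad] <- max(which(alpha > 0))
  j
}

#' Trajectory recording policy
#'
#' @param snapshot_times Monotone increasing grid of times (s) at which
#'   the state is recorded.  The state recorded at a grid point is the
#'   one in force at that instant (last state before the next event).
#' @param keep_event_log Record every `(t, channel, tau)` event?  Off by
#'   default: a full-scale labeling run generates millions of events.
#' @param max_events Safety cap on the number of events; reaching it
#'   truncates the run with a warning flag on the trajectory.
#' @return An object of class `recording_policy`.
#' @export
recording_policy <- function(snapshot_times, keep_event_log = FALSE,
                             max_events = 1e8) {
  if (!is.numeric(snapshot_times) || length(snapshot_times) < 1L ||
      is.unsorted(snapshot_times, strictly = TRUE))
    .stop("snapshot_times must be a strictly increasing numeric grid",
          "mabsim_parameter_error")
  if (!is.numeric(max_events) || length(max_events) != 1L || max_events < 1)
    .stop("max_events must be >= 1", "mabsim_parameter_error")
  structure(list(snapshot_times = as.numeric(snapshot_times),
                 keep_event_log = isTRUE(keep_event_log),
                 max_events = max_events),
            class = "recording_policy")
}

#' Logarithmic snapshot grid
#'
#' Convenience grid for runs whose dynamics span many decades, such as
#' the post-labeling wash (event intervals range from microseconds to
#' seconds over a 3e4 s horizon).
#'
#' @param t_min,t_end Grid limits (s), `0 < t_min < t_end`.
#' @param n Number of points.
#' @return Numeric vector of log-spaced times.
#' @export
log_time_grid <- function(t_min = 1e-6, t_end, n = 300) {
  stopifnot(t_min > 0, t_end > t_min, n >= 2)
  exp(seq(log(t_min), log(t_end), length.out = n))
}

default_policy <- function(t0, t_end, n = 300) {
  recording_policy(seq(t0, t_end, length.out = n))
}

#' One direct-method step (reference implementation)
#'
#' Computes all propensities, samples the waiting time and the channel
#' from the supplied uniforms (drawn from R's RNG when omitted), and
#' applies the reaction.  This is the transparent single-step form of
#' the loop that [ssa_run()] executes in compiled code.
#'
#' @param state A [system_state()].
#' @param channels Channel list from [build_channels()].
#' @param u1,u2 Optional uniform variates (for deterministic testing).
#' @return List with elements `state` (the updated [system_state()],
#'   time advanced by `tau`) and `event` (a one-row data frame with
#'   `t`, `channel`, `tau`).
#' @export
ssa_step <- function(state, channels, u1 = NULL, u2 = NULL) {
  alpha <- propensities(state, channels)
  total <- sum(alpha)
  if (total <= 0)
    .stop("propensities all zero: absorbing state", "mabsim_absorbing")
  if (is.null(u1)) {
    u1 <- runif(1)
    while (u1 <= 0) u1 <- runif(1)
  }
  tau <- sample_waiting_time(total, u1)
  if (is.null(u2)) u2 <- runif(1)
  j <- select_channel(alpha, u2)
  state <- apply_channel(state, channels[[j]])
  state$t <- state$t + tau
  list(state = state,
       event = data.frame(t = state$t, channel = j, tau = tau))
}

#' Run the stochastic simulation
#'
#' Gillespie direct method: repeat \{compute the ten propensities, draw
#' the exponential waiting time from `u1`, pick the channel by
#' propensity fractions from `u2`, apply the change-matrix column,
#' advance time\} until `t_end`, an absorbing state, or the event cap.
#'
#' The default engine is compiled; `engine = "R"` runs the pure-R
#' reference loop ([ssa_step()] repeatedly), which consumes the same
#' RNG stream and therefore reproduces the compiled trajectory
#' bit-for-bit under the same seed -- useful for validation, far too
#' slow for full-scale runs.
#'
#' @param initial A [system_state()] (its `A_s` is the constant source
#'   count for the run; set it to 0 for a wash).
#' @param rates A [rate_constants()] object.
#' @param t_end End time (s), greater than `initial$t`.
#' @param policy A [recording_policy()]; default: 300 uniform snapshot
#'   times over `[initial$t, t_end]`, no event log.
#' @param seed Integer seed; when non-NULL the run is a pure function
#'   of its arguments.
#' @param engine `"cpp"` (compiled, default) or `"R"` (reference).
#' @return An object of class `ssa_trajectory`: list with `times`,
#'   `counts` (matrix, one row per snapshot, columns
#'   `A_b, A_c, A_o, AR, ARR, R`), `final_state`, `event_count`,
#'   `truncated`, `absorbed`, `event_log` (data frame or NULL),
#'   plus the `initial` state and `rates` used.
#' @export
#' @examples
#' traj <- ssa_run(system_state(R = 500, A_s = 50), rate_constants(),
#'                 t_end = 5, seed = 1)
#' tail(as.data.frame(traj))
ssa_run <- function(initial, rates, t_end, policy = NULL, seed = NULL,
                    engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  initial <- validate_system_state(initial)
  rates <- validate_rate_constants(rates)
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end <= initial$t)
    .stop("t_end must exceed the initial time", "mabsim_parameter_error")
  if (is.null(policy)) policy <- default_policy(initial$t, t_end)
  stopifnot(inherits(policy, "recording_policy"))
  if (!is.null(seed)) set.seed(seed)

  if (engine == "cpp") {
    res <- ssa_core(state_counts(initial), initial$A_s,
                    as.numeric(unclass(rates)[.channel_names]),
                    initial$t, t_end, policy$snapshot_times,
                    policy$keep_event_log, policy$max_events)
  } else {
    res <- ssa_loop_r(initial, rates, t_end, policy)
  }

  counts <- res$snapshots
  colnames(counts) <- .species
  fin <- as.list(res$final)
  names(fin) <- .species
  final_state <- validate_system_state(
    c(list(A_s = initial$A_s), fin, list(t = res$t)))
  log <- res$event_log
  if (!is.null(log) && nrow(log) > 0 && engine == "cpp")
    log$channel <- log$channel + 1L
  if (isTRUE(res$truncated))
    warning("event cap reached at t = ", format(res$t),
            " s; trajectory truncated", call. = FALSE)
  structure(list(times = policy$snapshot_times, counts = counts,
                 final_state = final_state, event_count = res$event_count,
                 truncated = isTRUE(res$truncated),
                 absorbed = isTRUE(res$absorbed),
                 event_log = log, initial = initial, rates = rates,
                 t_end = t_end, engine = engine, seed = seed),
            class = "ssa_trajectory")
}

# Pure-R reference loop; mirrors ssa_core() statement-for-statement so
# that both engines consume the RNG stream identically.
ssa_loop_r <- function(initial, rates, t_end, policy) {
  channels <- build_channels(rates)
  delta <- channel_delta_matrix()
  state <- state_counts(initial)
  A_s <- initial$A_s
  k <- as.numeric(unclass(rates)[.channel_names])
  grid <- policy$snapshot_times
  nsnap <- length(grid)
  snaps <- matrix(NA_real_, nrow = nsnap, ncol = length(.species))
  si <- 1L
  t <- initial$t
  events <- 0
  truncated <- FALSE
  absorbed <- FALSE
  log_t <- numeric(0); log_ch <- integer(0); log_tau <- numeric(0)

  repeat {
    if (t >= t_end) break
    if (events >= policy$max_events) { truncated <- TRUE; break }
    a <- c(k[1] * A_s, k[2] * state[1], k[3] * state[1], k[4] * state[2],
           k[5] * state[2], k[6] * state[3], k[7] * state[3] * state[6],
           k[8] * state[4], k[9] * state[4] * state[6], k[10] * state[5])
    total <- sum(a)
    if (total <= 0) { absorbed <- TRUE; break }
    u1 <- runif(1)
    while (u1 <= 0) u1 <- runif(1)
    tau <- -log(u1) / total
    tnew <- t + tau
    while (si <= nsnap && grid[si] < tnew) {
      snaps[si, ] <- state
      si <- si + 1L
    }
    if (tnew > t_end) { t <- t_end; break }
    u2 <- runif(1)
    j <- select_channel(a, u2)
    state <- state + delta[, j]
    if (any(state < 0)) .stop("negative count", "mabsim_invariant_error")
    t <- tnew
    events <- events + 1
    if (policy$keep_event_log) {
      log_t <- c(log_t, t); log_ch <- c(log_ch, j)
      log_tau <- c(log_tau, tau)
    }
  }
  while (si <= nsnap) { snaps[si, ] <- state; si <- si + 1L }

  list(snapshots = snaps, final = state, t = t, event_count = events,
       truncated = truncated, absorbed = absorbed,
       event_log = if (policy$keep_event_log)
         data.frame(t = log_t, channel = log_ch, tau = log_tau))
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  cat(sprintf("ssa_trajectory: %g events over [%g, %g] s (%s engine)\n",
              x$event_count, x$initial$t, x$final_state$t, x$engine))
  if (x$truncated) cat("  ** truncated at the event cap **\n")
  if (x$absorbed) cat("  reached an absorbing state\n")
  cat(sprintf("  final: A_b = %g  A_c = %g  A_o = %g  AR = %g  ARR = %g  R = %g  (ABC = %g)\n",
              x$final_state$A_b, x$final_state$A_c, x$final_state$A_o,
              x$final_state$AR, x$final_state$ARR, x$final_state$R,
              abc(x$final_state)))
  invisible(x)
}

#' @export
as.data.frame.ssa_trajectory <- function(x, ...) {
  data.frame(t = x$times, x$counts,
             ABC = x$counts[, "AR"] + x$counts[, "ARR"])
}
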