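#' Mean-field rate equations
#'
#' Deterministic large-count limit of the reaction network: each
#' propensity becomes a mass-action term.  This is an engineering
#' validation oracle for the stochastic engine -- ensemble means of the
#' simulation should track these ODEs at the model's molecule numbers
#' -- not a claim of the underlying study.  It carries no fluctuation
#' information, so only means (never SD or CV%) are compared against
#' it.
#'
#' @param state Named numeric vector or list with `A_b, A_c, A_o, AR,
#'   ARR, R`.
#' @param rates A [rate_constants()] object.
#' @param A_s Constant source count.
#' @return Named numeric vector of time derivatives, in species order.
#' @export
#' @examples
#' ode_rhs(c(A_b = 0, A_c = 0, A_o = 0, AR = 0, ARR = 0, R = 1e5),
#'         rate_constants(), A_s = 3000)
ode_rhs <- function(state, rates, A_s) {
  rates <- validate_rate_constants(rates)
  s <- as.list(state)
  with(c(s, as.list(unclass(rates)), list(A_s = A_s)), {
    c(A_b = k_2p * A_s - (k_2n + k_1p) * A_b + k_1n * A_c,
      A_c = k_1p * A_b - (k_1n + k_on) * A_c + k_off * A_o,
      A_o = k_on * A_c - k_off * A_o - k_mp * A_o * R + k_mn * AR,
      AR = k_mp * A_o * R - k_mn * AR - k_bp * AR * R + k_bn * ARR,
      ARR = k_bp * AR * R - k_bn * ARR,
      R = -k_mp * A_o * R + k_mn * AR - k_bp * AR * R + k_bn * ARR)
  })
}

#' Integrate the mean-field equations
#'
#' Stiff-capable integration (the rate scales span roughly 1e-8 to
#' 1e5 1/s) via [deSolve::lsoda()].  Receptor conservation
#' `R + AR + 2*ARR` is monitored and must drift by less than 1e-6
#' relative over the run.
#'
#' @param initial A [system_state()] or named vector of the six counts.
#' @param rates A [rate_constants()] object.
#' @param t_end Horizon (s).
#' @param A_s Source count; taken from `initial` if it is a
#'   [system_state()] and `A_s` is NULL.
#' @param times Output time grid; default 300 uniform points.
#' @param rtol,atol Integrator tolerances.
#' @return Data frame with columns `t`, the six populations, and `ABC`.
#' @export
#' @examples
#' mf <- mean_field_run(system_state(), rate_constants(), t_end = 30)
#' tail(mf, 1)
mean_field_run <- function(initial, rates, t_end, A_s = NULL,
                           times = NULL, rtol = 1e-8, atol = 1e-6) {
  rates <- validate_rate_constants(rates)
  if (inherits(initial, "system_state")) {
    if (is.null(A_s)) A_s <- initial$A_s
    y0 <- state_counts(initial)
    t0 <- initial$t
  } else {
    y0 <- as.numeric(initial[.species])
    t0 <- 0
    if (is.null(A_s)) .stop("A_s required", "mabsim_parameter_error")
  }
  names(y0) <- .species
  stopifnot(rtol > 0, atol > 0, t_end >= t0)
  if (is.null(times)) times <- seq(t0, t_end, length.out = 300)
  if (t_end == t0) times <- c(t0, t0)

  rhs <- function(t, y, parms) list(ode_rhs(y, rates, A_s))
  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    .stop(paste("mean-field integration failed:",
                paste(attr(sol, "istate"), collapse = " ")),
          "mabsim_solver_error")
  out <- as.data.frame(sol)
  names(out)[1] <- "t"
  out$ABC <- out$AR + out$ARR

  cons <- out$R + out$AR + 2 * out$ARR
  ref <- cons[1]
  if (ref > 0 && max(abs(cons - ref)) / ref > 1e-6)
    .stop("receptor conservation drifted beyond 1e-6 relative",
          "mabsim_solver_error")
  if (t_end == t0) out <- out[1, , drop = FALSE]
  out
}
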