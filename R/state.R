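#' System state: molecule counts and simulated time
#'
#' Tracks the integer counts of the six dynamic populations -- antibody
#' in the boundary layer (`A_b`), cell layer (`A_c`), nonspecifically
#' adsorbed on the surface (`A_o`), monovalent complexes (`AR`),
#' bivalent complexes (`ARR`), free receptors (`R`) -- together with the
#' transition-layer count `A_s` (a fixed boundary condition, not a
#' dynamic variable) and the simulated time `t` in seconds.
#'
#' Counts are stored as exact whole numbers so the conservation law
#' `R + AR + 2*ARR = const` can be asserted bit-exactly.
#'
#' @param R Free receptors on the cell surface.
#' @param A_s Transition-layer antibody count (source value; held
#'   constant during a run).
#' @param A_b,A_c,A_o,AR,ARR Initial counts of the remaining
#'   populations.
#' @param t Simulated time (s).
#' @return An object of class `system_state`.
#' @export
#' @examples
#' s <- system_state(R = 1e5, A_s = 3000)
#' abc(s)              # antibodies bound per cell: AR + ARR
#' receptor_total(s)   # conserved quantity R + AR + 2*ARR
system_state <- function(R = 100000, A_s = 3000, A_b = 0, A_c = 0,
                         A_o = 0, AR = 0, ARR = 0, t = 0) {
  s <- list(A_s = A_s, A_b = A_b, A_c = A_c, A_o = A_o,
            AR = AR, ARR = ARR, R = R, t = t)
  validate_system_state(s)
}

validate_system_state <- function(s) {
  for (nm in c("A_s", .species)) {
    v <- s[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        v < 0 || v != round(v))
      .stop(sprintf("count '%s' must be a single non-negative integer", nm),
            "mabsim_state_error")
    s[[nm]] <- as.numeric(round(v))
  }
  if (!is.numeric(s$t) || length(s$t) != 1L || !is.finite(s$t) || s$t < 0)
    .stop("time t must be a single non-negative number", "mabsim_state_error")
  structure(s, class = "system_state")
}

#' Antibodies bound per cell (ABC)
#'
#' `ABC = AR + ARR`: each bound antibody counts once whether it engages
#' one receptor or bridges two.  This is the quantity a calibrated flow
#' cytometer reports via the mean fluorescence intensity.
#'
#' @param state A [system_state()].
#' @return Bound-antibody count.
#' @export
abc <- function(state) {
  stopifnot(inherits(state, "system_state"))
  state$AR + state$ARR
}

#' Occupied receptors
#'
#' `AR + 2*ARR`: monovalent complexes hold one receptor, bivalent
#' complexes two.  Together with the free count this is conserved:
#' `bound_receptors(s) + s$R` never changes during a run.
#'
#' @param state A [system_state()].
#' @return Receptor count held in complexes.
#' @export
bound_receptors <- function(state) {
  stopifnot(inherits(state, "system_state"))
  state$AR + 2 * state$ARR
}

#' Conserved receptor total
#'
#' @param state A [system_state()].
#' @return `R + AR + 2*ARR`, invariant over any event sequence.
#' @export
receptor_total <- function(state) {
  stopifnot(inherits(state, "system_state"))
  state$R + state$AR + 2 * state$ARR
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("system_state at t = %g s\n", x$t))
  cat(sprintf("  layers:  A_s = %g (source)  A_b = %g  A_c = %g\n",
              x$A_s, x$A_b, x$A_c))
  cat(sprintf("  surface: A_o = %g  AR = %g  ARR = %g  R = %g\n",
              x$A_o, x$AR, x$ARR, x$R))
  cat(sprintf("  ABC = %g;  receptor total = %g\n",
              abc(x), receptor_total(x)))
  invisible(x)
}

#' @export
as.data.frame.system_state <- function(x, ...) {
  data.frame(t = x$t, A_b = x$A_b, A_c = x$A_c, A_o = x$A_o,
             AR = x$AR, ARR = x$ARR, R = x$R, ABC = abc(x))
}

# counts as an unnamed numeric vector in .species order (internal)
state_counts <- function(state) {
  vapply(.species, function(nm) state[[nm]], numeric(1))
}
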