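#' Canonical rate presets
#'
#' Named binding-rate sets used throughout the study of ABC
#' variability; diffusion and adsorption rates always come from the
#' shell geometry.
#'
#' * `"similar"` -- comparable monovalent and bivalent occupancy at
#'   equilibrium: `k_mp = 1e-4, k_mn = 1e-6, k_bp = 2e-6, k_bn = 1e-8`.
#' * `"ar_dominant"` -- monovalent binding dominates:
#'   `k_mp = 2e-4, k_mn = 1e-6, k_bp = 1e-7, k_bn = 1e-9`.
#' * `"arr_dominant"` -- bivalent binding dominates:
#'   `k_mp = 1e-4, k_mn = 1e-6, k_bp = 2e-4, k_bn = 1e-8`.
#' * `"cluster_two_point"` -- base rates for the receptor-clustering
#'   ensemble in which each cell draws `k_bp` from \{1e-7, 1e-6\};
#'   `k_bn = 1e-9`.  The returned `k_bp` is the geometric midpoint
#'   10^-6.5; ensembles override it per cell.
#' * `"lognormal_kbp"` -- base rates for the ensemble with
#'   `log10(k_bp) ~ Normal(-6.5, 0.5)`; `k_bn = 1e-8`; returned
#'   `k_bp` is the median 10^-6.5.
#'
#' @param case_name One of the names above.
#' @param geometry A [geometry_params()] object.
#' @return A [rate_constants()] object.
#' @export
#' @examples
#' preset_rates("ar_dominant")[["k_mp"]]  # 2e-4
preset_rates <- function(case_name, geometry = geometry_params()) {
  presets <- list(
    similar          = c(k_mp = 1e-4, k_mn = 1e-6, k_bp = 2e-6,
                         k_bn = 1e-8),
    ar_dominant      = c(k_mp = 2e-4, k_mn = 1e-6, k_bp = 1e-7,
                         k_bn = 1e-9),
    arr_dominant     = c(k_mp = 1e-4, k_mn = 1e-6, k_bp = 2e-4,
                         k_bn = 1e-8),
    cluster_two_point = c(k_mp = 1e-4, k_mn = 1e-6, k_bp = 10^-6.5,
                          k_bn = 1e-9),
    lognormal_kbp    = c(k_mp = 1e-4, k_mn = 1e-6, k_bp = 10^-6.5,
                         k_bn = 1e-8))
  if (!is.character(case_name) || length(case_name) != 1L ||
      !case_name %in% names(presets))
    .stop(paste0("unknown rate preset '", paste(case_name, collapse = ","),
                 "'; valid: ", paste(names(presets), collapse = ", ")),
          "mabsim_parameter_error")
  p <- presets[[case_name]]
  rate_constants(k_mp = p[["k_mp"]], k_mn = p[["k_mn"]],
                 k_bp = p[["k_bp"]], k_bn = p[["k_bn"]],
                 geometry = geometry)
}

#' Scenario specification
#'
#' Bundles a name, rate set, initial state (whose `A_s` is the source
#' value in force during the run) and horizon.
#'
#' @param name Scenario label.
#' @param rates A [rate_constants()] object.
#' @param initial A [system_state()].
#' @param t_end Horizon (s).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, rates, initial, t_end) {
  rates <- validate_rate_constants(rates)
  initial <- validate_system_state(initial)
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end <= initial$t)
    .stop("t_end must be positive and exceed the initial time",
          "mabsim_parameter_error")
  structure(list(name = name, rates = rates, initial = initial,
                 t_end = t_end, source_value = initial$A_s),
            class = "scenario_spec")
}

#' The labeling scenario
#'
#' A cell with `R0` free receptors is immersed in a saturating antibody
#' suspension: the transition layer is pinned at `A_s` molecules and
#' all other populations start at zero.  The default 30 s horizon is
#' past the ~25 s equilibration of the transport layers; the remaining
#' ~30 min of a real incubation is stationary and need not be
#' simulated (raise `t_end` to do so anyway).
#'
#' @param R0 Initial free receptor count.
#' @param A_s Constant transition-layer count (source value).
#' @param rates A [rate_constants()] object.
#' @param t_end Horizon (s).
#' @return A [scenario_spec()].
#' @export
#' @examples
#' sc <- labeling_scenario()
#' sc$initial$R      # 100000
labeling_scenario <- function(R0 = 100000, A_s = 3000,
                              rates = preset_rates("similar"),
                              t_end = 30) {
  if (!is.numeric(R0) || length(R0) != 1L || R0 < 0)
    .stop("R0 must be a non-negative count", "mabsim_parameter_error")
  scenario_spec("labeling", rates,
                system_state(R = R0, A_s = A_s, A_b = 0, A_c = 0,
                             A_o = 0, AR = 0, ARR = 0, t = 0),
                t_end)
}

#' The post-labeling (wash) scenario
#'
#' The labeled cell is resuspended in antibody-free buffer: the run
#' continues from the final labeling state, but the transition layer is
#' now an empty sink (`A_s = 0`), so every molecule that diffuses out
#' of the boundary layer is lost to the bulk.  Dynamics span many
#' decades -- desorption and outward diffusion within milliseconds,
#' then slow dissociation of `AR`/`ARR` over hours -- hence the long
#' default horizon.
#'
#' @param labeled A [system_state()], normally the `final_state` of a
#'   labeling trajectory.
#' @param rates A [rate_constants()] object.
#' @param t_end Horizon (s).
#' @return A [scenario_spec()]; its initial time is reset to 0.
#' @export
post_labeling_scenario <- function(labeled,
                                   rates = preset_rates("similar"),
                                   t_end = 3e4) {
  labeled <- validate_system_state(labeled)
  labeled$A_s <- 0
  labeled$t <- 0
  scenario_spec("post_labeling", rates, labeled, t_end)
}

#' Run a scenario
#'
#' @param scenario A [scenario_spec()].
#' @param policy Optional [recording_policy()]; the default uses 300
#'   uniform snapshots for the labeling run and a logarithmic grid for
#'   the post-labeling run (its dynamics span ten decades of time).
#' @param seed,engine Passed to [ssa_run()].
#' @return An `ssa_trajectory`.
#' @export
run_scenario <- function(scenario, policy = NULL, seed = NULL,
                         engine = "cpp") {
  stopifnot(inherits(scenario, "scenario_spec"))
  if (is.null(policy)) {
    policy <- if (identical(scenario$name, "post_labeling"))
      recording_policy(log_time_grid(1e-6, scenario$t_end))
    else default_policy(scenario$initial$t, scenario$t_end)
  }
  ssa_run(scenario$initial, scenario$rates, scenario$t_end,
          policy = policy, seed = seed, engine = engine)
}

#' Sensitivity of equilibrium ABC to the desorption rate
#'
#' Cell-to-cell variation in surface area changes the adsorbed-antibody
#' pool; its effect can be probed by scanning the desorption-to-
#' adsorption ratio `k_off / k_on` around its default 0.5.  Equilibrium
#' is read as the state at the end of the run, so lengthening `t_end`
#' shrinks the residual sensitivity (adsorption level changes the time
#' to reach equilibrium more than the equilibrium itself).
#'
#' @param multipliers Values of `k_off / k_on` to scan.
#' @param t_end Horizon (s).
#' @param R0,A_s Labeling initial condition.
#' @param binding Binding-rate preset name for the scan.
#' @param seed Base seed; run `i` uses `seed + i - 1`.
#' @return Data frame with `multiplier`, final `ABC`, `AR`, `ARR`,
#'   `A_o`, and `rel_spread` (identical in every row: the full ABC
#'   range divided by the mean ABC).
#' @export
koff_sensitivity_scan <- function(multipliers = c(0.4, 0.5, 0.6),
                                  t_end = 30, R0 = 100000, A_s = 3000,
                                  binding = "similar", seed = 1) {
  rows <- lapply(seq_along(multipliers), function(i) {
    m <- multipliers[i]
    base <- preset_rates(binding)
    rates <- rate_constants(k_mp = base[["k_mp"]], k_mn = base[["k_mn"]],
                            k_bp = base[["k_bp"]], k_bn = base[["k_bn"]],
                            koff_factor = m)
    sc <- labeling_scenario(R0 = R0, A_s = A_s, rates = rates,
                            t_end = t_end)
    fin <- run_scenario(sc, seed = seed + i - 1)$final_state
    data.frame(multiplier = m, ABC = abc(fin), AR = fin$AR,
               ARR = fin$ARR, A_o = fin$A_o)
  })
  out <- do.call(rbind, rows)
  out$rel_spread <- (max(out$ABC) - min(out$ABC)) / mean(out$ABC)
  out
}
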