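#' Per-cell parameter distributions
#'
#' Heterogeneity across the cell population enters through two per-cell
#' parameters: the initial receptor count and the bivalent association
#' rate `k_bp`.
#'
#' * `dist_fixed(value)` -- every cell gets `value`.
#' * `dist_normal(mean, cv_percent)` -- Normal with SD given as CV%
#'   of the mean (receptor counts; draws are rounded and floored at 1).
#' * `dist_two_point(low, high, p_high)` -- `high` with probability
#'   `p_high`, else `low` (clustered vs solitary receptors).
#' * `dist_log10_normal(mean_exponent, sd_exponent)` -- `10^N` with
#'   `N ~ Normal(mean_exponent, sd_exponent)`.
#'
#' @param value,mean,cv_percent,low,high,p_high,mean_exponent,sd_exponent
#'   Distribution parameters.
#' @return An object of class `mabsim_dist`.
#' @name distributions
#' @export
dist_fixed <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, value >= 0)
  structure(list(kind = "fixed", value = value), class = "mabsim_dist")
}

#' @rdname distributions
#' @export
dist_normal <- function(mean, cv_percent) {
  stopifnot(mean > 0, cv_percent >= 0)
  structure(list(kind = "normal", mean = mean, cv_percent = cv_percent),
            class = "mabsim_dist")
}

#' @rdname distributions
#' @export
dist_two_point <- function(low, high, p_high = 0.5) {
  stopifnot(low > 0, high > 0, p_high >= 0, p_high <= 1)
  structure(list(kind = "two_point", low = low, high = high,
                 p_high = p_high), class = "mabsim_dist")
}

#' @rdname distributions
#' @export
dist_log10_normal <- function(mean_exponent, sd_exponent) {
  stopifnot(is.finite(mean_exponent), sd_exponent >= 0)
  structure(list(kind = "log10_normal", mean_exponent = mean_exponent,
                 sd_exponent = sd_exponent), class = "mabsim_dist")
}

sample_dist <- function(d, n) {
  stopifnot(inherits(d, "mabsim_dist"))
  switch(d$kind,
    fixed = rep(d$value, n),
    normal = rnorm(n, d$mean, d$mean * d$cv_percent / 100),
    two_point = ifelse(runif(n) < d$p_high, d$high, d$low),
    log10_normal = 10^rnorm(n, d$mean_exponent, d$sd_exponent))
}

#' Ensemble specification
#'
#' Describes a population of cells to be labeled independently: how
#' many, how their receptor counts and bivalent affinities vary, the
#' shared rate set, and the labeling horizon.  Results are a pure
#' function of the spec (including `master_seed`), regardless of
#' execution order.
#'
#' @param n_cells Number of cells (replicate simulations); at least 2.
#' @param receptor_dist A [dist_fixed()] or [dist_normal()] for the
#'   initial receptor count.
#' @param kbp_dist A [dist_fixed()], [dist_two_point()] or
#'   [dist_log10_normal()] for the per-cell `k_bp`.
#' @param base_rates Shared [rate_constants()]; `k_bp` is replaced
#'   per cell by the draw from `kbp_dist`.
#' @param A_s Constant source count during labeling.
#' @param t_end Labeling horizon (s); the equilibrium readout is the
#'   final state at `t_end`.  The default 60 s is past receptor
#'   saturation (`R = 0`) for every canonical preset -- the population
#'   tables describe the saturated state, and a real incubation runs
#'   ~30 min, so any horizon beyond saturation reads the same
#'   stationary values.  The slowest preset (`k_bp = 1e-7`) still
#'   carries ~7,500 free receptors at 30 s.
#' @param master_seed Integer seed from which all per-cell draws and
#'   per-cell simulation seeds derive.
#' @param on_truncated `"warn"` (keep the cell, warn) or `"error"`.
#' @return An object of class `ensemble_spec`.
#' @export
#' @examples
#' spec <- ensemble_spec(n_cells = 25,
#'                       receptor_dist = dist_normal(1e5, 6),
#'                       master_seed = 7)
ensemble_spec <- function(n_cells = 25,
                          receptor_dist = dist_fixed(100000),
                          kbp_dist = NULL,
                          base_rates = preset_rates("similar"),
                          A_s = 3000, t_end = 60, master_seed = 1,
                          on_truncated = c("warn", "error")) {
  base_rates <- validate_rate_constants(base_rates)
  if (is.null(kbp_dist)) kbp_dist <- dist_fixed(base_rates[["k_bp"]])
  stopifnot(inherits(receptor_dist, "mabsim_dist"),
            inherits(kbp_dist, "mabsim_dist"))
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 2)
    .stop("n_cells must be >= 2", "mabsim_parameter_error")
  if (!is.numeric(master_seed) || length(master_seed) != 1L ||
      !is.finite(master_seed))
    .stop("master_seed must be a finite integer", "mabsim_parameter_error")
  structure(list(n_cells = as.integer(n_cells),
                 receptor_dist = receptor_dist, kbp_dist = kbp_dist,
                 base_rates = base_rates, A_s = A_s, t_end = t_end,
                 master_seed = as.integer(master_seed),
                 on_truncated = match.arg(on_truncated)),
            class = "ensemble_spec")
}

#' Draw the per-cell parameters of an ensemble
#'
#' Deterministic in the spec: seeds the RNG with `master_seed`, draws
#' every cell's receptor count (rounded to an integer and floored at 1)
#' and `k_bp`, and derives one independent simulation seed per cell.
#'
#' @param spec An [ensemble_spec()].
#' @return Data frame with one row per cell: `cell`, `seed`, `R_init`,
#'   `k_bp`.
#' @export
sample_cell_parameters <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  set.seed(spec$master_seed)
  n <- spec$n_cells
  R_init <- pmax(1, round(sample_dist(spec$receptor_dist, n)))
  k_bp <- sample_dist(spec$kbp_dist, n)
  seeds <- sample.int(2147483646L, n)
  data.frame(cell = seq_len(n), seed = seeds, R_init = R_init,
             k_bp = k_bp)
}

#' Label a population of cells and summarise ABC variability
#'
#' Runs one independent labeling simulation per cell with that cell's
#' receptor count and bivalent affinity, reads the equilibrium state at
#' `t_end`, and tabulates the mean, standard deviation and CV% of the
#' initial receptor count, `AR`, `ARR` and total bound antibody
#' (`TotalA = AR + ARR = ABC`) across the population.
#'
#' @param spec An [ensemble_spec()].
#' @param engine Simulation engine, as in [ssa_run()].
#' @return An object of class `mabsim_ensemble`: list with `cells`
#'   (one row per cell: `cell`, `seed`, `R_init`, `k_bp`, `AR`, `ARR`,
#'   `R_free`, `ABC`, `bound_receptors`, `truncated`), `summary`
#'   (see [ensemble_summary()]) and the `spec`.
#' @export
#' @examples
#' \donttest{
#' res <- run_ensemble(ensemble_spec(n_cells = 5, t_end = 30,
#'                                   master_seed = 1))
#' res$summary
#' }
run_ensemble <- function(spec, engine = "cpp") {
  stopifnot(inherits(spec, "ensemble_spec"))
  pars <- sample_cell_parameters(spec)
  rows <- lapply(seq_len(nrow(pars)), function(i) {
    r <- spec$base_rates
    rates <- validate_rate_constants(
      replace(unclass(r), "k_bp", pars$k_bp[i]))
    sc <- labeling_scenario(R0 = pars$R_init[i], A_s = spec$A_s,
                            rates = rates, t_end = spec$t_end)
    # single end-point snapshot keeps 25+ full-scale runs lightweight
    pol <- recording_policy(spec$t_end)
    traj <- ssa_run(sc$initial, sc$rates, sc$t_end, policy = pol,
                    seed = pars$seed[i], engine = engine)
    fin <- traj$final_state
    data.frame(cell = pars$cell[i], seed = pars$seed[i],
               R_init = pars$R_init[i], k_bp = pars$k_bp[i],
               AR = fin$AR, ARR = fin$ARR, R_free = fin$R,
               ABC = abc(fin), bound_receptors = bound_receptors(fin),
               truncated = traj$truncated)
  })
  cells <- do.call(rbind, rows)
  if (any(cells$truncated)) {
    msg <- sprintf("%d of %d cell runs hit the event cap",
                   sum(cells$truncated), nrow(cells))
    if (identical(spec$on_truncated, "error"))
      .stop(msg, "mabsim_truncation_error")
    warning(msg, call. = FALSE)
  }
  structure(list(cells = cells, summary = ensemble_summary(cells),
                 spec = spec),
            class = "mabsim_ensemble")
}

#' Coefficient of variation, in percent
#'
#' `100 * SD / mean`, with the sample (n-1 denominator) standard
#' deviation.
#'
#' @param values Numeric vector, length >= 2, non-zero mean.
#' @return CV%.
#' @export
#' @examples
#' cv_percent(c(90, 100, 110))  # 10
cv_percent <- function(values) {
  if (!is.numeric(values) || length(values) < 2L)
    .stop("need at least two values", "mabsim_parameter_error")
  m <- mean(values)
  if (m == 0)
    .stop("CV% undefined: mean is zero", "mabsim_parameter_error")
  100 * sd(values) / m
}

#' Population summary table
#'
#' @param cells The per-cell results of [run_ensemble()].
#' @return Data frame with rows `mean`, `SD`, `CV%` and columns
#'   `R_init`, `AR`, `ARR`, `TotalA`.
#' @export
ensemble_summary <- function(cells) {
  stopifnot(is.data.frame(cells), nrow(cells) >= 2L)
  cols <- list(R_init = cells$R_init, AR = cells$AR, ARR = cells$ARR,
               TotalA = cells$ABC)
  out <- data.frame(row.names = c("mean", "SD", "CV%"))
  for (nm in names(cols)) {
    v <- cols[[nm]]
    out[[nm]] <- c(mean(v), sd(v),
                   if (mean(v) == 0) NA_real_ else 100 * sd(v) / mean(v))
  }
  out
}

#' ABC against initial receptor count
#'
#' The scatter underlying the population analysis: with fixed binding
#' rates, equilibrium ABC is (up to intrinsic noise) an increasing,
#' nearly linear function of the cell's receptor count; fluctuating
#' bivalent affinity scatters the points off that line.
#'
#' @param results A `mabsim_ensemble` or its `cells` data frame.
#' @return Data frame with columns `R_init`, `ABC`.
#' @export
abc_vs_receptors_table <- function(results) {
  cells <- if (inherits(results, "mabsim_ensemble")) results$cells
           else results
  if (!is.data.frame(cells) || nrow(cells) == 0L)
    .stop("no cell results to tabulate", "mabsim_parameter_error")
  data.frame(R_init = cells$R_init, ABC = cells$ABC)
}

#' @export
print.mabsim_ensemble <- function(x, ...) {
  cat(sprintf("mabsim_ensemble: %d cells, t_end = %g s, master seed %d\n",
              nrow(x$cells), x$spec$t_end, x$spec$master_seed))
  print(round(x$summary, 3))
  invisible(x)
}

#' Canonical ensemble presets
#'
#' The named population studies of ABC variability, in increasing order
#' of heterogeneity:
#'
#' * `"table4"`: fixed `R = 1e5`, similar rates -- intrinsic
#'   stochastic noise only.
#' * `"table5_similar"`, `"table5_ar"`, `"table5_arr"`: receptor count
#'   `~ Normal(1e5, CV 6%)` with the three binding presets.
#' * `"table6"`: fixed `R`, two-point `k_bp` in \{1e-7, 1e-6\}
#'   (`k_bn = 1e-9`) -- receptor clustering, upper-bound scenario.
#' * `"table7"`: receptor count `~ Normal(1e5, CV 6%)` and
#'   `log10(k_bp) ~ Normal(-6.5, 0.5)` (`k_bn = 1e-8`).
#'
#' @param name Preset name (see above).
#' @param n_cells,master_seed,t_end Overrides of the study defaults
#'   (25 cells, seed 1, 60 s -- past saturation for every preset).
#' @return An [ensemble_spec()].
#' @export
preset_ensemble <- function(name, n_cells = 25, master_seed = 1,
                            t_end = 60) {
  fixedR <- dist_fixed(100000)
  normR <- dist_normal(100000, 6)
  specs <- list(
    table4 = list(receptor_dist = fixedR, kbp_dist = NULL,
                  base = "similar"),
    table5_similar = list(receptor_dist = normR, kbp_dist = NULL,
                          base = "similar"),
    table5_ar = list(receptor_dist = normR, kbp_dist = NULL,
                     base = "ar_dominant"),
    table5_arr = list(receptor_dist = normR, kbp_dist = NULL,
                      base = "arr_dominant"),
    table6 = list(receptor_dist = fixedR,
                  kbp_dist = dist_two_point(1e-7, 1e-6, 0.5),
                  base = "cluster_two_point"),
    table7 = list(receptor_dist = normR,
                  kbp_dist = dist_log10_normal(-6.5, 0.5),
                  base = "lognormal_kbp"))
  if (!is.character(name) || length(name) != 1L || !name %in% names(specs))
    .stop(paste0("unknown ensemble preset '",
                 paste(name, collapse = ","), "'; valid: ",
                 paste(names(specs), collapse = ", ")),
          "mabsim_parameter_error")
  s <- specs[[name]]
  ensemble_spec(n_cells = n_cells, receptor_dist = s$receptor_dist,
                kbp_dist = s$kbp_dist, base_rates = preset_rates(s$base),
                t_end = t_end, master_seed = master_seed)
}
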