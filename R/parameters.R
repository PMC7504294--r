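#' Geometry of the diffusion shells and the bulk suspension
#'
#' The cell is surrounded by three concentric spherical shells ("layers"):
#' the cell layer (adjacent to the membrane), the boundary layer, and the
#' transition layer, which exchanges antibody with the bulk suspension.
#' Each shell is 3.75 um thick by default, about the radius of a T cell.
#' Diffusive transfer of one antibody between adjacent shells occurs at
#' rate `D / h^2`, where `h` is the thickness of the shell the molecule
#' leaves.
#'
#' @param h_c Thickness of the cell layer (m).
#' @param h_b Thickness of the boundary layer (m).
#' @param h_t Thickness of the transition layer (m).
#' @param D Antibody diffusion coefficient in free solution (m^2/s).
#' @param transition_volume Volume of the transition shell (m^3).
#' @param bulk_concentration Antibody concentration in the bulk
#'   suspension (mol/m^3); the default 1e-6 mol/m^3 is 1 umol/m^3,
#'   a saturating label concentration.
#'
#' @return An object of class `geometry_params`.
#' @seealso [rate_constants()], [source_count_from_geometry()]
#' @export
#' @examples
#' g <- geometry_params()
#' g$D / g$h_c^2  # diffusive hop rate, 1/s
geometry_params <- function(h_c = 3.75e-6, h_b = 3.75e-6, h_t = 3.75e-6,
                            D = 0.5e-10,
                            transition_volume = 4.76e-15,
                            bulk_concentration = 1e-6) {
  g <- list(h_c = h_c, h_b = h_b, h_t = h_t, D = D,
            transition_volume = transition_volume,
            bulk_concentration = bulk_concentration)
  for (nm in names(g)) {
    v <- g[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      .stop(sprintf("geometry field '%s' must be a single positive number", nm),
            "mabsim_parameter_error")
  }
  hops <- c(D / h_c^2, D / h_b^2, D / h_t^2)
  if (!all(is.finite(hops) & hops > 0))
    .stop("derived hop rates D/h^2 must be finite and positive",
          "mabsim_parameter_error")
  structure(g, class = "geometry_params")
}

#' @export
print.geometry_params <- function(x, ...) {
  cat("Shell geometry: h_c =", format(x$h_c), " h_b =", format(x$h_b),
      " h_t =", format(x$h_t), "m\n")
  cat("D =", format(x$D), "m^2/s;  hop rate D/h_c^2 =",
      format(x$D / x$h_c^2), "1/s\n")
  invisible(x)
}

#' Constant antibody count of the transition layer
#'
#' The transition layer acts as a constant-count source during labeling.
#' Its count is the number of antibody molecules the shell holds at the
#' bulk concentration: volume x concentration x Avogadro's number,
#' rounded to the nearest multiple of `round_to` (default: the nearest
#' thousand, which turns 4.76e-15 m^3 at 1 umol/m^3, about 2,867
#' molecules, into the canonical 3000).
#'
#' @param geometry A [geometry_params()] object.
#' @param round_to Rounding granule in molecules; use `1` for no
#'   coarse rounding.
#' @return Molecule count (non-negative number).
#' @export
#' @examples
#' source_count_from_geometry(geometry_params())            # 3000
#' source_count_from_geometry(geometry_params(), round_to = 1)
source_count_from_geometry <- function(geometry, round_to = 1000) {
  stopifnot(inherits(geometry, "geometry_params"))
  n <- geometry$transition_volume * geometry$bulk_concentration * .avogadro
  round(n / round_to) * round_to
}

#' Reaction rate constants of the ten channels
#'
#' Builds the full ten-rate parameter set.  The six transport/adsorption
#' rates derive from the geometry: `k_2p = D/h_t^2` (transition to
#' boundary), `k_2n = D/h_b^2` (boundary to transition), `k_1p = D/h_c^2`
#' (boundary to cell layer), `k_1n = D/h_c^2` (cell to boundary layer),
#' `k_on = D/h_c^2` (adsorption: every arrival at the surface sticks),
#' and `k_off = koff_factor * k_on` (desorption; the default factor 0.5
#' keeps adsorbed antibody plentiful without depleting adsorption
#' sites).  The four binding rates are stochastic per-molecule
#' (`k_mn`, `k_bn`) or per-pair (`k_mp`, `k_bp`) probabilities per unit
#' time (1/s), applied directly to counts or count products.
#'
#' Any rate can be overridden explicitly, in which case the geometry is
#' ignored for that rate.
#'
#' @param k_mp Monovalent association rate, adsorbed antibody + free
#'   receptor -> AR (1/s per pair).
#' @param k_mn Monovalent dissociation rate, AR -> adsorbed + free
#'   receptor (1/s per molecule).
#' @param k_bp Bivalent association rate, AR + free receptor -> ARR
#'   (1/s per pair).
#' @param k_bn Bivalent dissociation rate, ARR -> AR + free receptor
#'   (1/s per molecule).
#' @param geometry A [geometry_params()] object supplying the transport
#'   rates.
#' @param koff_factor Desorption-to-adsorption ratio `k_off / k_on`.
#' @param k_2p,k_2n,k_1p,k_1n,k_on,k_off Optional explicit overrides
#'   (1/s).
#' @return A named numeric vector of class `rate_constants`, in the
#'   canonical channel order.
#' @export
#' @examples
#' r <- rate_constants()       # the default ("similar"-binding) rate set
#' r[["k_off"]] / r[["k_on"]]  # 0.5
rate_constants <- function(k_mp = 1e-4, k_mn = 1e-6,
                           k_bp = 2e-6, k_bn = 1e-8,
                           geometry = geometry_params(),
                           koff_factor = 0.5,
                           k_2p = NULL, k_2n = NULL, k_1p = NULL,
                           k_1n = NULL, k_on = NULL, k_off = NULL) {
  stopifnot(inherits(geometry, "geometry_params"))
  if (!is.numeric(koff_factor) || length(koff_factor) != 1L || koff_factor < 0)
    .stop("koff_factor must be a single non-negative number",
          "mabsim_parameter_error")
  kon <- if (is.null(k_on)) geometry$D / geometry$h_c^2 else k_on
  k <- c(k_2p = if (is.null(k_2p)) geometry$D / geometry$h_t^2 else k_2p,
         k_2n = if (is.null(k_2n)) geometry$D / geometry$h_b^2 else k_2n,
         k_1p = if (is.null(k_1p)) geometry$D / geometry$h_c^2 else k_1p,
         k_1n = if (is.null(k_1n)) geometry$D / geometry$h_c^2 else k_1n,
         k_on = kon,
         k_off = if (is.null(k_off)) koff_factor * kon else k_off,
         k_mp = k_mp, k_mn = k_mn, k_bp = k_bp, k_bn = k_bn)
  validate_rate_constants(k)
}

#' Validate a raw vector of ten rates
#'
#' @param k Named numeric vector containing the ten canonical rates.
#' @return The vector, classed `rate_constants`, in canonical order.
#' @keywords internal
#' @export
validate_rate_constants <- function(k) {
  if (!is.numeric(k) || !all(.channel_names %in% names(k)))
    .stop("rate set must be numeric and name all ten channels",
          "mabsim_parameter_error")
  k <- k[.channel_names]
  if (any(!is.finite(k)) || any(k < 0))
    .stop("all rate constants must be finite and >= 0",
          "mabsim_parameter_error")
  structure(k, class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Reaction rate constants (1/s):\n")
  print(setNames(as.numeric(x), names(unclass(x))))
  invisible(x)
}

#' @export
`[.rate_constants` <- function(x, i, ...) unclass(x)[i]
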