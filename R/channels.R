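#' The ten reaction channels
#'
#' Builds the reaction network: five reversible transitions that carry
#' an antibody from the bulk source to a bivalently bound complex.
#' In canonical order:
#'
#' | channel | event                              | propensity        |
#' |---------|------------------------------------|-------------------|
#' | `k_2p`  | transition -> boundary layer hop   | `k_2p * A_s`      |
#' | `k_2n`  | boundary -> transition layer hop   | `k_2n * A_b`      |
#' | `k_1p`  | boundary -> cell layer hop         | `k_1p * A_b`      |
#' | `k_1n`  | cell -> boundary layer hop         | `k_1n * A_c`      |
#' | `k_on`  | adsorption onto the surface        | `k_on * A_c`      |
#' | `k_off` | desorption into the cell layer     | `k_off * A_o`     |
#' | `k_mp`  | monovalent binding `A_o + R -> AR` | `k_mp * A_o * R`  |
#' | `k_mn`  | monovalent release `AR -> A_o + R` | `k_mn * AR`       |
#' | `k_bp`  | bivalent binding `AR + R -> ARR`   | `k_bp * AR * R`   |
#' | `k_bn`  | bivalent release `ARR -> AR + R`   | `k_bn * ARR`      |
#'
#' `k_2p` has source semantics: it fires at rate `k_2p * A_s` and adds a
#' molecule to the boundary layer, but `A_s` itself never changes (the
#' transition layer is pinned to the bulk suspension).  Likewise `k_2n`
#' removes a molecule from the boundary layer without crediting `A_s`.
#'
#' @param rates A [rate_constants()] object.
#' @return A list of ten `reaction_channel` objects, each with fields
#'   `name`, `rate`, `reactants` (state fields whose counts the rate
#'   multiplies) and `delta` (integer change vector over
#'   `A_b, A_c, A_o, AR, ARR, R`).
#' @export
#' @examples
#' ch <- build_channels(rate_constants())
#' ch[["k_mp"]]$delta  # A_o -1, AR +1, R -1
build_channels <- function(rates) {
  rates <- validate_rate_constants(rates)
  reactants <- list(
    k_2p = "A_s",  k_2n = "A_b",
    k_1p = "A_b",  k_1n = "A_c",
    k_on = "A_c",  k_off = "A_o",
    k_mp = c("A_o", "R"), k_mn = "AR",
    k_bp = c("AR", "R"),  k_bn = "ARR")
  delta <- channel_delta_matrix()
  chans <- lapply(.channel_names, function(nm) {
    structure(list(name = nm,
                   rate = rates[[nm]],
                   reactants = reactants[[nm]],
                   delta = delta[, nm]),
              class = "reaction_channel")
  })
  names(chans) <- .channel_names
  chans
}

#' Change matrix of the reaction network
#'
#' @return A 6 x 10 integer matrix; rows are the tracked species
#'   (`A_b, A_c, A_o, AR, ARR, R`), columns the channels in canonical
#'   order.  Applying a reaction adds its column to the count vector.
#' @export
channel_delta_matrix <- function() {
  m <- matrix(0L, nrow = length(.species), ncol = length(.channel_names),
              dimnames = list(.species, .channel_names))
  m["A_b", "k_2p"] <- 1L
  m["A_b", "k_2n"] <- -1L
  m[c("A_b", "A_c"), "k_1p"] <- c(-1L, 1L)
  m[c("A_b", "A_c"), "k_1n"] <- c(1L, -1L)
  m[c("A_c", "A_o"), "k_on"] <- c(-1L, 1L)
  m[c("A_c", "A_o"), "k_off"] <- c(1L, -1L)
  m[c("A_o", "AR", "R"), "k_mp"] <- c(-1L, 1L, -1L)
  m[c("A_o", "AR", "R"), "k_mn"] <- c(1L, -1L, 1L)
  m[c("AR", "ARR", "R"), "k_bp"] <- c(-1L, 1L, -1L)
  m[c("AR", "ARR", "R"), "k_bn"] <- c(1L, -1L, 1L)
  m
}

#' Propensity vector of the ten channels
#'
#' The propensity of a channel is its rate constant times the count (or
#' count product, for the two bimolecular channels) of its reactants;
#' a channel with an exhausted reactant has propensity zero.
#'
#' @param state A [system_state()].
#' @param channels Channel list from [build_channels()].
#' @return Named numeric vector of ten non-negative propensities (1/s).
#' @export
#' @examples
#' ch <- build_channels(rate_constants())
#' propensities(system_state(R = 1e5, A_s = 3000), ch)
propensities <- function(state, channels) {
  stopifnot(inherits(state, "system_state"))
  vapply(channels, function(ch) {
    ch$rate * prod(vapply(ch$reactants, function(nm) state[[nm]],
                          numeric(1)))
  }, numeric(1))
}

#' Apply one reaction to the state
#'
#' Adds the channel's change-matrix column to the count vector and
#' leaves `A_s` and `t` untouched.  Called by the engine after channel
#' selection; a negative resulting count signals an engine bug and
#' raises an error.
#'
#' @param state A [system_state()].
#' @param channel A `reaction_channel`.
#' @return The updated [system_state()].
#' @export
#' @examples
#' ch <- build_channels(rate_constants())
#' s <- system_state(R = 10, A_o = 5, A_s = 0)
#' apply_channel(s, ch[["k_mp"]])  # A_o 4, AR 1, R 9
apply_channel <- function(state, channel) {
  stopifnot(inherits(state, "system_state"),
            inherits(channel, "reaction_channel"))
  for (nm in names(channel$delta)) {
    d <- channel$delta[[nm]]
    if (d != 0L) {
      v <- state[[nm]] + d
      if (v < 0)
        .stop(sprintf("channel %s would drive %s below zero",
                      channel$name, nm),
              "mabsim_invariant_error")
      state[[nm]] <- v
    }
  }
  state
}

#' @export
print.reaction_channel <- function(x, ...) {
  cat(sprintf("reaction channel %s: rate = %g /s; reactants: %s\n",
              x$name, x$rate, paste(x$reactants, collapse = " * ")))
  d <- x$delta[x$delta != 0L]
  cat("  delta:", paste(sprintf("%s %+d", names(d), d), collapse = ", "),
      "\n")
  invisible(x)
}
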