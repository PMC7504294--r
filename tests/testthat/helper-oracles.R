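# Independent brute-force oracles used across the suite.

# Propensities hard-coded straight from the rate-law table, independent
# of the package's generic reactant-product machinery.
oracle_propensities <- function(state, k) {
  c(k[["k_2p"]] * state$A_s,
    k[["k_2n"]] * state$A_b,
    k[["k_1p"]] * state$A_b,
    k[["k_1n"]] * state$A_c,
    k[["k_on"]] * state$A_c,
    k[["k_off"]] * state$A_o,
    k[["k_mp"]] * state$A_o * state$R,
    k[["k_mn"]] * state$AR,
    k[["k_bp"]] * state$AR * state$R,
    k[["k_bn"]] * state$ARR)
}

random_state <- function() {
  system_state(A_s = sample(0:5000, 1), A_b = sample(0:5000, 1),
               A_c = sample(0:5000, 1), A_o = sample(0:10000, 1),
               AR = sample(0:50000, 1), ARR = sample(0:50000, 1),
               R = sample(0:100000, 1))
}

# Change matrix transcribed literally from the model's variable-change
# table (rows: A_b, A_c, A_o, AR, ARR, R; columns in canonical order).
oracle_delta <- matrix(
  c( 1, -1, -1,  1,  0,  0,  0,  0,  0,  0,
     0,  0,  1, -1, -1,  1,  0,  0,  0,  0,
     0,  0,  0,  0,  1, -1, -1,  1,  0,  0,
     0,  0,  0,  0,  0,  0,  1, -1, -1,  1,
     0,  0,  0,  0,  0,  0,  0,  0,  1, -1,
     0,  0,  0,  0,  0,  0, -1,  1, -1,  1),
  nrow = 6, byrow = TRUE,
  dimnames = list(c("A_b", "A_c", "A_o", "AR", "ARR", "R"),
                  c("k_2p", "k_2n", "k_1p", "k_1n", "k_on",
                    "k_off", "k_mp", "k_mn", "k_bp", "k_bn")))

# A small, quick system (scaled counts) for structural engine tests.
small_scenario <- function(R0 = 2000, A_s = 100,
                           rates = rate_constants(), t_end = 5) {
  labeling_scenario(R0 = R0, A_s = A_s, rates = rates, t_end = t_end)
}

state_unlist <- function(s)
  c(s$A_s, s$A_b, s$A_c, s$A_o, s$AR, s$ARR, s$R)

storage.mode(oracle_delta) <- "integer"
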