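test_that("the ten channels reproduce the change matrix column for column", {
  ch <- build_channels(rate_constants())
  expect_named(ch, colnames(oracle_delta))
  for (nm in names(ch))
    expect_equal(ch[[nm]]$delta, oracle_delta[, nm],
                 ignore_attr = FALSE, label = nm)
  expect_identical(channel_delta_matrix(), oracle_delta)
  # spot checks called out explicitly
  expect_equal(ch[["k_mp"]]$delta[c("A_o", "AR", "R")],
               c(A_o = -1L, AR = 1L, R = -1L))
  expect_equal(ch[["k_bn"]]$delta[c("AR", "ARR", "R")],
               c(AR = 1L, ARR = -1L, R = 1L))
})

test_that("every channel conserves receptors and moves antibody only via the source", {
  d <- channel_delta_matrix()
  # receptor bookkeeping: dR + dAR + 2 dARR = 0 for every channel
  expect_equal(unname(d["R", ] + d["AR", ] + 2 * d["ARR", ]),
               rep(0L, 10))
  # net tracked-antibody flux: +1 for the source inflow, -1 for the
  # source outflow, 0 for every internal channel
  flux <- colSums(d[c("A_b", "A_c", "A_o", "AR", "ARR"), ])
  expect_equal(unname(flux), c(1L, -1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L))
})

test_that("propensities match the brute-force rate-law oracle on random states", {
  set.seed(42)
  r <- rate_constants()
  ch <- build_channels(r)
  for (i in 1:1000) {
    s <- random_state()
    expect_equal(unname(propensities(s, ch)), oracle_propensities(s, r))
  }
})

test_that("propensity values follow the rate laws in hand-checked cases", {
  r <- rate_constants(k_mp = 1e-4)
  ch <- build_channels(r)
  s <- system_state(R = 100000, A_o = 6000, A_s = 0)
  expect_equal(propensities(s, ch)[["k_mp"]], 6e4)
  # fresh labeling state: only the source channel is active
  s0 <- system_state(R = 0, A_s = 3000)
  a <- propensities(s0, ch)
  expect_equal(a[["k_2p"]], 3000 * 32 / 9)  # A_s * D/h_t^2
  expect_equal(unname(a[-1]), rep(0, 9))
})

test_that("applying a channel adds its column exactly and rejects negative counts", {
  ch <- build_channels(rate_constants())
  s <- system_state(A_o = 5, R = 10, A_s = 0)
  s2 <- apply_channel(s, ch[["k_mp"]])
  expect_equal(c(s2$A_o, s2$R, s2$AR), c(4, 9, 1))
  s3 <- system_state(AR = 3, ARR = 2, R = 0, A_s = 0)
  s4 <- apply_channel(s3, ch[["k_bn"]])
  expect_equal(c(s4$AR, s4$ARR, s4$R), c(4, 1, 1))
  # forward/backward hops are exact inverses
  s5 <- apply_channel(apply_channel(system_state(A_b = 7, A_s = 1),
                                    ch[["k_1p"]]), ch[["k_1n"]])
  expect_equal(state_unlist(s5), state_unlist(system_state(A_b = 7, A_s = 1)))
  expect_error(apply_channel(system_state(A_o = 0, R = 1, A_s = 0),
                             ch[["k_mp"]]),
               class = "mabsim_invariant_error")
})
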