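test_that("waiting times follow the exponential closed form", {
  expect_equal(sample_waiting_time(2, exp(-1)), 0.5)
  expect_equal(sample_waiting_time(10, 1), 0)
  expect_error(sample_waiting_time(0, 0.5), class = "mabsim_absorbing")
  expect_error(sample_waiting_time(1, 0), class = "mabsim_parameter_error")
  # Monte-Carlo mean: 1e6 exponential draws at rate 1e5
  set.seed(42)
  tau <- sample_waiting_time(1e5, runif(1e6))
  expect_lt(abs(mean(tau) - 1e-5) / 1e-5, 0.005)
})

test_that("channel selection partitions (0,1) by propensity fractions", {
  expect_identical(select_channel(c(1, 1, rep(0, 8)), 0.25), 1L)
  expect_identical(select_channel(c(1, 1, rep(0, 8)), 0.75), 2L)
  # single enabled channel wins for any u2
  expect_identical(select_channel(c(0, 0, 5, 0), c(0, 0.37, 0.999)),
                   c(3L, 3L, 3L))
  expect_error(select_channel(rep(0, 10), 0.5), class = "mabsim_absorbing")
  # multinomial frequencies for alpha = (1, 2, 3): 1e6 draws within 3 SD
  set.seed(42)
  j <- select_channel(c(1, 2, 3), runif(1e6))
  p <- c(1, 2, 3) / 6
  freq <- tabulate(j, 3) / 1e6
  expect_true(all(abs(freq - p) < 3 * sqrt(p * (1 - p) / 1e6)))
})

test_that("a single step applies one reaction and advances time", {
  ch <- build_channels(rate_constants())
  s0 <- system_state(R = 0, A_s = 3000)  # only the source channel enabled
  st <- ssa_step(s0, ch, u1 = 0.5, u2 = 0.5)
  expect_equal(st$state$A_b, 1)
  expect_equal(st$event$channel, 1L)
  expect_equal(st$state$t, log(2) / (3000 * 32 / 9))
  expect_error(ssa_step(system_state(R = 5, A_s = 0), ch),
               class = "mabsim_absorbing")
})

test_that("fixed seeds reproduce trajectories exactly, across both engines", {
  sc <- small_scenario(R0 = 50, A_s = 20, t_end = 0.3)
  a <- run_scenario(sc, seed = 7)
  b <- run_scenario(sc, seed = 7)
  expect_identical(a$counts, b$counts)
  expect_identical(a$event_count, b$event_count)
  r <- run_scenario(sc, seed = 7, engine = "R")
  expect_identical(a$counts, r$counts)
  expect_equal(a$final_state$t, r$final_state$t)
  expect_equal(state_unlist(a$final_state), state_unlist(r$final_state))
})

test_that("event-by-event replay conserves receptors and never goes negative", {
  sc <- small_scenario(t_end = 2)
  pol <- recording_policy(c(1, 2), keep_event_log = TRUE)
  tr <- run_scenario(sc, policy = pol, seed = 11)
  log <- tr$event_log
  expect_gt(nrow(log), 1000)
  expect_true(all(log$tau > 0))
  expect_true(all(diff(log$t) > 0))
  expect_equal(log$t, cumsum(log$tau), tolerance = 1e-9)
  s0 <- vapply(c("A_b", "A_c", "A_o", "AR", "ARR", "R"),
               function(nm) sc$initial[[nm]], numeric(1))
  total0 <- s0[["R"]] + s0[["AR"]] + 2 * s0[["ARR"]]
  # cumulative replay of the change-matrix columns, one row per prefix
  states <- t(apply(oracle_delta[, log$channel], 1, cumsum)) + s0
  expect_true(all(states >= 0))
  cons <- states["R", ] + states["AR", ] + 2 * states["ARR", ]
  expect_true(all(cons == total0))
  expect_equal(unname(states[, ncol(states)]),
               unname(state_unlist(tr$final_state)[-1]))
})

test_that("a frozen system records a constant trajectory with zero events", {
  r0 <- validate_rate_constants(setNames(rep(0, 10),
        c("k_2p", "k_2n", "k_1p", "k_1n", "k_on",
          "k_off", "k_mp", "k_mn", "k_bp", "k_bn")))
  tr <- ssa_run(system_state(R = 10, AR = 3, A_s = 5), r0, t_end = 2,
                seed = 1)
  expect_equal(tr$event_count, 0)
  expect_true(tr$absorbed)
  expect_true(all(tr$counts[, "AR"] == 3))
  expect_true(all(tr$counts[, "R"] == 10))
})

test_that("the event cap truncates with a warning and flags the trajectory", {
  sc <- small_scenario(t_end = 5)
  pol <- recording_policy(5, max_events = 100)
  expect_warning(tr <- run_scenario(sc, policy = pol, seed = 3),
                 "event cap")
  expect_true(tr$truncated)
  expect_equal(tr$event_count, 100)
})

test_that("with binding off the layers equilibrate to the source count and A_o to twice the cell layer", {
  r0 <- rate_constants(k_mp = 0, k_mn = 0, k_bp = 0, k_bn = 0)
  fins <- vapply(1:10, function(s) {
    f <- ssa_run(system_state(R = 0, A_s = 3000), r0, t_end = 40,
                 policy = recording_policy(40), seed = 100 + s)$final_state
    c(f$A_b, f$A_c, f$A_o)
  }, numeric(3))
  m <- rowMeans(fins)
  se <- apply(fins, 1, sd) / sqrt(ncol(fins))
  expect_lt(abs(m[1] - 3000), 3 * se[1])   # boundary layer = A_s
  expect_lt(abs(m[2] - 3000), 3 * se[2])   # cell layer = A_s
  # adsorbed/cell-layer ratio -> k_on / k_off = 2
  expect_equal(m[3] / m[2], 2, tolerance = 0.05)
})
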