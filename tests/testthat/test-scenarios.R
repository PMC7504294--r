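test_that("the labeling scenario starts from a bare cell in a pinned source", {
  sc <- labeling_scenario()
  expect_equal(sc$initial$R, 100000)
  expect_equal(sc$initial$A_s, 3000)
  expect_equal(sc$source_value, 3000)
  expect_equal(state_unlist(sc$initial)[2:6], rep(0, 5))  # A_b..ARR
  expect_equal(sc$t_end, 30)
  expect_error(labeling_scenario(R0 = -5), class = "mabsim_parameter_error")
})

test_that("without receptors no complexes ever form", {
  sc <- labeling_scenario(R0 = 0, A_s = 200, t_end = 2)
  tr <- run_scenario(sc, seed = 4)
  expect_true(all(tr$counts[, "AR"] == 0))
  expect_true(all(tr$counts[, "ARR"] == 0))
  expect_gt(tr$event_count, 0)  # transport still churns
})

test_that("the labeling run saturates: R reaches 0 and bound receptors equal the initial pool exactly", {
  tr <- run_scenario(labeling_scenario(t_end = 60), seed = 42)
  fin <- tr$final_state
  expect_equal(fin$R, 0)
  expect_identical(bound_receptors(fin), 100000)
  # at saturation the adsorption balance holds: A_o ~ 2 A_c, layers ~ A_s
  df <- as.data.frame(tr)
  late <- df[df$t >= 50, ]
  expect_equal(mean(late$A_o) / mean(late$A_c), 2, tolerance = 0.05)
  expect_equal(mean(late$A_b), 3000, tolerance = 0.03)
  expect_equal(mean(late$A_c), 3000, tolerance = 0.03)
})

test_that("the wash scenario continues from the labeled state with an empty source", {
  lab <- run_scenario(small_scenario(t_end = 5), seed = 9)
  pl <- post_labeling_scenario(lab$final_state, rate_constants(),
                               t_end = 100)
  expect_equal(pl$initial$A_s, 0)
  expect_equal(pl$source_value, 0)
  expect_equal(pl$initial$t, 0)
  expect_equal(pl$initial$AR, lab$final_state$AR)
  tr <- run_scenario(pl, seed = 10)
  # with no source, tracked antibody can only decrease or bind
  expect_lte(sum(state_unlist(tr$final_state)[-1][1:5]),
             sum(state_unlist(pl$initial)[-1][1:5]))
})

test_that("bound antibody is quasi-conserved for two hours after the wash", {
  lab <- run_scenario(labeling_scenario(t_end = 60), seed = 42)
  pl <- post_labeling_scenario(lab$final_state)
  tr <- run_scenario(pl, policy = recording_policy(log_time_grid(1, 7200)),
                     seed = 43)
  df <- as.data.frame(tr)
  abc0 <- abc(pl$initial)
  abc_2h <- df$ABC[nrow(df)]
  expect_gt(abc_2h / abc0, 0.9)
  # AR and ARR keep exchanging while their sum barely moves
  expect_gt(tr$event_count, 1000)
})

test_that("the k_off scan moves equilibrium ABC by at most ~1.5% and tightens with a longer run", {
  scan30 <- koff_sensitivity_scan(t_end = 30, seed = 42)
  expect_equal(scan30$multiplier, c(0.4, 0.5, 0.6))
  expect_lte(scan30$rel_spread[1], 0.015)
  scan40 <- koff_sensitivity_scan(t_end = 40, seed = 42)
  expect_lte(scan40$rel_spread[1], scan30$rel_spread[1])
})
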