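test_that("interval histograms bin waiting times logarithmically", {
  log <- data.frame(t = c(0.1, 0.2, 5), channel = c(1L, 2L, 8L),
                    tau = c(1e-6, 1e-6, 2))
  h <- interval_histogram(log, bins_per_decade = 1)
  expect_s3_class(h, "interval_histogram")
  expect_true(all(diff(h$edges) > 0))
  expect_equal(sum(h$counts), 3)
  decade_of <- function(x) findInterval(x, h$edges)
  expect_equal(h$counts[decade_of(1.5e-6)], 2)  # both microsecond taus
  expect_equal(h$counts[decade_of(2)], 1)
  # time-window filtering
  h_early <- interval_histogram(log, 1, time_window = c(0, 1))
  expect_equal(h_early$n_events, 2)
  expect_error(interval_histogram(log[0, ]),
               class = "mabsim_parameter_error")
  expect_error(interval_histogram(NULL), class = "mabsim_parameter_error")
})

test_that("labeling inter-event intervals span sub-nanoseconds to milliseconds", {
  pol <- recording_policy(c(1, 2), keep_event_log = TRUE)
  tr <- ssa_run(system_state(), rate_constants(), t_end = 2,
                policy = pol, seed = 42)
  tau <- tr$event_log$tau
  expect_gt(min(tau), 1e-12)
  expect_lt(max(tau), 1e-2)
  h <- interval_histogram(tr$event_log, bins_per_decade = 1,
                          by_channel = TRUE)
  expect_equal(sum(h$counts), nrow(tr$event_log))
  expect_equal(sum(h$channel_counts), nrow(tr$event_log))
})

test_that("the wash run shifts the interval distribution from microseconds to seconds", {
  lab <- run_scenario(labeling_scenario(t_end = 60), seed = 42)
  pl <- post_labeling_scenario(lab$final_state)
  tr <- run_scenario(pl, policy = recording_policy(
    log_time_grid(1e-6, 3e4), keep_event_log = TRUE), seed = 43)
  early <- interval_histogram(tr$event_log, 1, time_window = c(0, 0.5))
  late <- interval_histogram(tr$event_log, 1, time_window = c(2e4, 3e4))
  expect_lt(modal_interval(early), 1e-3)     # desorption/diffusion churn
  expect_gt(modal_interval(late), 0.05)      # slow dissociation era
  # mean late interval is of order seconds ("around 2 s")
  mean_late <- 1e4 / late$n_events
  expect_gt(mean_late, 0.4)
  expect_lt(mean_late, 10)
})

test_that("equilibration detection finds the earliest settled snapshot", {
  # constant trace settles immediately
  const <- data.frame(t = 0:10, x = rep(4, 11))
  expect_equal(detect_equilibrium(const, "x", window = 3), 0)
  # hand-built relaxation: within 5% of the final value from t = 3 on
  tr <- data.frame(t = 0:10, x = c(5, 3, 2, rep(1, 8)))
  expect_equal(detect_equilibrium(tr, "x", window = 3, rel_tol = 0.05), 3)
  # a diverging trace never settles
  div <- data.frame(t = 0:10, x = 2^(0:10))
  expect_true(is.na(detect_equilibrium(div, "x", window = 3)))
  # multiple fields: the slowest one governs
  two <- data.frame(t = 0:10, x = c(5, rep(1, 10)),
                    y = c(5, 5, 5, 5, rep(1, 7)))
  expect_equal(detect_equilibrium(two, c("x", "y"), window = 3), 4)
  expect_error(detect_equilibrium(tr, "x", window = 50),
               class = "mabsim_parameter_error")
})

test_that("the labeling transport layers settle on the tens-of-seconds scale", {
  tr <- run_scenario(labeling_scenario(t_end = 40), seed = 42)
  t_eq <- detect_equilibrium(tr, c("A_b", "A_c"), window = 5,
                             rel_tol = 0.05)
  expect_false(is.na(t_eq))
  expect_gt(t_eq, 15)
  expect_lt(t_eq, 35)
})
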