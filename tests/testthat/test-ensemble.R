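test_that("CV% is 100 SD/mean with the sample SD", {
  expect_equal(cv_percent(c(10, 10, 10)), 0)
  expect_equal(cv_percent(c(90, 100, 110)), 10)  # SD = 10, by hand
  x <- c(3, 9, 14, 2, 30)
  expect_equal(cv_percent(5 * x), cv_percent(x))  # scale invariance
  expect_error(cv_percent(7), class = "mabsim_parameter_error")
  expect_error(cv_percent(c(-1, 1)), class = "mabsim_parameter_error")
})

test_that("parameter samplers reproduce their distributions", {
  set.seed(42)
  expect_equal(unique(mabsim:::sample_dist(dist_fixed(1e5), 50)), 1e5)
  x <- mabsim:::sample_dist(dist_normal(1e5, 6), 1e4)
  expect_lt(abs(mean(x) - 1e5), 3 * 6000 / sqrt(1e4))
  expect_lt(abs(sd(x) - 6000) / 6000, 0.05)
  y <- mabsim:::sample_dist(dist_two_point(1e-7, 1e-6, 0.5), 1e4)
  expect_setequal(unique(y), c(1e-7, 1e-6))
  expect_lt(abs(mean(y == 1e-6) - 0.5), 3 * 0.5 / sqrt(1e4))
  z <- log10(mabsim:::sample_dist(dist_log10_normal(-6.5, 0.5), 1e4))
  expect_lt(abs(mean(z) + 6.5), 3 * 0.5 / sqrt(1e4))
  expect_lt(abs(sd(z) - 0.5) / 0.5, 0.05)
})

test_that("cell parameters are a pure function of the spec", {
  spec <- ensemble_spec(n_cells = 10, receptor_dist = dist_normal(1e5, 6),
                        kbp_dist = dist_two_point(1e-7, 1e-6),
                        master_seed = 5)
  a <- sample_cell_parameters(spec)
  b <- sample_cell_parameters(spec)
  expect_identical(a, b)
  expect_true(all(a$R_init == round(a$R_init) & a$R_init >= 1))
  expect_true(all(a$seed >= 1 & a$seed < 2^31))
  expect_equal(anyDuplicated(a$seed), 0)
})

test_that("ensembles are reproducible and respect per-cell receptor conservation exactly", {
  spec <- ensemble_spec(n_cells = 4, receptor_dist = dist_normal(2000, 6),
                        A_s = 100, t_end = 10, master_seed = 8)
  res <- run_ensemble(spec)
  res2 <- run_ensemble(spec)
  expect_identical(res$cells, res2$cells)
  with(res$cells, expect_identical(bound_receptors + R_free, R_init))
  expect_identical(res$cells$ABC, res$cells$AR + res$cells$ARR)
  s <- res$summary
  expect_equal(rownames(s), c("mean", "SD", "CV%"))
  expect_equal(s["CV%", "TotalA"],
               100 * s["SD", "TotalA"] / s["mean", "TotalA"])
})

test_that("under fixed conditions the conservation constraint anticorrelates AR and ARR", {
  res <- run_ensemble(preset_ensemble("table4", n_cells = 10,
                                      master_seed = 12))
  s <- res$summary
  # every run saturates, so AR and ARR trade off under AR + 2 ARR = R0
  expect_lt(s["CV%", "TotalA"], s["CV%", "AR"])
  expect_lt(s["CV%", "TotalA"], s["CV%", "ARR"])
  expect_equal(cor(res$cells$AR, res$cells$ARR), -1)
})

test_that("valence limits bracket the bound count: all monovalent doubles all bivalent", {
  mono <- ssa_run(system_state(), rate_constants(k_bp = 0), t_end = 60,
                  policy = recording_policy(60), seed = 21)$final_state
  expect_equal(mono$R, 0)
  expect_equal(abc(mono), 100000)   # ABC -> R_init, exactly at saturation
  expect_equal(mono$ARR, 0)
  biv <- ssa_run(system_state(), preset_rates("arr_dominant"), t_end = 60,
                 policy = recording_policy(60), seed = 22)$final_state
  expect_equal(abc(biv) / 100000, 0.5, tolerance = 0.06)
})

test_that("CV% of total bound antibody grows as heterogeneity sources are added", {
  n <- 12
  cv <- vapply(c("table4", "table5_similar", "table7"), function(p)
    run_ensemble(preset_ensemble(p, n_cells = n, master_seed = 31))$
      summary["CV%", "TotalA"], numeric(1))
  expect_lt(cv[["table4"]], cv[["table5_similar"]])
  expect_lt(cv[["table5_similar"]], cv[["table7"]])
})

test_that("ABC tracks the receptor count linearly when only receptors vary", {
  res <- run_ensemble(preset_ensemble("table5_similar", n_cells = 15,
                                      master_seed = 17))
  tab <- abc_vs_receptors_table(res)
  expect_named(tab, c("R_init", "ABC"))
  expect_gt(cor(tab$R_init, tab$ABC), 0.95)
  expect_error(abc_vs_receptors_table(data.frame()),
               class = "mabsim_parameter_error")
})
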