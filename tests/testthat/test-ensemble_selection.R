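test_that("ensemble averaging equals a brute-force mean", {
  set.seed(23)
  n <- 25
  pool <- toy_pool(stats::rnorm(n, 52, 2), stats::rnorm(n, 4.3, 0.3))
  rs <- toy_restraints()
  avg <- ensemble_average_shifts(pool$models, rs)
  # independent summation oracle
  ca <- 0; ha <- 0
  for (m in pool$models) {
    ca <- ca + m$predicted_shifts[["1:CA"]]
    ha <- ha + m$predicted_shifts[["1:HA"]]
  }
  expect_equal(avg[["1:CA"]], ca / n, tolerance = 1e-12)
  expect_equal(avg[["1:HA"]], ha / n, tolerance = 1e-12)

  one <- ensemble_average_shifts(pool$models[1], rs)
  expect_equal(one, pool$models[[1]]$predicted_shifts[names(one)])

  two <- toy_pool(c(1, 3), c(1, 3))
  expect_equal(ensemble_average_shifts(two$models, rs)[["1:CA"]], 2)
})

test_that("missing predictions are reported by model and atom", {
  pool <- toy_pool(c(52, 53), c(4.2, 4.4))
  pool$models[[2]]$predicted_shifts <- c("1:CA" = 53)
  expect_error(ensemble_average_shifts(pool$models, toy_restraints()),
               "model 2.*1:HA")
})

test_that("cs_rmsd applies carbon scaling to residuals only", {
  tb <- shift_table(1, "ALA", "CO", 170)
  rs <- select_restraints(tb, "CO")
  expect_equal(cs_rmsd(c("1:CO" = 174), rs, carbon_scale = 4), 1.0)
  expect_equal(cs_rmsd(c("1:CO" = 170), rs), 0.0)

  tb <- shift_table(1, "ALA", "HA", 4)
  rs <- select_restraints(tb, "HA")
  expect_equal(cs_rmsd(c("1:HA" = 5), rs, carbon_scale = 4), 1.0)

  expect_error(cs_rmsd(numeric(), toy_restraints()[0, ]), "empty")
})

test_that("greedy selection matches exhaustive enumeration on a small pool", {
  set.seed(29)
  pool <- toy_pool(stats::rnorm(8, 52, 2), stats::rnorm(8, 4.3, 0.3))
  rs <- toy_restraints()
  oracle <- exhaustive_best_rmsd(pool, rs, 2, 3)
  cfg <- selection_config(min_size = 2, max_size = 3, cycles = 50000,
                          seed = 101)
  ens <- select_ensemble(pool, rs, cfg)
  expect_equal(ens$rmsd, oracle, tolerance = 1e-10)
  expect_true(length(ens$member_ids) %in% 2:3)
})

test_that("degenerate pools and bound violations behave as specified", {
  pool <- toy_pool(rep(52, 6), rep(4.3, 6))
  rs <- toy_restraints(ca = 51, ha = 4.0)
  cfg <- selection_config(min_size = 2, max_size = 4, cycles = 2000, seed = 5)
  ens <- select_ensemble(pool, rs, cfg)
  single <- cs_rmsd(pool$models[[1]]$predicted_shifts, rs)
  expect_equal(ens$rmsd, single, tolerance = 1e-12)

  expect_error(select_ensemble(pool, rs,
                               selection_config(min_size = 10, max_size = 12,
                                                cycles = 10)),
               "smaller than min_size")
})

test_that("greedy acceptance never worsens and the trace is monotone", {
  set.seed(31)
  pool <- toy_pool(stats::rnorm(30, 52, 2), stats::rnorm(30, 4.3, 0.3))
  rs <- toy_restraints()
  cfg <- selection_config(min_size = 3, max_size = 8, cycles = 20000,
                          seed = 77, trace_every = 100)
  ens <- select_ensemble(pool, rs, cfg)
  expect_lte(ens$rmsd, ens$initial_rmsd)
  expect_true(all(diff(ens$trace$rmsd) <= 1e-12))
  # size bounds hold at every logged cycle
  expect_true(all(ens$trace$size >= 3 & ens$trace$size <= 8))
})

test_that("identical seeds reproduce member sets and traces exactly", {
  set.seed(37)
  pool <- toy_pool(stats::rnorm(20, 52, 2), stats::rnorm(20, 4.3, 0.3))
  rs <- toy_restraints()
  cfg <- selection_config(min_size = 3, max_size = 6, cycles = 10000,
                          seed = 42)
  a <- select_ensemble(pool, rs, cfg)
  b <- select_ensemble(pool, rs, cfg)
  expect_identical(a$member_ids, b$member_ids)
  expect_identical(a$trace, b$trace)
  expect_identical(a$rmsd, b$rmsd)
})

test_that("reported rmsd equals a from-scratch recomputation", {
  set.seed(43)
  pool <- toy_pool(stats::rnorm(15, 52, 2), stats::rnorm(15, 4.3, 0.3))
  rs <- toy_restraints()
  ens <- select_ensemble(pool, rs,
                         selection_config(min_size = 3, max_size = 5,
                                          cycles = 5000, seed = 9))
  members <- ensemble_models(pool, ens)
  again <- cs_rmsd(ensemble_average_shifts(members, rs), rs, 4)
  expect_equal(ens$rmsd, again, tolerance = 1e-10)
})

test_that("metropolis mode runs and still returns the best-seen ensemble", {
  set.seed(47)
  pool <- toy_pool(stats::rnorm(12, 52, 2), stats::rnorm(12, 4.3, 0.3))
  rs <- toy_restraints()
  cfg <- selection_config(min_size = 2, max_size = 4, cycles = 20000,
                          seed = 3, acceptance_rule = "metropolis",
                          temperature = 0.05)
  ens <- select_ensemble(pool, rs, cfg)
  oracle <- exhaustive_best_rmsd(pool, rs, 2, 4)
  expect_gte(ens$rmsd, oracle - 1e-12)
  members <- ensemble_models(pool, ens)
  expect_equal(cs_rmsd(ensemble_average_shifts(members, rs), rs),
               ens$rmsd, tolerance = 1e-10)
})

test_that("selection config validates its bounds", {
  expect_error(selection_config(min_size = 5, max_size = 2), "min_size")
  expect_error(selection_config(carbon_scale = 0), "carbon_scale")
  expect_error(selection_config(acceptance_rule = "metropolis"), "temperature")
})
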