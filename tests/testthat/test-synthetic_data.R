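test_that("a pure-helix recipe with zero noise gives exact torsions", {
  rec <- pool_recipe(20, sequence = "GSSFL",
                     class_mix = c(helix = 1, ppii = 0, coil = 0),
                     torsion_sd = 0, shift_sd = 0, seed = 2)
  pool <- gen_pool(rec)
  for (m in pool$models) {
    expect_equal(m$torsions$phi, rep(-57, 5))
    expect_equal(m$torsions$psi, rep(-47, 5))
    expect_equal(m$ss_class, "helix")
  }
})

test_that("class counts fall inside binomial 99% bounds", {
  rec <- pool_recipe(2000, sequence = "GSSFL",
                     class_mix = c(helix = 0.5, ppii = 0.3, coil = 0.2),
                     seed = 19)
  pool <- gen_pool(rec)
  counts <- table(vapply(pool$models, `[[`, "", "ss_class"))
  for (cl in c("helix", "ppii", "coil")) {
    p <- rec$class_mix[[cl]]
    bounds <- stats::qbinom(c(0.005, 0.995), 2000, p)
    expect_gte(counts[[cl]], bounds[1])
    expect_lte(counts[[cl]], bounds[2])
  }
})

test_that("pools are byte-identical across runs with the same seed", {
  rec <- pool_recipe(10, sequence = "GSSFL", seed = 23)
  p1 <- gen_pool(rec); p2 <- gen_pool(rec)
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  e1 <- withr::local_tempfile(); e2 <- withr::local_tempfile()
  s1 <- withr::local_tempfile(fileext = ".csv")
  s2 <- withr::local_tempfile(fileext = ".csv")
  write_pool(p1, f1, e1, s1); write_pool(p2, f2, e2, s2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(s1), readLines(s2))

  # anchor z placement lands inside the requested range
  z <- vapply(p1$models, function(m)
    m$coords$z[m$coords$residue == 3 & m$coords$atom == "CA"], numeric(1))
  expect_true(all(z >= rec$z_range[1] & z <= rec$z_range[2]))
})

test_that("generated pools satisfy the conformer invariants", {
  rec <- pool_recipe(30, seed = 29)
  pool <- gen_pool(rec)
  ids <- vapply(pool$models, `[[`, integer(1), "model_id")
  expect_false(anyDuplicated(ids) > 0)
  n <- nchar(pool$sequence)
  for (m in pool$models[1:5]) {
    expect_equal(nrow(m$torsions), n)
    tor <- measure_torsions(m$coords)
    expect_equal(tor$phi[-1], m$torsions$phi[-1], tolerance = 1e-3)
    expect_true(all(abs(m$torsions$phi) <= 180))
  }
})

test_that("synthetic experimental shifts are consistent with their subset", {
  rec <- pool_recipe(30, sequence = "ASSFL",
                     class_mix = c(helix = 1, ppii = 0, coil = 0),
                     shift_sd = 0.2, seed = 31)
  pool <- gen_pool(rec)
  subset <- pool$models[1:20]

  # sigma = 0, subset of 1: equals that model's predictions
  tb <- gen_experimental_shifts(subset[1], "ASSFL", noise_sd = 0, seed = 1)
  rs <- select_restraints(tb, c("CO", "CA", "CB", "HA"))
  expect_equal(cs_rmsd(ensemble_average_shifts(subset[1], rs), rs), 0)

  # sigma = 0, subset of 20: zero RMSD against the subset average
  tb <- gen_experimental_shifts(subset, "ASSFL", noise_sd = 0, seed = 1)
  rs <- select_restraints(tb, c("CO", "CA", "CB", "HA"))
  expect_equal(cs_rmsd(ensemble_average_shifts(subset, rs), rs), 0,
               tolerance = 1e-12)

  # CLT bound on the noise: mean deviation per atom ~ N(0, sigma/sqrt(R))
  sigma <- 0.1; R <- 200
  devs <- vapply(seq_len(R), function(s) {
    tb <- gen_experimental_shifts(subset, "ASSFL", noise_sd = sigma, seed = s)
    tb$shift_ppm[1]
  }, numeric(1))
  tb0 <- gen_experimental_shifts(subset, "ASSFL", noise_sd = 0, seed = 1)
  expect_lt(abs(mean(devs) - tb0$shift_ppm[1]), 3 * sigma / sqrt(R))
})

test_that("binding and buildup generators are deterministic and invertible", {
  d1 <- gen_binding_data(seed = 7); d2 <- gen_binding_data(seed = 7)
  expect_identical(d1, d2)
  # L = 0 gives f = 0 before noise
  d0 <- gen_binding_data(noise_sd = 0, seed = 7)
  expect_equal(d0$I_pellet[d0$lipid_total_mM == 0], c(0, 0))

  # noiseless round trip through correction and step fitting
  omega <- 25
  t <- c(0.00001, 0.001, 0.005, 0.01, 0.025, 0.05, 0.1, 0.2, 0.4, 0.9)
  for (n in c(1, 3, 5, 8)) {
    curve <- gen_buildup(n, omega, t, noise_sd = 0, T1 = 0.6, seed = 1,
                         n_sites = 13L)
    norm <- correct_and_normalize(curve)
    spec <- lattice_spec(n_sites = 13, omega = omega)
    expect_equal(fit_step_distance(norm, spec, n_max = 10)$n_steps, n)
    # T1 decay is exactly inverted
    clean <- gen_buildup(n, omega, t, noise_sd = 0, T1 = Inf, seed = 1,
                         n_sites = 13L)
    clean_norm <- correct_and_normalize(clean)
    expect_equal(norm$intensities, clean_norm$intensities, tolerance = 1e-9)
  }
})

test_that("invalid recipes are rejected", {
  expect_error(pool_recipe(0), "n_models")
  expect_error(pool_recipe(5, class_mix = c(helix = 0.5, ppii = 0.2,
                                            coil = 0.2)), "sum to 1")
})
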