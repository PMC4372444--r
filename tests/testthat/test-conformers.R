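test_that("backbone construction uses ideal geometry", {
  bb <- build_backbone(c(-60, -60), c(-40, -40), c(180, 180), "AA")
  for (r in 1:2) {
    n <- unlist(bb[bb$residue == r & bb$atom == "N", c("x", "y", "z")])
    ca <- unlist(bb[bb$residue == r & bb$atom == "CA", c("x", "y", "z")])
    expect_equal(sqrt(sum((n - ca)^2)), 1.458, tolerance = 1e-9)
  }
  expect_equal(unlist(bb[1, c("x", "y", "z")]), c(x = 0, y = 0, z = 0))
})

test_that("helical and extended torsions give the expected CA geometry", {
  # ideal alpha-helix: CA(i)-CA(i+4) about 6.2 A
  bb <- build_backbone(rep(-57, 10), rep(-47, 10), rep(180, 10),
                       strrep("A", 10))
  ca <- as.matrix(bb[bb$atom == "CA", c("x", "y", "z")])
  expect_equal(sqrt(sum((ca[1, ] - ca[5, ])^2)), 6.2, tolerance = 0.3 / 6.2)
  # trans-extended chain: consecutive CA-CA about 3.8 A
  bb <- build_backbone(rep(180, 5), rep(180, 5), rep(180, 5), "AAAAA")
  ca <- as.matrix(bb[bb$atom == "CA", c("x", "y", "z")])
  d <- sqrt(rowSums((ca[-1, ] - ca[-5, ])^2))
  expect_true(all(abs(d - 3.8) < 0.1))
})

test_that("torsion re-measurement recovers the inputs", {
  set.seed(7)
  for (rep_i in 1:5) {
    n <- 8
    phi <- stats::runif(n, -175, 175)
    psi <- stats::runif(n, -175, 175)
    omega <- stats::runif(n, -175, 175)
    bb <- build_backbone(phi, psi, omega, strrep("A", n))
    tor <- measure_torsions(bb)
    expect_equal(tor$phi[-1], phi[-1], tolerance = 1e-3)
    expect_equal(tor$psi[-n], psi[-n], tolerance = 1e-3)
    expect_equal(tor$omega[-n], omega[-n], tolerance = 1e-3)
  }
})

test_that("non-finite and out-of-range torsions are rejected", {
  expect_error(build_backbone(c(NaN, 0), c(0, 0), c(180, 180), "AA"),
               "non-finite")
  expect_error(build_backbone(c(181, 0), c(0, 0), c(180, 180), "AA"),
               "-180, 180")
})

make_z_pool <- function(z_values) {
  # minimal 3-residue models whose residue-3 CA z is set directly
  models <- lapply(seq_along(z_values), function(i) {
    bb <- build_backbone(rep(180, 3), rep(180, 3), rep(180, 3), "GSS")
    z_anchor <- bb$z[bb$residue == 3 & bb$atom == "CA"]
    bb$z <- bb$z + (z_values[i] - z_anchor)
    conformer_model(i, data.frame(phi = rep(180, 3), psi = rep(180, 3),
                                  omega = rep(180, 3)), bb,
                    energy = i)
  })
  model_pool(models, "GSS", "z-test")
}

test_that("membrane slab filter keeps exactly the in-slab models", {
  cfg <- filter_config(anchor_residue = 3, slab_zmin = 12, slab_zmax = 18)
  pool <- make_z_pool(c(15, 0, -14, 20, 12, 18))
  kept <- filter_membrane_contact(pool, cfg)
  expect_equal(vapply(kept$models, `[[`, integer(1), "model_id"),
               c(1L, 3L, 5L, 6L))

  # exhaustive oracle on a random pool
  set.seed(11)
  z <- stats::runif(300, 0, 30)
  pool <- make_z_pool(z)
  kept <- filter_membrane_contact(pool, cfg)
  expect_equal(length(kept$models), sum(z >= 12 & z <= 18))
  expect_equal(attr(kept, "n_removed"), sum(!(z >= 12 & z <= 18)))
})

test_that("receptor distance filter matches an all-pairs brute-force scan", {
  set.seed(13)
  pool <- make_z_pool(stats::runif(40, 0, 30))
  receptor <- matrix(stats::rnorm(30 * 3, sd = 8), ncol = 3,
                     dimnames = list(NULL, c("x", "y", "z")))
  cfg <- filter_config(receptor_min_distance = 5)
  kept <- filter_receptor_distance(pool, receptor, cfg)
  brute <- vapply(pool$models, function(m) {
    p <- as.matrix(m$coords[, c("x", "y", "z")])
    dmin <- Inf
    for (i in seq_len(nrow(p)))
      for (j in seq_len(nrow(receptor)))
        dmin <- min(dmin, sqrt(sum((p[i, ] - receptor[j, ])^2)))
    dmin >= 5
  }, logical(1))
  expect_equal(vapply(kept$models, `[[`, integer(1), "model_id"),
               which(brute))

  # a receptor block 50 A away removes nothing
  far <- cbind(x = 50 + stats::rnorm(5), y = stats::rnorm(5),
               z = stats::rnorm(5))
  expect_length(filter_receptor_distance(pool, far, cfg)$models, 40)

  expect_error(filter_receptor_distance(pool, receptor[0, , drop = FALSE], cfg),
               "empty")
})

test_that("energy percentile filter follows the sort-and-count oracle", {
  pool <- make_z_pool(rep(15, 100))
  for (i in seq_along(pool$models)) pool$models[[i]]$energy <- i
  cfg <- filter_config(energy_fraction = 0.10)
  kept <- filter_energy_percentile(pool, cfg)
  expect_equal(sort(vapply(kept$models, `[[`, numeric(1), "energy")), 1:10)

  # fraction 1 keeps everything
  expect_length(filter_energy_percentile(
    pool, filter_config(energy_fraction = 1))$models, 100)

  # all-equal energies: ties at the threshold are included
  for (i in seq_along(pool$models)) pool$models[[i]]$energy <- 3.14
  expect_length(filter_energy_percentile(pool, cfg)$models, 100)

  expect_error(filter_config(energy_fraction = 0), "\\(0, 1\\]")
})

test_that("filters commute as set operations", {
  set.seed(17)
  pool <- make_z_pool(stats::runif(60, 0, 30))
  for (i in seq_along(pool$models))
    pool$models[[i]]$energy <- stats::rnorm(1)
  receptor <- matrix(c(30, 0, 0, 0, 30, 0), 2, 3, byrow = TRUE,
                     dimnames = list(NULL, c("x", "y", "z")))
  cfg <- filter_config()
  ids <- function(p) sort(vapply(p$models, `[[`, integer(1), "model_id"))

  a <- filter_energy_percentile(
    filter_receptor_distance(filter_membrane_contact(pool, cfg), receptor, cfg),
    cfg, reference_pool = pool)
  b <- filter_receptor_distance(
    filter_membrane_contact(
      filter_energy_percentile(pool, cfg, reference_pool = pool), cfg),
    receptor, cfg)
  expect_equal(ids(a), ids(b))
  expect_true(all(ids(a) %in% ids(pool)))
})

test_that("pool PDB round trip preserves coordinates, energies and shifts", {
  rec <- pool_recipe(5, sequence = "GSSFL", seed = 3)
  pool <- gen_pool(rec)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  en <- withr::local_tempfile(fileext = ".tsv")
  sh <- withr::local_tempfile(fileext = ".csv")
  write_pool(pool, pdb, en, sh)
  pool2 <- read_pool(pdb, en, sh)

  expect_equal(length(pool2$models), 5)
  expect_equal(pool2$sequence, "GSSFL")
  for (k in 1:5) {
    m1 <- pool$models[[k]]; m2 <- pool2$models[[k]]
    expect_equal(m2$energy, m1$energy, tolerance = 1e-9)
    expect_equal(as.matrix(m2$coords[, c("x", "y", "z")]),
                 as.matrix(m1$coords[, c("x", "y", "z")]),
                 tolerance = 1e-3, ignore_attr = TRUE)
    expect_equal(m2$predicted_shifts[names(m1$predicted_shifts)],
                 m1$predicted_shifts, tolerance = 1e-9)
  }
})
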