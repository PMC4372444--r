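# Fixtures built in code; nothing here reads the network or large files.

table1_path <- function() {
  system.file("extdata", "ghrelin_shifts.csv", package = "memnmr",
              mustWork = TRUE)
}

table1 <- function() read_shift_table(table1_path())

rc_reference <- function() read_random_coil_reference()

# A tiny pool whose models carry hand-set predicted shifts over two
# restraints ("1:CA" carbon, "1:HA" proton); energies 1..n.
toy_pool <- function(preds_ca, preds_ha, sequence = "AA") {
  n <- length(preds_ca)
  models <- lapply(seq_len(n), function(i) {
    tor <- data.frame(phi = c(NA, -57), psi = c(-47, NA),
                      omega = c(180, NA))
    conformer_model(i, tor, coords = NULL, energy = i,
                    predicted_shifts = c("1:CA" = preds_ca[i],
                                         "1:HA" = preds_ha[i]))
  })
  model_pool(models, sequence, "toy")
}

toy_restraints <- function(ca = 52, ha = 4.3) {
  tb <- shift_table(c(1, 1), c("ALA", "ALA"), c("CA", "HA"), c(ca, ha))
  select_restraints(tb, c("CA", "HA"))
}

# Brute-force ensemble search over all subsets of sizes kmin..kmax.
exhaustive_best_rmsd <- function(pool, restraints, kmin, kmax,
                                 carbon_scale = 4) {
  n <- length(pool$models)
  best <- Inf
  for (k in kmin:kmax) {
    for (idx in utils::combn(n, k, simplify = FALSE)) {
      avg <- ensemble_average_shifts(pool$models[idx], restraints)
      r <- cs_rmsd(avg, restraints, carbon_scale)
      if (r < best) best <- r
    }
  }
  best
}
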