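#' Seeded synthetic-data generators
#'
#' The upstream tools of the real pipeline -- a de novo folding engine for
#' conformer pools, a chemical-shift predictor, the NMR spectrometer and
#' the binding assay -- are replaced here by small seeded generators, so
#' every downstream stage can be exercised and its parameter recovery
#' measured without any external software.  All generators are pure
#' functions of their arguments and seed.
#'
#' @name synthetic-data
NULL

#' Toy chemical-shift model
#'
#' Predicted shift = random-coil base value + secondary-structure-class
#' offset + Gaussian noise.  Deliberately linear, so the optimum of the
#' ensemble-selection objective is analytically known in recovery tests;
#' it makes no attempt at the realism of a trained predictor.
#'
#' @param reference A [read_random_coil_reference] table (default the
#'   packaged one).
#' @param offsets Named list of per-class named offset vectors in ppm.
#'   Default: helix CA +2.5 / CB -0.5 (standard secondary-shift
#'   magnitudes); PPII and coil 0.
#' @param noise_sd Per-prediction Gaussian noise in ppm.
#' @return A `toy_shift_model` list.
#' @export
toy_shift_model <- function(reference = read_random_coil_reference(),
                            offsets = list(helix = c(CA = 2.5, CB = -0.5),
                                           ppii = numeric(),
                                           coil = numeric()),
                            noise_sd = 0.3) {
  if (any(!is.finite(unlist(offsets)))) stopf("offsets must be finite")
  structure(list(reference = reference, offsets = offsets,
                 noise_sd = noise_sd),
            class = "toy_shift_model")
}

# Predict shifts for one model.  `ss_class` is the model's torsion class
# (helix/ppii/coil), applied to all residues; atoms without a random-coil
# reference entry (e.g. Gly CB) are skipped.
#' @noRd
toy_predict <- function(model3, ss_class, shift_model,
                        atoms = c("CO", "CA", "CB", "HA")) {
  off <- shift_model$offsets[[ss_class]]
  ref <- shift_model$reference
  out <- numeric(0)
  for (i in seq_along(model3)) {
    rn <- model3[i]
    for (at in atoms) {
      j <- which(ref$residue_name == rn & ref$atom == at)
      if (length(j) == 0) next
      base <- ref$shift_ppm[j[1]]
      delta <- if (at %in% names(off)) off[[at]] else 0
      val <- base + delta + stats::rnorm(1, 0, shift_model$noise_sd)
      out[restraint_key(i, at)] <- val
    }
  }
  out
}

#' Recipe for a synthetic conformer pool
#'
#' @param n_models Number of models (>= 1).
#' @param sequence One-letter sequence (default the 28-residue ghrelin
#'   sequence).
#' @param class_mix Named fractions over `helix`, `ppii`, `coil`, summing
#'   to 1.  Default 0.4/0.3/0.3: a folding run over a mostly disordered
#'   peptide samples all three basins broadly.
#' @param torsion_sd Gaussian torsion noise around the class centers, in
#'   degrees (default 10).
#' @param shift_sd Per-prediction shift noise in ppm (default 0.3).
#' @param anchor_residue Residue translated into the membrane frame
#'   (default 3).
#' @param z_range Uniform range (A) for the anchor CA |z| draw (default
#'   0-30, spanning bilayer center to bulk water).
#' @param energy_mean Named per-class mean energies (score units; lower =
#'   better).  Helix-rich models score best by default, emulating a
#'   scoring function that rewards compact hydrogen-bonded structure.
#' @param energy_sd Energy standard deviation (default 5).
#' @param seed RNG seed.
#' @return A `pool_recipe` list.
#' @export
pool_recipe <- function(n_models, sequence = GHRELIN_SEQUENCE,
                        class_mix = c(helix = 0.4, ppii = 0.3, coil = 0.3),
                        torsion_sd = 10, shift_sd = 0.3,
                        anchor_residue = 3L, z_range = c(0, 30),
                        energy_mean = c(helix = -20, ppii = -15, coil = -10),
                        energy_sd = 5, seed = 1L) {
  if (n_models < 1) stopf("n_models must be >= 1")
  if (abs(sum(class_mix) - 1) > 1e-9) stopf("class fractions must sum to 1")
  if (!all(c("helix", "ppii", "coil") %in% names(class_mix)))
    stopf("class_mix needs names helix, ppii, coil")
  structure(list(n_models = as.integer(n_models), sequence = sequence,
                 class_mix = class_mix, torsion_sd = torsion_sd,
                 shift_sd = shift_sd, anchor_residue = as.integer(anchor_residue),
                 z_range = z_range, energy_mean = energy_mean,
                 energy_sd = energy_sd, seed = seed),
            class = "pool_recipe")
}

# Torsion-basin centers (degrees)
.CLASS_CENTERS <- list(
  helix = c(phi = -57, psi = -47),
  ppii  = c(phi = -75, psi = 145)
)

#' @noRd
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Generate a synthetic conformer pool
#'
#' Each model is assigned a secondary-structure class by the recipe's mix;
#' its torsions are drawn around the class centers (helix phi/psi
#' -57/-47; PPII -75/145; coil broad) with Gaussian noise, the backbone is
#' built with ideal geometry and rigidly translated so the anchor CA sits
#' at a z drawn from the recipe's range, and an energy plus toy predicted
#' shifts are attached.  Identical recipes (including seed) give identical
#' pools.
#'
#' @param recipe A [pool_recipe].
#' @param shift_model A [toy_shift_model]; its `noise_sd` is overridden by
#'   the recipe's `shift_sd`.
#' @return A [model_pool]; each model carries its class in `$ss_class`.
#' @export
gen_pool <- function(recipe, shift_model = toy_shift_model()) {
  stopifnot(inherits(recipe, "pool_recipe"))
  set.seed(recipe$seed)
  shift_model$noise_sd <- recipe$shift_sd
  n <- nchar(recipe$sequence)
  res3 <- aa1to3(recipe$sequence)
  classes <- sample(names(recipe$class_mix), recipe$n_models, replace = TRUE,
                    prob = recipe$class_mix)
  models <- vector("list", recipe$n_models)
  for (k in seq_len(recipe$n_models)) {
    cl <- classes[k]
    if (cl == "coil") {
      phi <- stats::runif(n, -180, -40)
      psi <- stats::runif(n, -180, 180)
    } else {
      ctr <- .CLASS_CENTERS[[cl]]
      phi <- wrap180(stats::rnorm(n, ctr["phi"], recipe$torsion_sd))
      psi <- wrap180(stats::rnorm(n, ctr["psi"], recipe$torsion_sd))
    }
    omega <- rep(180, n)
    coords <- build_backbone(phi, psi, omega, recipe$sequence)
    z_target <- stats::runif(1, recipe$z_range[1], recipe$z_range[2])
    z_anchor <- coords$z[coords$residue == recipe$anchor_residue &
                           coords$atom == "CA"]
    coords$z <- coords$z + (z_target - z_anchor)
    energy <- stats::rnorm(1, recipe$energy_mean[[cl]], recipe$energy_sd)
    shifts <- toy_predict(res3, cl, shift_model)
    m <- conformer_model(k, data.frame(phi = phi, psi = psi, omega = omega),
                         coords, energy, shifts)
    m$ss_class <- cl
    models[[k]] <- m
  }
  pool <- model_pool(models, recipe$sequence,
                     sprintf("synthetic pool (seed %s)", format(recipe$seed)))
  pool
}

#' Generate a synthetic "experimental" shift table
#'
#' Builds ground truth for recovery tests: per restraint atom, the mean of
#' a chosen model subset's predictions plus Gaussian noise.
#'
#' @param models Non-empty list of [conformer_model]s (the ground-truth
#'   subset).
#' @param sequence One-letter sequence of the models.
#' @param atoms Atom labels to emit (default CO/CA/CB/HA).
#' @param noise_sd Gaussian noise in ppm (default 0.1).
#' @param seed RNG seed.
#' @return A [shift_table].
#' @export
gen_experimental_shifts <- function(models, sequence,
                                    atoms = c("CO", "CA", "CB", "HA"),
                                    noise_sd = 0.1, seed = 1L) {
  if (length(models) == 0) stopf("empty model subset")
  set.seed(seed)
  res3 <- aa1to3(sequence)
  keys <- names(models[[1]]$predicted_shifts)
  parts <- strsplit(keys, ":", fixed = TRUE)
  key_atom <- vapply(parts, `[`, "", 2)
  keys <- keys[key_atom %in% atoms]
  P <- matrix(NA_real_, length(models), length(keys))
  for (i in seq_along(models)) {
    ps <- models[[i]]$predicted_shifts
    hit <- match(keys, names(ps))
    if (anyNA(hit))
      stopf("model %d lacks prediction for %s", models[[i]]$model_id,
            keys[which(is.na(hit))[1]])
    P[i, ] <- unname(ps[hit])
  }
  mu <- colMeans(P) + stats::rnorm(length(keys), 0, noise_sd)
  parts <- strsplit(keys, ":", fixed = TRUE)
  rn <- as.integer(vapply(parts, `[`, "", 1))
  shift_table(rn, res3[rn], vapply(parts, `[`, "", 2), mu)
}

#' Generate a synthetic binding dataset
#'
#' Bound fractions follow the hyperbolic isotherm
#' `f = Bmax * L_eff / (K_D + L_eff)` at the effective lipid
#' concentration, with Gaussian noise clipped to [0, 1], and are encoded
#' as supernatant/pellet intensity pairs summing to 1.
#'
#' @param kd_uM Dissociation constant in uM (> 0; default 520, the
#'   measured value for acyl-ghrelin on anionic vesicles).
#' @param bmax Saturating bound fraction (default 0.95, ">90 % bound").
#' @param lipid_concs_mM Total lipid concentrations (default 0-10 mM, the
#'   assay's range).
#' @param noise_sd Gaussian noise on the fraction (default 0.02).
#' @param replicates Replicates per concentration (default 2, as assayed).
#' @param seed RNG seed.
#' @param cfg A [thermo_config] for the effective-lipid factor.
#' @return Data.frame `lipid_total_mM,I_supernatant,I_pellet,replicate`.
#' @export
gen_binding_data <- function(kd_uM = 520, bmax = 0.95,
                             lipid_concs_mM = c(0, 0.25, 0.5, 1, 2, 3, 4, 5,
                                                6, 8, 10),
                             noise_sd = 0.02, replicates = 2L, seed = 1L,
                             cfg = thermo_config()) {
  if (kd_uM <= 0) stopf("K_D must be > 0")
  set.seed(seed)
  kd_mM <- kd_uM / 1000
  grid <- expand.grid(replicate = seq_len(replicates),
                      lipid_total_mM = lipid_concs_mM)
  L_eff <- effective_lipid(grid$lipid_total_mM, cfg)
  f <- bmax * L_eff / (kd_mM + L_eff)
  f <- pmin(pmax(f + stats::rnorm(nrow(grid), 0, noise_sd), 0), 1)
  data.frame(lipid_total_mM = grid$lipid_total_mM,
             I_supernatant = 1 - f, I_pellet = f,
             replicate = grid$replicate)
}

#' Generate a synthetic spin-diffusion buildup curve
#'
#' Simulates the clamped-source lattice trace of the site `steps` away
#' from the reservoir, applies T1 decay (`* exp(-t/T1)`) and adds noise:
#' exactly the inverse of [correct_and_normalize].
#'
#' @param steps Lattice distance of the observed site (>= 1).
#' @param omega Transfer rate in 1/s.
#' @param t_list Mixing times in s (must include the normalization time).
#' @param noise_sd Gaussian intensity noise (default 0).
#' @param T1 Longitudinal relaxation time in s (default `Inf`).
#' @param seed RNG seed.
#' @param n_sites Chain length used for the simulation (default
#'   `steps + 3`: source plus `steps + 2` free sites, matching
#'   [fit_step_distance]'s boundary insulation).
#' @param normalization_time Recorded normalization time (default 0.9 s).
#' @return A [buildup_curve] with the generator's T1 attached.
#' @export
gen_buildup <- function(steps, omega, t_list, noise_sd = 0, T1 = Inf,
                        seed = 1L, n_sites = steps + 3L,
                        normalization_time = 0.9) {
  if (steps < 1) stopf("steps must be >= 1")
  set.seed(seed)
  spec <- lattice_spec(n_sites = n_sites, omega = omega,
                       source_mode = "clamped_reservoir")
  M <- simulate_lattice(spec, t_list)
  tr <- M[, steps + 1L]
  obs <- tr * exp(-t_list / T1) + stats::rnorm(length(t_list), 0, noise_sd)
  buildup_curve(t_list, obs, T1 = T1, normalization_time = normalization_time)
}
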