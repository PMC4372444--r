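#' Backbone construction and conformer pools
#'
#' A `conformer_model` is one peptide backbone: per-residue phi/psi/omega
#' torsions, N/CA/C coordinates in a membrane frame (z axis = membrane
#' normal, bilayer center at z = 0), a scalar energy (lower is better) and
#' a map of predicted chemical shifts.  A `model_pool` is a list of such
#' models sharing one sequence.
#'
#' @name conformers
NULL

# Engh-Huber-style ideal backbone geometry (A, degrees)
.B_N_CA  <- 1.458
.B_CA_C  <- 1.525
.B_C_N   <- 1.329
.ANG_N_CA_C <- 111.2
.ANG_CA_C_N <- 116.2
.ANG_C_N_CA <- 121.7

#' @noRd
deg2rad <- function(x) x * pi / 180

#' @noRd
vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @noRd
vunit <- function(v) v / sqrt(sum(v^2))

# Natural-extension (NeRF) placement: position atom D given chain atoms
# A-B-C, the C-D bond length, the B-C-D angle and the A-B-C-D dihedral.
#' @noRd
place_atom <- function(a, b, c_, length, angle_deg, dihedral_deg) {
  th <- deg2rad(angle_deg)
  ph <- deg2rad(dihedral_deg)
  d2 <- c(-length * cos(th),
          length * sin(th) * cos(ph),
          -length * sin(th) * sin(ph))
  bc <- vunit(c_ - b)
  n  <- vunit(vcross(b - a, bc))
  m  <- cbind(bc, vcross(n, bc), n)
  c_ + as.vector(m %*% d2)
}

#' @noRd
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Build an ideal-geometry backbone from torsion angles
#'
#' Constructs sequential N/CA/C coordinates from per-residue phi/psi/omega
#' using ideal bond lengths (N-CA 1.458 A, CA-C 1.525 A, C-N 1.329 A) and
#' standard bond angles.  The first residue's N is placed at the origin;
#' phi of residue 1 and psi/omega of the last residue are not used.
#'
#' @param phi,psi,omega Numeric vectors of torsions in degrees, one per
#'   residue, each in (-180, 180].
#' @param sequence One-letter sequence string with `length(phi)` residues.
#' @return Data.frame with columns `residue`, `atom` (N/CA/C), `x`, `y`, `z`.
#' @examples
#' bb <- build_backbone(rep(-57, 5), rep(-47, 5), rep(180, 5), "AAAAA")
#' @export
build_backbone <- function(phi, psi, omega, sequence) {
  n <- nchar(sequence)
  if (length(phi) != n || length(psi) != n || length(omega) != n)
    stopf("torsion vectors must have one value per residue (%d)", n)
  tors <- c(phi, psi, omega)
  if (any(!is.finite(tors))) stopf("non-finite torsion angle")
  if (any(abs(tors) > 180)) stopf("torsions must lie in (-180, 180] degrees")

  N  <- matrix(NA_real_, n, 3)
  CA <- matrix(NA_real_, n, 3)
  C  <- matrix(NA_real_, n, 3)
  N[1, ]  <- c(0, 0, 0)
  CA[1, ] <- c(.B_N_CA, 0, 0)
  th <- deg2rad(.ANG_N_CA_C)
  C[1, ] <- CA[1, ] + .B_CA_C * c(-cos(th), sin(th), 0)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      N[i + 1, ]  <- place_atom(N[i, ], CA[i, ], C[i, ],
                                .B_C_N, .ANG_CA_C_N, psi[i])
      CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ],
                                .B_N_CA, .ANG_C_N_CA, omega[i])
      C[i + 1, ]  <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ],
                                .B_CA_C, .ANG_N_CA_C, phi[i + 1])
    }
  }
  data.frame(
    residue = rep(seq_len(n), each = 3),
    atom    = rep(c("N", "CA", "C"), n),
    x = as.vector(t(cbind(N[, 1], CA[, 1], C[, 1]))),
    y = as.vector(t(cbind(N[, 2], CA[, 2], C[, 2]))),
    z = as.vector(t(cbind(N[, 3], CA[, 3], C[, 3]))),
    stringsAsFactors = FALSE
  )
}

#' Measure backbone torsions from coordinates
#'
#' Inverse of [build_backbone]: recovers phi/psi/omega (degrees) from
#' N/CA/C coordinates.  Undefined terminal torsions are `NA`.
#'
#' @param coords Backbone data.frame as produced by [build_backbone].
#' @return Data.frame with columns `residue`, `phi`, `psi`, `omega`.
#' @export
measure_torsions <- function(coords) {
  n <- max(coords$residue)
  get <- function(res, atom) {
    r <- coords[coords$residue == res & coords$atom == atom, ]
    c(r$x, r$y, r$z)
  }
  phi <- psi <- omega <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1)
      phi[i] <- dihedral(get(i - 1, "C"), get(i, "N"), get(i, "CA"), get(i, "C"))
    if (i < n) {
      psi[i]   <- dihedral(get(i, "N"), get(i, "CA"), get(i, "C"), get(i + 1, "N"))
      omega[i] <- dihedral(get(i, "CA"), get(i, "C"), get(i + 1, "N"), get(i + 1, "CA"))
    }
  }
  data.frame(residue = seq_len(n), phi = phi, psi = psi, omega = omega)
}

#' Construct a single conformer model
#'
#' @param model_id Unique integer id within a pool.
#' @param torsions Data.frame with columns `phi`, `psi`, `omega` (degrees).
#' @param coords Backbone coordinates ([build_backbone] layout) in the
#'   membrane frame (z = distance from bilayer center, A).
#' @param energy Scalar score (lower is better).
#' @param predicted_shifts Named numeric vector of predicted shifts keyed
#'   `"residue:atom"`, e.g. `"3:CA"`.
#' @return A `conformer_model`.
#' @export
conformer_model <- function(model_id, torsions, coords, energy,
                            predicted_shifts = numeric()) {
  stopifnot(is.data.frame(torsions),
            all(c("phi", "psi", "omega") %in% names(torsions)))
  m <- structure(
    list(model_id = as.integer(model_id), torsions = torsions,
         coords = coords, energy = as.numeric(energy),
         predicted_shifts = predicted_shifts),
    class = "conformer_model"
  )
  m
}

#' Construct a pool of conformer models
#'
#' @param models List of [conformer_model] objects with unique ids and a
#'   common residue count.
#' @param sequence One-letter sequence shared by all models.
#' @param provenance Free-text description of how the pool was produced.
#' @return A `model_pool`.
#' @export
model_pool <- function(models, sequence, provenance = "") {
  ids <- vapply(models, function(m) m$model_id, integer(1))
  if (anyDuplicated(ids)) stopf("model ids must be unique")
  nres <- nchar(sequence)
  lens <- vapply(models, function(m) nrow(m$torsions), integer(1))
  if (length(lens) > 0 && any(lens != nres))
    stopf("all models must have %d residues", nres)
  structure(list(models = models, sequence = sequence,
                 provenance = provenance),
            class = "model_pool")
}

#' @export
print.model_pool <- function(x, ...) {
  cat(sprintf("<model_pool> %d models, sequence %s\n",
              length(x$models), x$sequence))
  invisible(x)
}

#' @export
length.model_pool <- function(x) length(x$models)

#' @noRd
pool_energies <- function(pool) {
  vapply(pool$models, function(m) m$energy, numeric(1))
}

#' @noRd
pool_subset <- function(pool, keep, provenance) {
  model_pool(pool$models[keep], pool$sequence, provenance)
}

#' Filter configuration for pool selection
#'
#' @param anchor_residue Residue whose CA must sit in the membrane polar
#'   region (default 3, the acylation site of ghrelin).
#' @param slab_zmin,slab_zmax Bounds (A) of the polar-region slab measured
#'   as |z| from the bilayer center (defaults 12 and 18: the conventional
#'   implicit-membrane hydrophobic half-thickness plus interfacial shell).
#' @param receptor_min_distance Minimum allowed peptide-to-receptor atom
#'   distance in A (default 5).
#' @param energy_fraction Fraction of lowest-energy reference models that
#'   defines the energy cutoff (default 0.10).
#' @return A `filter_config` list.
#' @export
filter_config <- function(anchor_residue = 3L, slab_zmin = 12, slab_zmax = 18,
                          receptor_min_distance = 5, energy_fraction = 0.10) {
  if (!(slab_zmin > 0 && slab_zmax > slab_zmin))
    stopf("need 0 < slab_zmin < slab_zmax")
  if (receptor_min_distance <= 0) stopf("receptor_min_distance must be > 0")
  if (!(energy_fraction > 0 && energy_fraction <= 1))
    stopf("energy_fraction must lie in (0, 1]")
  structure(list(anchor_residue = as.integer(anchor_residue),
                 slab_zmin = slab_zmin, slab_zmax = slab_zmax,
                 receptor_min_distance = receptor_min_distance,
                 energy_fraction = energy_fraction),
            class = "filter_config")
}

#' Keep models whose anchor CA lies in the membrane polar slab
#'
#' A model survives iff `slab_zmin <= |z(anchor CA)| <= slab_zmax`; the
#' absolute value makes the slab symmetric across both leaflets.  Models
#' without coordinates are dropped with a warning.
#'
#' @param pool A [model_pool].
#' @param cfg A [filter_config].
#' @return Filtered [model_pool]; the number removed is reported via
#'   attribute `n_removed`.
#' @export
filter_membrane_contact <- function(pool, cfg = filter_config()) {
  if (cfg$anchor_residue > nchar(pool$sequence))
    stopf("anchor residue %d outside sequence", cfg$anchor_residue)
  keep <- vapply(pool$models, function(m) {
    if (is.null(m$coords)) {
      warnf("model %d has no coordinates; removed", m$model_id)
      return(FALSE)
    }
    z <- m$coords$z[m$coords$residue == cfg$anchor_residue &
                      m$coords$atom == "CA"]
    length(z) == 1 && abs(z) >= cfg$slab_zmin && abs(z) <= cfg$slab_zmax
  }, logical(1))
  out <- pool_subset(pool, keep,
                     sprintf("%s | membrane slab [%g, %g] on residue %d",
                             pool$provenance, cfg$slab_zmin, cfg$slab_zmax,
                             cfg$anchor_residue))
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Keep models clear of the receptor proxy
#'
#' A model survives iff the minimum distance between any of its backbone
#' atoms and any receptor atom is at least `receptor_min_distance`.  The
#' receptor here is only a spatial proxy marking where a receptor would
#' sit; no interaction is modeled.
#'
#' @param pool A [model_pool].
#' @param receptor_coords Matrix or data.frame of receptor atom x/y/z (A).
#' @param cfg A [filter_config].
#' @return Filtered [model_pool].
#' @export
filter_receptor_distance <- function(pool, receptor_coords,
                                     cfg = filter_config()) {
  if (is.data.frame(receptor_coords))
    receptor_coords <- as.matrix(receptor_coords[, c("x", "y", "z")])
  if (is.null(receptor_coords) || nrow(receptor_coords) == 0)
    stopf("receptor coordinate set is empty; the distance filter is undefined")
  keep <- vapply(pool$models, function(m) {
    p <- as.matrix(m$coords[, c("x", "y", "z")])
    d2min <- min(vapply(seq_len(nrow(receptor_coords)), function(j) {
      min(rowSums((p - matrix(receptor_coords[j, ], nrow(p), 3,
                              byrow = TRUE))^2))
    }, numeric(1)))
    sqrt(d2min) >= cfg$receptor_min_distance
  }, logical(1))
  out <- pool_subset(pool, keep,
                     sprintf("%s | receptor distance >= %g A", pool$provenance,
                             cfg$receptor_min_distance))
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Keep models within the lowest-energy fraction of a reference pool
#'
#' The cutoff is the energy at the `ceiling(fraction * N)`-th lowest
#' position of the reference pool ("top" = lowest energy); models with
#' energy `<=` cutoff pass, so ties at the threshold are included.  By
#' default the reference is the pool itself, but passing the original
#' unfiltered pool reproduces a protocol where the percentile is taken
#' over all generated models and intersected with earlier filters.
#'
#' @param pool A [model_pool] to filter.
#' @param cfg A [filter_config].
#' @param reference_pool Pool defining the energy distribution (default
#'   `pool`).
#' @return Filtered [model_pool].
#' @export
filter_energy_percentile <- function(pool, cfg = filter_config(),
                                     reference_pool = pool) {
  if (length(reference_pool$models) == 0) stopf("reference pool is empty")
  e_ref <- sort(pool_energies(reference_pool))
  k <- ceiling(cfg$energy_fraction * length(e_ref))
  cutoff <- e_ref[k]
  keep <- pool_energies(pool) <= cutoff
  out <- pool_subset(pool, keep,
                     sprintf("%s | energy <= %g (lowest %g%% of reference)",
                             pool$provenance, cutoff,
                             100 * cfg$energy_fraction))
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "energy_cutoff") <- cutoff
  out
}
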