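#' Polyproline-II-aware secondary structure analysis
#'
#' DSSP assigns secondary structure from hydrogen bonding, so the
#' left-handed polyproline II (PPII) helix -- which lacks the regular
#' intra-chain hydrogen bonds of alpha-helices -- is reported as coil
#' (`-`).  The overlay implemented here relabels coil residues as `P`
#' when their phi/psi torsions fall in the PPII region (phi = -75 +/- 29
#' degrees, psi = 145 +/- 29 degrees) for at least two sequential
#' residues.
#'
#' @name secstruct
NULL

#' PPII torsion-window rule
#'
#' @param phi_center,phi_halfwidth Phi window in degrees (default -75 +/- 29).
#' @param psi_center,psi_halfwidth Psi window in degrees (default 145 +/- 29).
#' @param min_run Minimum run length of qualifying residues (default 2).
#' @return A `ppii_rule` list.
#' @export
ppii_rule <- function(phi_center = -75, phi_halfwidth = 29,
                      psi_center = 145, psi_halfwidth = 29, min_run = 2L) {
  if (phi_halfwidth <= 0 || psi_halfwidth <= 0) stopf("halfwidths must be > 0")
  if (min_run < 2) stopf("min_run must be >= 2")
  structure(list(phi_center = phi_center, phi_halfwidth = phi_halfwidth,
                 psi_center = psi_center, psi_halfwidth = psi_halfwidth,
                 min_run = as.integer(min_run)),
            class = "ppii_rule")
}

#' Overlay PPII assignments on a DSSP string
#'
#' Residue i is relabeled from `-` to `P` iff (1) its DSSP symbol is `-`,
#' (2) phi lies in the phi window, (3) psi lies in the psi window
#' (both windows closed), and (4) at least one sequence neighbor also
#' satisfies conditions 1-3, so runs of `P` have length >= 2.  Terminal
#' residues with undefined phi or psi (`NA`) are never eligible.  No
#' symbol other than `-` is ever changed.
#'
#' @param assignment Character string of per-residue DSSP symbols over
#'   `H G I E B T S -`.
#' @param phi,psi Numeric torsion vectors (degrees) matching the
#'   assignment length; `NA` at undefined termini.
#' @param rule A [ppii_rule].
#' @return The modified assignment string.
#' @examples
#' ppii_overlay("----", c(NA, -75, -75, -80), c(145, 145, 150, NA))
#' @export
ppii_overlay <- function(assignment, phi, psi, rule = ppii_rule()) {
  sym <- strsplit(assignment, "")[[1]]
  n <- length(sym)
  if (length(phi) != n || length(psi) != n)
    stopf("torsion vectors (%d, %d) do not match assignment length %d",
          length(phi), length(psi), n)
  in_window <- function(x, center, hw) !is.na(x) & x >= center - hw & x <= center + hw
  ok <- sym == "-" &
    in_window(phi, rule$phi_center, rule$phi_halfwidth) &
    in_window(psi, rule$psi_center, rule$psi_halfwidth)
  neighbor_ok <- c(ok[-1], FALSE) | c(FALSE, ok[-n])
  sym[ok & neighbor_ok] <- "P"
  paste(sym, collapse = "")
}

# Symbol classes used for ensemble composition: coil, bend/turn,
# helix (alpha, 3-10, PPII), other (strand/bridge/pi).
.SS_CLASSES <- list(
  coil  = "-",
  turn  = c("S", "T"),
  helix = c("H", "G", "P"),
  other = c("E", "B", "I")
)

#' Per-position secondary-structure composition of an ensemble
#'
#' @param assignments Character vector of equal-length assignment strings
#'   (one per model), possibly PPII-overlaid.
#' @return Data.frame with columns `position`, `coil`, `turn`, `helix`,
#'   `other`; the four fractions sum to 1 at every position.
#' @export
ss_composition <- function(assignments) {
  if (length(assignments) == 0) stopf("no assignments given")
  mat <- do.call(rbind, strsplit(assignments, ""))
  if (length(unique(nchar(assignments))) != 1)
    stopf("assignments differ in length")
  n <- ncol(mat)
  out <- data.frame(position = seq_len(n))
  for (cl in names(.SS_CLASSES))
    out[[cl]] <- colMeans(matrix(mat %in% .SS_CLASSES[[cl]], nrow(mat), n))
  out
}

#' Flat phi/psi table for Ramachandran plotting
#'
#' @param models List of [conformer_model]s.
#' @param residue_ranges Named list of integer vectors, e.g.
#'   `list("1-7" = 1:7, "8-12" = 8:12)`.
#' @return Data.frame with columns `range`, `model_id`, `residue`, `phi`,
#'   `psi`.
#' @export
ramachandran_export <- function(models, residue_ranges) {
  if (length(models) == 0) stopf("no models given")
  nres <- nrow(models[[1]]$torsions)
  rows <- list()
  for (label in names(residue_ranges)) {
    rng <- residue_ranges[[label]]
    if (length(rng) == 0) stopf("empty residue range '%s'", label)
    if (any(rng < 1 | rng > nres))
      stopf("range '%s' outside sequence 1..%d", label, nres)
    for (m in models) {
      rows[[length(rows) + 1L]] <- data.frame(
        range = label, model_id = m$model_id, residue = rng,
        phi = m$torsions$phi[rng], psi = m$torsions$psi[rng],
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Torsion-only secondary structure assignment
#'
#' A documented fallback for backbone-only models where DSSP (which needs
#' full-atom coordinates and hydrogen bonds) cannot run: residues in the
#' alpha region (phi in [-100, -30], psi in [-80, -5]) become `H`, in the
#' beta region (phi in [-180, -100], psi in [90, 180] or psi near -180)
#' become `E`, everything else `-`.  Runs shorter than 3 (helix) or 2
#' (strand) are reset to coil, mimicking DSSP's minimal element lengths.
#'
#' @param phi,psi Torsion vectors in degrees (`NA` at termini).
#' @return Assignment string with source label attribute `"torsion-only"`.
#' @export
assign_ss_torsion <- function(phi, psi) {
  n <- length(phi)
  sym <- rep("-", n)
  is_h <- !is.na(phi) & !is.na(psi) &
    phi >= -100 & phi <= -30 & psi >= -80 & psi <= -5
  is_e <- !is.na(phi) & !is.na(psi) &
    phi >= -180 & phi < -100 & (psi >= 90 | psi <= -170)
  sym[is_h] <- "H"; sym[is_e] <- "E"
  # enforce minimal element lengths
  r <- rle(sym)
  drop_ <- (r$values == "H" & r$lengths < 3) | (r$values == "E" & r$lengths < 2)
  r$values[drop_] <- "-"
  out <- paste(inverse.rle(r), collapse = "")
  attr(out, "source") <- "torsion-only"
  out
}

#' Read per-residue assignments from a classic DSSP output file
#'
#' Parses the per-residue block of a `.dssp` file and returns the symbol
#' string (spaces mapped to `-`).  Chain breaks (`!` rows) are skipped.
#'
#' @param path Path to a DSSP output file.
#' @return Assignment string with source label attribute `"external-dssp"`.
#' @export
read_dssp <- function(path) {
  lines <- readLines(path)
  start <- grep("^  #  RESIDUE", lines)
  if (length(start) == 0) stopf("%s does not look like DSSP output", path)
  body <- lines[(start[1] + 1):length(lines)]
  body <- body[nchar(body) >= 17]
  aa <- substr(body, 14, 14)
  body <- body[aa != "!"]
  sym <- substr(body, 17, 17)
  sym[sym == " "] <- "-"
  out <- paste(sym, collapse = "")
  attr(out, "source") <- "external-dssp"
  out
}
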