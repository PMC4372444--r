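# Internal helpers shared across modules.

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Atom vocabulary.  Carbons carry ~10x larger shift magnitudes than protons,
# which is why the selection objective scales them down.
.CARBON_ATOMS <- c("CO", "CA", "CB", "CG", "CD")
.PROTON_ATOMS <- c("HA", "HB", "HG", "HD")
.ALL_ATOMS    <- c(.CARBON_ATOMS, .PROTON_ATOMS)

.AA1 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)
.AA3 <- stats::setNames(names(.AA1), .AA1)

#' Convert a one-letter sequence string to three-letter residue codes
#' @noRd
aa1to3 <- function(sequence) {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  unknown <- setdiff(letters1, names(.AA1))
  if (length(unknown) > 0)
    stopf("unknown residue letter(s): %s", paste(unknown, collapse = ", "))
  unname(.AA1[letters1])
}

#' @noRd
atom_class <- function(atom) {
  ifelse(atom %in% .CARBON_ATOMS, "carbon",
         ifelse(atom %in% .PROTON_ATOMS, "proton", NA_character_))
}

#' Restraint key "residue:atom" used for fast map lookups
#' @noRd
restraint_key <- function(residue_number, atom) paste0(residue_number, ":", atom)

#' The 28-residue human ghrelin sequence (Gly1..Arg28)
#'
#' Default sequence for the synthetic pool generator and the net-charge
#' calculator.
#' @export
GHRELIN_SEQUENCE <- "GSSFLSPEHQRVQQRKESKKPPAKLQPR"
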