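#' Experimental chemical-shift tables
#'
#' A `shift_table` holds per-residue, per-atom isotropic chemical shifts
#' (ppm) measured for a peptide, with optional experimental uncertainties.
#' It is a thin data.frame subclass with columns `residue_number`,
#' `residue_name`, `atom`, `shift_ppm`, `uncertainty_ppm`.
#'
#' Missing measurements are simply absent rows (never zeros); at most one
#' entry may exist per (residue, atom) pair.
#'
#' @param residue_number 1-based residue numbers (integer-like).
#' @param residue_name Three-letter residue codes, e.g. `"GLY"`.
#' @param atom Atom labels, one of CO, CA, CB, CG, CD, HA, HB, HG, HD.
#' @param shift_ppm Chemical shifts in ppm; must be finite.
#' @param uncertainty_ppm Optional uncertainties in ppm (`NA` allowed),
#'   non-negative where present.
#' @return An object of class `shift_table`.
#' @examples
#' shift_table(1, "GLY", "CA", 40.9, 0.2)
#' @export
shift_table <- function(residue_number, residue_name, atom, shift_ppm,
                        uncertainty_ppm = NA_real_) {
  df <- data.frame(
    residue_number  = as.integer(residue_number),
    residue_name    = toupper(as.character(residue_name)),
    atom            = toupper(as.character(atom)),
    shift_ppm       = as.numeric(shift_ppm),
    uncertainty_ppm = as.numeric(uncertainty_ppm),
    stringsAsFactors = FALSE
  )
  validate_shift_table(df)
  class(df) <- c("shift_table", "data.frame")
  df
}

#' @noRd
validate_shift_table <- function(df) {
  if (any(df$residue_number < 1L))
    stopf("residue numbers must be >= 1 (1-based numbering)")
  bad_atom <- setdiff(unique(df$atom), .ALL_ATOMS)
  if (length(bad_atom) > 0)
    stopf("unknown atom label(s): %s (allowed: %s)",
          paste(bad_atom, collapse = ", "), paste(.ALL_ATOMS, collapse = ", "))
  if (any(!is.finite(df$shift_ppm)))
    stopf("all shifts must be finite")
  if (any(!is.na(df$uncertainty_ppm) & df$uncertainty_ppm < 0))
    stopf("uncertainties must be >= 0 where present")
  key <- restraint_key(df$residue_number, df$atom)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stopf("duplicate (residue, atom) entry: %s", dup)
  }
  invisible(df)
}

#' Read a chemical-shift table from CSV
#'
#' The schema is `residue_number,residue_name,atom,shift_ppm,uncertainty_ppm`
#' with the uncertainty column optional/empty-allowed.  Duplicate
#' (residue, atom) pairs and non-numeric shifts are rejected with the
#' offending line numbers.
#'
#' @param path Path to a UTF-8 CSV file.
#' @return A [shift_table].
#' @export
read_shift_table <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("residue_number", "residue_name", "atom", "shift_ppm")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0)
    stopf("shift CSV %s lacks column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  if (!"uncertainty_ppm" %in% names(raw)) raw$uncertainty_ppm <- ""

  # data line i of the file is CSV row i + 1 (header)
  lines <- seq_len(nrow(raw)) + 1L
  shift_num <- suppressWarnings(as.numeric(raw$shift_ppm))
  bad <- which(is.na(shift_num))
  if (length(bad) > 0)
    stopf("non-numeric shift_ppm at line(s) %s of %s",
          paste(lines[bad], collapse = ", "), path)
  unc <- suppressWarnings(as.numeric(raw$uncertainty_ppm))
  unc[raw$uncertainty_ppm == ""] <- NA_real_

  key <- restraint_key(raw$residue_number, toupper(raw$atom))
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    at <- lines[key == d]
    stopf("duplicate (residue, atom) entry %s at lines %s of %s",
          d, paste(at, collapse = " and "), path)
  }
  shift_table(raw$residue_number, raw$residue_name, raw$atom, shift_num, unc)
}

#' Write a chemical-shift table to CSV
#'
#' Values are written in plain decimal so that a write/read round trip
#' reproduces the table exactly at the stored precision.
#'
#' @param table A [shift_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shift_table <- function(table, path) {
  out <- as.data.frame(table)
  out$shift_ppm <- vapply(out$shift_ppm, format, "", digits = 15)
  out$uncertainty_ppm <- ifelse(is.na(out$uncertainty_ppm), "",
                                vapply(out$uncertainty_ppm, format, "", digits = 15))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Select shift restraints by atom type
#'
#' Subsets a shift table to the atoms used as structural restraints,
#' optionally excluding residues (e.g. a terminal glycine whose shifts are
#' perturbed by the free amine).  Each restraint is tagged with its atom
#' class (carbon or proton), which the ensemble-selection objective uses
#' for scaling.
#'
#' @param table A [shift_table].
#' @param atoms Character vector of atom labels to keep (may be empty).
#' @param excluded_residues Integer residue numbers to drop (default none).
#' @return A `restraint_set`: data.frame with columns `residue_number`,
#'   `atom`, `shift_ppm`, `atom_class`, carrying attribute `n`.
#' @examples
#' tb <- shift_table(c(1, 2), c("GLY", "SER"), c("CA", "CA"), c(40.9, 55.6))
#' select_restraints(tb, atoms = "CA", excluded_residues = 1)
#' @export
select_restraints <- function(table, atoms, excluded_residues = integer()) {
  stopifnot(inherits(table, "shift_table"))
  atoms <- toupper(as.character(atoms))
  bad <- setdiff(atoms, .ALL_ATOMS)
  if (length(bad) > 0)
    stopf("unknown atom label(s) in selection: %s", paste(bad, collapse = ", "))
  keep <- table$atom %in% atoms &
    !(table$residue_number %in% as.integer(excluded_residues))
  rs <- data.frame(
    residue_number = table$residue_number[keep],
    atom           = table$atom[keep],
    shift_ppm      = table$shift_ppm[keep],
    stringsAsFactors = FALSE
  )
  rs$atom_class <- atom_class(rs$atom)
  attr(rs, "n") <- nrow(rs)
  class(rs) <- c("restraint_set", "data.frame")
  rs
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf("<restraint_set> %d restraints (%d carbon, %d proton)\n",
              nrow(x), sum(x$atom_class == "carbon"),
              sum(x$atom_class == "proton")))
  invisible(x)
}

#' Random-coil chemical-shift reference
#'
#' Reads a random-coil reference CSV (`residue_name,atom,shift_ppm`) used to
#' compute secondary chemical shifts.  The package ships a Wishart-style
#' random-coil table for CO/CA/CB/HA under `inst/extdata`; pass `path` to
#' override it.
#'
#' @param path CSV path; defaults to the packaged reference table.
#' @param provenance Free-text label describing where the values came from.
#' @return A `random_coil_reference` data.frame with a `provenance` attribute.
#' @export
read_random_coil_reference <- function(path = NULL,
                                       provenance = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "random_coil_reference.csv",
                        package = "memnmr", mustWork = TRUE)
    if (is.null(provenance))
      provenance <- "packaged Wishart-style random-coil values (1995 compilation)"
  }
  if (is.null(provenance)) provenance <- paste("user file:", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("residue_name", "atom", "shift_ppm")
  if (!all(need %in% names(df)))
    stopf("random-coil CSV needs columns: %s", paste(need, collapse = ", "))
  df$residue_name <- toupper(df$residue_name)
  df$atom <- toupper(df$atom)
  attr(df, "provenance") <- provenance
  class(df) <- c("random_coil_reference", "data.frame")
  df
}

#' Look up a random-coil reference shift, erroring if absent
#' @noRd
rc_lookup <- function(reference, residue_name, atom) {
  i <- which(reference$residue_name == residue_name & reference$atom == atom)
  if (length(i) == 0)
    stopf("random-coil reference has no entry for %s %s", residue_name, atom)
  reference$shift_ppm[i[1]]
}

#' Chemical-shift index from Ca/Cb secondary shifts
#'
#' Computes, for every residue carrying both a CA and a CB measurement, the
#' secondary-shift difference
#' (observed Ca - random-coil Ca) - (observed Cb - random-coil Cb).
#' Values above `+threshold` ppm indicate alpha-helical tendency, values
#' below `-threshold` ppm beta-sheet character, and values in between no
#' regular secondary structure.  Glycine (no Cb) is skipped with a message.
#'
#' @param table A [shift_table].
#' @param reference A [read_random_coil_reference] table.
#' @param threshold Classification threshold in ppm (default 1).
#' @return Data.frame with columns `residue_number`, `residue_name`,
#'   `csi_ppm`, `label` (one of `"helix"`, `"sheet"`, `"none"`).
#' @export
chemical_shift_index <- function(table, reference, threshold = 1.0) {
  stopifnot(inherits(table, "shift_table"), threshold > 0)
  residues <- unique(table$residue_number)
  rows <- list()
  for (r in residues) {
    sub <- table[table$residue_number == r, , drop = FALSE]
    rname <- sub$residue_name[1]
    if (rname == "GLY") {
      message(sprintf("residue %d (GLY) skipped: no CB", r))
      next
    }
    ca <- sub$shift_ppm[sub$atom == "CA"]
    cb <- sub$shift_ppm[sub$atom == "CB"]
    if (length(ca) == 0 || length(cb) == 0) next
    d <- (ca - rc_lookup(reference, rname, "CA")) -
         (cb - rc_lookup(reference, rname, "CB"))
    label <- if (d > threshold) "helix" else if (d < -threshold) "sheet" else "none"
    rows[[length(rows) + 1L]] <- data.frame(
      residue_number = r, residue_name = rname,
      csi_ppm = d, label = label, stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0)
    return(data.frame(residue_number = integer(), residue_name = character(),
                      csi_ppm = numeric(), label = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
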