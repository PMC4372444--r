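#' Read and write conformer pools
#'
#' Pools are stored as a multi-model backbone PDB (MODEL/ENDMDL blocks with
#' N/CA/C ATOM records), a sidecar TSV of per-model energies and a
#' predicted-shifts CSV (shift-table schema plus a `model_id` column).
#' This is a deliberately narrow fixed-width reader/writer for the
#' package's own backbone-only models, not a general PDB parser.
#'
#' @name pool-io
NULL

#' @noRd
format_atom_line <- function(serial, atom, resname, resnum, x, y, z) {
  sprintf("ATOM  %5d  %-3s%4s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, atom, resname, resnum, x, y, z)
}

#' Write a model pool to disk
#'
#' @param pool A [model_pool].
#' @param pdb_path Multi-model PDB output path.
#' @param energies_path TSV output (`model_id`, `energy`).
#' @param shifts_path Optional CSV output of per-model predicted shifts
#'   (`model_id,residue_number,residue_name,atom,shift_ppm`); skipped when
#'   `NULL`.
#' @return `pdb_path`, invisibly.
#' @export
write_pool <- function(pool, pdb_path, energies_path, shifts_path = NULL) {
  res3 <- aa1to3(pool$sequence)
  con <- file(pdb_path, "w")
  on.exit(close(con))
  for (m in pool$models) {
    writeLines(sprintf("MODEL     %4d", m$model_id), con)
    serial <- 0L
    for (i in seq_len(nrow(m$coords))) {
      serial <- serial + 1L
      r <- m$coords[i, ]
      writeLines(format_atom_line(serial, r$atom, res3[r$residue], r$residue,
                                  r$x, r$y, r$z), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)

  en <- data.frame(model_id = vapply(pool$models, `[[`, integer(1), "model_id"),
                   energy = pool_energies(pool))
  utils::write.table(en, energies_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)

  if (!is.null(shifts_path)) {
    rows <- lapply(pool$models, function(m) {
      if (length(m$predicted_shifts) == 0) return(NULL)
      key <- strsplit(names(m$predicted_shifts), ":", fixed = TRUE)
      rn <- as.integer(vapply(key, `[`, "", 1))
      data.frame(model_id = m$model_id, residue_number = rn,
                 residue_name = res3[rn],
                 atom = vapply(key, `[`, "", 2),
                 shift_ppm = unname(m$predicted_shifts),
                 stringsAsFactors = FALSE)
    })
    utils::write.csv(do.call(rbind, rows), shifts_path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(pdb_path)
}

#' Read a model pool from disk
#'
#' @param pdb_path Multi-model backbone PDB written by [write_pool].
#' @param energies_path Energy TSV (`model_id`, `energy`).
#' @param shifts_path Optional predicted-shifts CSV.
#' @param provenance Free-text provenance for the pool.
#' @return A [model_pool] (torsions re-measured from the coordinates).
#' @export
read_pool <- function(pdb_path, energies_path, shifts_path = NULL,
                      provenance = NULL) {
  if (is.null(provenance)) provenance <- paste("read from", pdb_path)
  lines <- readLines(pdb_path)
  en <- utils::read.delim(energies_path)
  energy_of <- stats::setNames(en$energy, en$model_id)

  shift_map <- list()
  if (!is.null(shifts_path)) {
    sh <- utils::read.csv(shifts_path, stringsAsFactors = FALSE)
    shift_map <- split(sh, sh$model_id)
  }

  models <- list()
  cur_id <- NA_integer_
  cur_rows <- list()
  sequence_codes <- NULL
  flush_model <- function() {
    coords <- do.call(rbind, cur_rows)
    tor <- measure_torsions(coords)
    ps <- numeric()
    key <- as.character(cur_id)
    if (!is.null(shift_map[[key]])) {
      sm <- shift_map[[key]]
      ps <- stats::setNames(sm$shift_ppm, restraint_key(sm$residue_number, sm$atom))
    }
    conformer_model(cur_id, tor[, c("phi", "psi", "omega")], coords,
                    energy_of[[key]], ps)
  }
  for (ln in lines) {
    tag <- substr(ln, 1, 6)
    if (tag == "MODEL ") {
      cur_id <- as.integer(substr(ln, 7, 14))
      cur_rows <- list()
    } else if (tag == "ENDMDL") {
      models[[length(models) + 1L]] <- flush_model()
    } else if (tag == "ATOM  ") {
      resnum <- as.integer(substr(ln, 23, 26))
      row <- data.frame(
        residue = resnum,
        atom = trimws(substr(ln, 13, 16)),
        x = as.numeric(substr(ln, 31, 38)),
        y = as.numeric(substr(ln, 39, 46)),
        z = as.numeric(substr(ln, 47, 54)),
        stringsAsFactors = FALSE
      )
      cur_rows[[length(cur_rows) + 1L]] <- row
      if (is.null(sequence_codes) || length(sequence_codes) < resnum)
        sequence_codes[resnum] <- trimws(substr(ln, 18, 20))
    }
  }
  sequence <- paste(.AA3[sequence_codes], collapse = "")
  model_pool(models, sequence, provenance)
}
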