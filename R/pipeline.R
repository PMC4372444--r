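#' Full-pipeline orchestration
#'
#' Runs the complete analysis -- membrane-depth filter, receptor-distance
#' filter, energy percentile, Monte Carlo ensemble selection, PPII-aware
#' secondary-structure composition -- from one configuration, and writes a
#' machine-readable report.
#'
#' @name pipeline
NULL

#' Run configuration
#'
#' Inputs may be given as in-memory objects or as file paths (a path is
#' loaded with the package's readers).
#'
#' @param pool A [model_pool], or `NULL` if `pool_pdb` is given.
#' @param pool_pdb,pool_energies,pool_shifts Paths for [read_pool].
#' @param exp_shifts A [shift_table] or a CSV path.
#' @param restraint_atoms Atom labels used as restraints (default
#'   CO/CA/CB/HA).
#' @param excluded_residues Residues excluded from the restraints
#'   (default 1: N-terminal shifts are perturbed by the free amine).
#' @param receptor_coords Receptor atom coordinates (matrix/data.frame
#'   with x,y,z) or `NULL` to skip the receptor filter.
#' @param filter A [filter_config].
#' @param selection A [selection_config].
#' @param ppii A [ppii_rule].
#' @param output_dir Directory for intermediate artifacts, or `NULL` to
#'   keep everything in memory.
#' @return A `run_config` list.
#' @export
run_config <- function(pool = NULL, pool_pdb = NULL, pool_energies = NULL,
                       pool_shifts = NULL, exp_shifts = NULL,
                       restraint_atoms = c("CO", "CA", "CB", "HA"),
                       excluded_residues = 1L, receptor_coords = NULL,
                       filter = filter_config(),
                       selection = selection_config(),
                       ppii = ppii_rule(), output_dir = NULL) {
  if (is.null(pool) && is.null(pool_pdb))
    stopf("give either a pool object or pool_pdb/pool_energies paths")
  structure(list(pool = pool, pool_pdb = pool_pdb,
                 pool_energies = pool_energies, pool_shifts = pool_shifts,
                 exp_shifts = exp_shifts, restraint_atoms = restraint_atoms,
                 excluded_residues = excluded_residues,
                 receptor_coords = receptor_coords, filter = filter,
                 selection = selection, ppii = ppii,
                 output_dir = output_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML file has per-module sections (`pool`, `shifts`, `filter`,
#' `selection`, `ppii`, `output_dir`); unknown keys are rejected so typos
#' fail loudly.
#'
#' @param path YAML path.
#' @return A [run_config].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("pool", "shifts", "receptor", "filter", "selection", "ppii",
             "output_dir")
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0)
    stopf("unknown config section(s): %s", paste(unknown, collapse = ", "))
  fl <- do.call(filter_config, as.list(y$filter %||% list()))
  sel <- do.call(selection_config, as.list(y$selection %||% list()))
  pp <- do.call(ppii_rule, as.list(y$ppii %||% list()))
  receptor <- NULL
  if (!is.null(y$receptor))
    receptor <- utils::read.csv(y$receptor, stringsAsFactors = FALSE)
  run_config(pool_pdb = y$pool$pdb, pool_energies = y$pool$energies,
             pool_shifts = y$pool$predicted_shifts,
             exp_shifts = y$shifts$experimental,
             restraint_atoms = y$shifts$atoms %||% c("CO", "CA", "CB", "HA"),
             excluded_residues = y$shifts$excluded_residues %||% 1L,
             receptor_coords = receptor, filter = fl, selection = sel,
             ppii = pp, output_dir = y$output_dir)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full filter-select-analyze pipeline
#'
#' Stages run in order: membrane-contact filter, receptor-distance filter
#' (skipped when no receptor is given), energy percentile (threshold taken
#' over the original pool), Monte Carlo ensemble selection, torsion-based
#' secondary-structure assignment with PPII overlay, and per-position
#' composition.  Deterministic given the selection seed.  A failing stage
#' aborts with the stage name.
#'
#' @param cfg A [run_config].
#' @return A `run_report` list with per-stage counts, ensemble size and
#'   RMSD, the composition table, seed and timestamp.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    tryCatch(force(expr),
             error = function(e) stopf("stage '%s' failed: %s", name,
                                       conditionMessage(e)))
  }
  pool0 <- stage("load_pool",
    cfg$pool %||% read_pool(cfg$pool_pdb, cfg$pool_energies, cfg$pool_shifts))
  exp_tab <- stage("load_shifts", {
    if (inherits(cfg$exp_shifts, "shift_table")) cfg$exp_shifts
    else read_shift_table(cfg$exp_shifts)
  })
  restraints <- stage("select_restraints",
    select_restraints(exp_tab, cfg$restraint_atoms, cfg$excluded_residues))

  p1 <- stage("membrane_filter", filter_membrane_contact(pool0, cfg$filter))
  p2 <- if (is.null(cfg$receptor_coords)) p1 else
    stage("receptor_filter",
          filter_receptor_distance(p1, cfg$receptor_coords, cfg$filter))
  p3 <- stage("energy_filter",
    filter_energy_percentile(p2, cfg$filter, reference_pool = pool0))

  ens <- stage("ensemble_selection",
    select_ensemble(p3, restraints, cfg$selection))
  members <- ensemble_models(p3, ens)

  assignments <- stage("secstruct", vapply(members, function(m) {
    base <- assign_ss_torsion(m$torsions$phi, m$torsions$psi)
    ppii_overlay(base, m$torsions$phi, m$torsions$psi, cfg$ppii)
  }, ""))
  comp <- stage("composition", ss_composition(assignments))

  report <- structure(list(
    counts = c(pool = length(pool0), membrane = length(p1),
               receptor = length(p2), energy = length(p3)),
    n_restraints = nrow(restraints),
    ensemble_size = length(ens$member_ids),
    member_ids = ens$member_ids,
    rmsd_ppm = ens$rmsd,
    seed = cfg$selection$seed,
    cycles = cfg$selection$cycles,
    composition = comp,
    assignments = unname(assignments),
    version = as.character(utils::packageVersion("memnmr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_report")

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_pool(model_pool(members, pool0$sequence, "selected ensemble"),
               file.path(cfg$output_dir, "ensemble.pdb"),
               file.path(cfg$output_dir, "ensemble_energies.tsv"))
    utils::write.csv(comp, file.path(cfg$output_dir, "ss_composition.csv"),
                     row.names = FALSE)
    write_run_report(report, file.path(cfg$output_dir, "report.json"))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf(
    "<run_report> pool %d -> membrane %d -> receptor %d -> energy %d\n",
    x$counts["pool"], x$counts["membrane"], x$counts["receptor"],
    x$counts["energy"]))
  cat(sprintf("  ensemble: %d models, CS-RMSD %.4f ppm (seed %s)\n",
              x$ensemble_size, x$rmsd_ppm, format(x$seed)))
  invisible(x)
}

.REPORT_FIELDS <- c("counts", "n_restraints", "ensemble_size", "member_ids",
                    "rmsd_ppm", "seed", "cycles", "composition", "version",
                    "timestamp")

#' Write a run report as JSON
#'
#' @param report A `run_report` from [run_full_analysis].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  missing_f <- setdiff(.REPORT_FIELDS, names(report))
  if (length(missing_f) > 0)
    stopf("report lacks field(s): %s", paste(missing_f, collapse = ", "))
  out <- unclass(report)
  out$counts <- as.list(out$counts)   # keep stage names in the JSON object
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a run report back from JSON
#'
#' @param path JSON path written by [write_run_report].
#' @return A `run_report` list.
#' @export
read_run_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing_f <- setdiff(.REPORT_FIELDS, names(x))
  if (length(missing_f) > 0)
    stopf("report file lacks field(s): %s", paste(missing_f, collapse = ", "))
  x$counts <- unlist(x$counts)
  x$composition <- as.data.frame(x$composition)
  structure(x, class = "run_report")
}
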