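# Pipeline orchestration: pose analysis (pocket -> perception -> all
# detectors -> contact table) and trajectory analysis (RMSD/RMSF/occupancy),
# with deterministic TSV/JSON report bundles. Log messages go to stderr with
# stage tags; machine-readable output only to files.

.stage <- function(tag, ...) message("[", tag, "] ", ...)

#' Pipeline run configuration
#'
#' @param complex_path PDB file of the pose (or NULL when a `complex` object
#'   is passed to the run functions directly).
#' @param trajectory_path multi-model PDB trajectory (trajectory runs).
#' @param ligand ligand selector (residue name or `"chain:resno"`).
#' @param radius binding-sphere pocket radius, A (default 4).
#' @param tie_threshold TIE inclusion threshold, kcal/mol (default 3).
#' @param criteria a \code{\link{geometric_criteria}} list.
#' @param keep_waters keep crystallographic waters when reading the pose.
#' @param seed integer seed recorded in outputs.
#' @param out_dir output directory (created if missing).
#' @return list of class `run_config`.
#' @export
run_config <- function(complex_path = NULL, trajectory_path = NULL,
                       ligand = "LIG", radius = 4.0, tie_threshold = 3.0,
                       criteria = geometric_criteria(), keep_waters = TRUE,
                       seed = 1L, out_dir = ".") {
  stopifnot(radius > 0, tie_threshold >= 0)
  structure(list(complex_path = complex_path,
                 trajectory_path = trajectory_path, ligand = ligand,
                 radius = radius, tie_threshold = tie_threshold,
                 criteria = criteria, keep_waters = keep_waters,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a JSON file
#'
#' A single JSON object; keys are \code{\link{run_config}} argument names,
#' with `criteria` given as a nested object of threshold overrides.
#'
#' @param path JSON file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$criteria)) cfg$criteria <- do.call(geometric_criteria, cfg$criteria)
  bad <- setdiff(names(cfg), names(formals(run_config)))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, cfg)
}

#' Export interaction records
#'
#' `write_records_tsv` emits one record per row with the fixed geometry
#' columns; `write_records_json` the same as a JSON array.
#'
#' @param records detector output.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_records_tsv <- function(records, path) {
  utils::write.table(records[, RECORD_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_records_tsv
#' @export
write_records_json <- function(records, path) {
  jsonlite::write_json(records[, RECORD_COLS], path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Run the pose-analysis pipeline
#'
#' Pocket extraction -> chemistry perception -> all detectors (including the
#' docking proton-heteroatom scan) -> contact table. Writes `contacts.tsv`
#' (all records), `contact_table.tsv` (per-residue minimum-distance
#' summary) and `summary.json` into `config$out_dir`. Outputs are pure
#' functions of (inputs, config): reruns are byte-identical.
#'
#' @param config a \code{\link{run_config}}.
#' @param complex optional `plcomplex` overriding `config$complex_path`.
#' @return (invisibly) list with `pocket`, `records`, `contact_table` and
#'   the output paths.
#' @export
run_pose_analysis <- function(config, complex = NULL) {
  if (is.null(complex)) {
    .stage("read", "reading complex from ", config$complex_path)
    complex <- read_complex(config$complex_path, config$ligand,
                            keep_waters = config$keep_waters)
  }
  .stage("pocket", "extracting pocket at ", config$radius, " A")
  pocket <- extract_pocket(complex, config$radius)
  if (is.null(pocket$chemistry)) pocket <- perceive(pocket)
  .stage("detect", "running interaction detectors")
  rec <- detect_all(pocket, config$criteria, include_docking = TRUE)
  res_keys <- unique(rec$residue_key[!is.na(rec$residue_key)])
  tab <- contact_distance_table(pocket, res_keys, config$criteria)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    contacts = file.path(config$out_dir, "contacts.tsv"),
    table = file.path(config$out_dir, "contact_table.tsv"),
    summary = file.path(config$out_dir, "summary.json"))
  write_records_tsv(rec, paths$contacts)
  utils::write.table(tab, paths$table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(
    seed = config$seed, radius = config$radius,
    n_pocket_residues = sum(residue_table(pocket)$moiety == "protein"),
    n_records = nrow(rec),
    records_by_kind = as.list(table(rec$kind))),
    paths$summary, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .stage("done", nrow(rec), " records over ", length(res_keys), " residues")
  invisible(list(pocket = pocket, records = rec, contact_table = tab,
                 paths = paths))
}

#' Run the trajectory-analysis pipeline
#'
#' Reads the trajectory, computes both ligand RMSD modes, per-residue
#' backbone RMSF and the interaction occupancy profile, and writes
#' `rmsd.tsv`, `rmsf.tsv`, `occupancy.tsv` plus the histogram-ready
#' interaction-diagram JSON (`diagram.json`, per-residue stacked fractions
#' by kind).
#'
#' @param config a \code{\link{run_config}} (`complex_path` gives the
#'   topology unless `trajectory` is supplied).
#' @param trajectory optional `pltrajectory` overriding the config paths.
#' @return (invisibly) list with `rmsd` (both series), `rmsf`, `profile`
#'   and the output paths.
#' @export
run_trajectory_analysis <- function(config, trajectory = NULL) {
  if (is.null(trajectory)) {
    .stage("read", "reading topology from ", config$complex_path)
    topo <- read_complex(config$complex_path, config$ligand,
                         keep_waters = config$keep_waters)
    .stage("read", "reading trajectory from ", config$trajectory_path)
    trajectory <- read_trajectory(config$trajectory_path, topo)
  }
  .stage("rmsd", "ligand RMSD (both alignment modes)")
  r1 <- ligand_rmsd(trajectory, "lig_fit_protein")
  r2 <- ligand_rmsd(trajectory, "lig_fit_lig")
  rmsf <- if (n_frames(trajectory) >= 2) {
    .stage("rmsf", "per-residue backbone RMSF")
    residue_rmsf(trajectory)
  } else NULL
  .stage("occupancy", "per-residue interaction occupancy over ",
         n_frames(trajectory), " frames")
  prof <- occupancy(trajectory, config$criteria)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(rmsd = file.path(config$out_dir, "rmsd.tsv"),
                rmsf = file.path(config$out_dir, "rmsf.tsv"),
                occupancy = file.path(config$out_dir, "occupancy.tsv"),
                diagram = file.path(config$out_dir, "diagram.json"))
  utils::write.table(
    data.frame(time = trajectory$times, lig_fit_protein = r1$values,
               lig_fit_lig = r2$values),
    paths$rmsd, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(rmsf)) write_rmsf_tsv(rmsf, paths$rmsf)
  write_occupancy_tsv(prof, paths$occupancy)
  write_diagram_json(prof, paths$diagram)
  .stage("done", "trajectory analysis complete")
  invisible(list(rmsd = list(lig_fit_protein = r1, lig_fit_lig = r2),
                 rmsf = rmsf, profile = prof, paths = paths))
}
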