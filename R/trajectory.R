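# Trajectory analytics: ligand RMSD in two alignment modes, per-residue
# backbone RMSF about the mean structure, and per-residue interaction
# occupancy profiles. Heavy atoms only throughout; hydrogen positions are
# noise-dominated.

# xyz-index helper (atom rows -> flat xyz indices, bio3d layout)
.xyz_idx <- function(atom_rows) as.numeric(t(outer(3 * (atom_rows - 1), 1:3, "+")))

.backbone_rows <- function(cx) {
  at <- cx$atoms
  which(at$moiety == "protein" & !at$is_h & at$elety %in% c("N", "CA", "C"))
}

.ligand_heavy_rows <- function(cx) {
  at <- cx$atoms
  which(at$moiety == "ligand" & !at$is_h)
}

.row_rmsd <- function(xyz_a, xyz_b) {
  d <- matrix(xyz_a - xyz_b, ncol = 3, byrow = TRUE)
  sqrt(mean(rowSums(d^2)))
}

#' Ligand RMSD along a trajectory
#'
#' Two alignment modes:
#' \describe{
#'   \item{lig_fit_protein}{each frame's protein backbone (N, CA, C) is
#'     least-squares superposed onto the reference frame's backbone; the
#'     RMSD is then taken over ligand heavy atoms with no further fitting.
#'     Measures ligand stability relative to the protein and its pocket.}
#'   \item{lig_fit_lig}{the frame's ligand heavy atoms are superposed onto
#'     the reference ligand and the residual RMSD reported: the ligand's
#'     internal fluctuation, zero at the reference frame.}
#' }
#'
#' @param traj a \code{\link{pltrajectory}}.
#' @param mode `"lig_fit_protein"` or `"lig_fit_lig"`.
#' @param reference_frame index of the reference frame (default 1).
#' @return object of class `rmsd_series`: list with `mode`, `values` (A, one
#'   per frame; 0 at the reference), `times` (ps), `reference_frame`.
#' @export
ligand_rmsd <- function(traj, mode = c("lig_fit_protein", "lig_fit_lig"),
                        reference_frame = 1L) {
  mode <- match.arg(mode)
  stopifnot(reference_frame >= 1, reference_frame <= n_frames(traj))
  lig <- .ligand_heavy_rows(traj$topology)
  if (length(lig) < 3) stop("ligand has fewer than 3 heavy atoms")
  fit_rows <- if (mode == "lig_fit_protein") .backbone_rows(traj$topology) else lig
  if (length(fit_rows) < 3) stop("alignment needs at least 3 atoms")
  ref <- traj$xyz[reference_frame, ]
  assert_fittable(matrix(ref[.xyz_idx(fit_rows)], ncol = 3, byrow = TRUE))
  fit_xyz <- .xyz_idx(fit_rows)
  lig_xyz <- .xyz_idx(lig)
  moved <- bio3d::fit.xyz(fixed = ref, mobile = traj$xyz,
                          fixed.inds = fit_xyz, mobile.inds = fit_xyz)
  moved <- matrix(moved, nrow = n_frames(traj))
  vals <- vapply(seq_len(n_frames(traj)), function(f)
    .row_rmsd(moved[f, lig_xyz], ref[lig_xyz]), 1.0)
  vals[reference_frame] <- 0
  structure(list(mode = mode, values = vals, times = traj$times,
                 reference_frame = reference_frame),
            class = "rmsd_series")
}

#' Per-residue backbone RMSF about the mean structure
#'
#' Every frame's backbone is superposed onto the time-mean structure (the
#' mean is refined by a second fit iteration), then the RMSF of residue r is
#' the root mean square, over frames and over r's backbone atoms, of the
#' displacement from the mean position.
#'
#' @param traj a `pltrajectory` with >= 2 frames.
#' @return named numeric vector, residue_key -> RMSF (A), protein residues
#'   in sequence order.
#' @export
residue_rmsf <- function(traj) {
  if (n_frames(traj) < 2) stop("RMSF needs at least 2 frames")
  bb <- .backbone_rows(traj$topology)
  if (length(bb) < 3) stop("alignment needs at least 3 backbone atoms")
  bb_xyz <- .xyz_idx(bb)
  assert_fittable(matrix(traj$xyz[1, bb_xyz], ncol = 3, byrow = TRUE))
  moved <- traj$xyz
  for (it in 1:2) {
    mn <- colMeans(moved)
    moved <- bio3d::fit.xyz(fixed = mn, mobile = moved,
                            fixed.inds = bb_xyz, mobile.inds = bb_xyz)
    moved <- matrix(moved, nrow = n_frames(traj))
  }
  mn <- colMeans(moved)
  at <- traj$topology$atoms
  keys <- unique(at$residue_key[bb])
  out <- vapply(keys, function(k) {
    rows <- bb[at$residue_key[bb] == k]
    idx <- .xyz_idx(rows)
    dev <- sweep(moved[, idx, drop = FALSE], 2, mn[idx])
    # rows of dev are frames; regroup into (frames*atoms) x 3 displacement rows
    sqrt(mean(rowSums(matrix(as.numeric(t(dev)), ncol = 3, byrow = TRUE)^2)))
  }, 1.0)
  names(out) <- keys
  out
}

#' Interaction occupancy profile over a trajectory
#'
#' Runs all six detectors on every frame; a (residue, kind) pair is present
#' in a frame iff at least one record of that kind touches that residue
#' (binary presence, not instance multiplicity). The occupancy is the
#' fraction of frames present.
#'
#' @param traj a `pltrajectory` whose topology is perceived (or perceivable;
#'   \code{\link{perceive}} is applied when chemistry is missing).
#' @param criteria a \code{\link{geometric_criteria}} list.
#' @param quantifier acceptor-angle quantifier for H-bonds/bridges.
#' @return object of class `occupancy_profile`: data.frame (residue_key,
#'   kind, fraction) with attribute `n_frames`; pairs never observed are
#'   absent (query with \code{\link{occupancy_of}}).
#' @export
occupancy <- function(traj, criteria = geometric_criteria(),
                      quantifier = c("every", "any")) {
  quantifier <- match.arg(quantifier)
  topo <- traj$topology
  if (is.null(topo$chemistry)) topo <- perceive(topo)
  nf <- n_frames(traj)
  counts <- new.env(parent = emptyenv())
  for (f in seq_len(nf)) {
    cx <- set_coords(topo, traj$xyz[f, ])
    rec <- detect_all(cx, criteria, quantifier = quantifier)
    if (!nrow(rec)) next
    seen <- unique(paste(rec$residue_key, rec$kind, sep = "\r"))
    for (s in seen) {
      prev <- counts[[s]]
      counts[[s]] <- if (is.null(prev)) 1L else prev + 1L
    }
  }
  keys <- sort(ls(counts))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    residue_key = vapply(parts, `[`, "", 1),
    kind = vapply(parts, `[`, "", 2),
    fraction = vapply(keys, function(k) counts[[k]] / nf, 1.0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_frames") <- nf
  class(out) <- c("occupancy_profile", "data.frame")
  out
}

#' Query an occupancy profile
#'
#' @param profile an `occupancy_profile`.
#' @param residue_key,kind the entry to look up.
#' @return the fraction in \[0, 1\]; 0 for pairs never observed.
#' @export
occupancy_of <- function(profile, residue_key, kind) {
  hit <- profile$fraction[profile$residue_key == residue_key &
                          profile$kind == kind]
  if (length(hit)) hit[1] else 0
}

# TSV / JSON exports ----------------------------------------------------------

#' Export trajectory statistics
#'
#' `write_rmsd_tsv` emits (time, value); `write_rmsf_tsv` (residue, value);
#' `write_occupancy_tsv` (residue, kind, fraction);
#' `occupancy_diagram` builds the histogram-ready per-residue stacked
#' fraction structure (residue -> kind -> fraction) used for
#' interaction-diagram plots, which `write_diagram_json` serialises.
#'
#' @param series,rmsf,profile objects from \code{\link{ligand_rmsd}},
#'   \code{\link{residue_rmsf}}, \code{\link{occupancy}}.
#' @param path output file.
#' @return `path` (writers, invisibly); a nested list (`occupancy_diagram`).
#' @export
write_rmsd_tsv <- function(series, path) {
  utils::write.table(data.frame(time = series$times, value = series$values),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rmsd_tsv
#' @export
write_rmsf_tsv <- function(rmsf, path) {
  utils::write.table(data.frame(residue = names(rmsf), value = unname(rmsf)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rmsd_tsv
#' @export
write_occupancy_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_rmsd_tsv
#' @export
occupancy_diagram <- function(profile) {
  res <- unique(profile$residue_key)
  lst <- lapply(res, function(rk) {
    sub <- profile[profile$residue_key == rk, , drop = FALSE]
    stats::setNames(as.list(sub$fraction), sub$kind)
  })
  list(n_frames = attr(profile, "n_frames"),
       residues = stats::setNames(lst, res))
}

#' @rdname write_rmsd_tsv
#' @export
write_diagram_json <- function(profile, path) {
  jsonlite::write_json(occupancy_diagram(profile), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
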