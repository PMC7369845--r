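# PDB input/output. Parsing is delegated to bio3d::read.pdb; this layer adds
# the package contracts: ligand/water/protein partitioning, altloc policy,
# hydrogen->parent linking, per-MODEL validation, REMARK TIME frames, and
# fixed-column writers (3-decimal coordinates) whose output round-trips.

#' Read a protein-ligand complex from a PDB file
#'
#' ATOM/HETATM records are partitioned into protein, ligand and waters
#' (residue names HOH/WAT/...). Hydrogens are linked to their covalent heavy
#' atom by the nearest-heavy rule (H-X <= 1.2 A). Alternate locations other
#' than 'A' or blank are dropped with a warning. No record is silently lost:
#' atoms in == atoms partitioned (after the stated altloc policy).
#'
#' @param path PDB file.
#' @param ligand ligand selector passed to \code{\link{plcomplex}}: residue
#'   name or `"chain:resno"`. Must match exactly one residue.
#' @param keep_waters keep water residues (default TRUE). Docking-style
#'   workflows that discard crystallographic waters can set FALSE.
#' @return a \code{\link{plcomplex}}.
#' @export
read_complex <- function(path, ligand, keep_waters = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- .bio3d_atoms(pdb)
  if (!keep_waters) at <- at[!(toupper(at$resid) %in% WATER_NAMES), , drop = FALSE]
  plcomplex(at, ligand)
}

# bio3d atom table -> plcomplex atom columns, with altloc policy applied.
.bio3d_atoms <- function(pdb) {
  a <- pdb$atom
  drop <- !(a$alt %in% c("", " ", NA, "A"))
  if (any(drop)) {
    warning(sum(drop), " alternate-location atom(s) dropped (kept altloc 'A'/blank)")
    a <- a[!drop, , drop = FALSE]
  }
  elesy <- a$elesy
  blank <- is.na(elesy) | elesy == ""
  if (any(blank)) elesy[blank] <- .element_from_name(a$elety[blank])
  fc <- .parse_formal_charge(a$charge)
  data.frame(eleno = a$eleno, elety = a$elety, elesy = toupper(elesy),
             resid = a$resid, chain = ifelse(is.na(a$chain), "A", a$chain),
             resno = a$resno, x = a$x, y = a$y, z = a$z,
             formal_charge = fc, stringsAsFactors = FALSE)
}

# PDB element column absent: first alphabetic character of the atom name,
# honouring the 2-char names that matter here (no metals expected).
.element_from_name <- function(name) {
  nm <- toupper(gsub("[^A-Z]", "", toupper(name)))
  el <- substr(nm, 1, 1)
  el[substr(nm, 1, 2) %in% c("CL", "BR")] <- substr(nm, 1, 2)[substr(nm, 1, 2) %in% c("CL", "BR")]
  el
}

# PDB charge field "1+", "2-" (or already numeric) -> signed integer.
.parse_formal_charge <- function(ch) {
  if (is.null(ch)) return(0L)
  out <- rep.int(0L, length(ch))
  ok <- !is.na(ch) & ch != ""
  v <- ch[ok]
  num <- suppressWarnings(as.integer(gsub("[+-]", "", v)))
  num[is.na(num)] <- 0L
  sgn <- ifelse(grepl("-", v, fixed = TRUE), -1L, 1L)
  out[ok] <- num * sgn
  out
}

#' Write a complex as a fixed-column PDB file
#'
#' Emits ATOM records for protein atoms and HETATM for ligand/waters,
#' 3-decimal coordinates, deterministic order (input atom order). Formal
#' charges are written in PDB columns 79-80 so they round-trip.
#'
#' @param cx a `plcomplex`.
#' @param path output file.
#' @param remarks optional character vector written as leading REMARK lines.
#' @return `path`, invisibly.
#' @export
write_complex <- function(cx, path, remarks = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(remarks)) writeLines(paste("REMARK  ", remarks), con)
  writeLines(.pdb_atom_lines(cx$atoms), con)
  writeLines("END", con)
  invisible(path)
}

.pdb_atom_lines <- function(at) {
  rec <- ifelse(at$moiety == "protein", "ATOM  ", "HETATM")
  fc <- at$formal_charge
  chg <- ifelse(fc == 0, "  ", paste0(abs(fc), ifelse(fc > 0, "+", "-")))
  name4 <- ifelse(nchar(at$elety) >= 4, substr(at$elety, 1, 4),
                  sprintf(" %-3s", at$elety))
  sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s%2s",
          rec, at$eleno %% 100000L, name4, substr(at$resid, 1, 3),
          substr(at$chain, 1, 1), at$resno %% 10000L,
          at$x, at$y, at$z, 1.0, 0.0,
          sprintf("%2s", at$elesy), chg)
}

# Trajectory container --------------------------------------------------------

#' Construct a trajectory over a fixed topology
#'
#' @param topology a `plcomplex`.
#' @param xyz frames as an `(n_frames x 3*n_atoms)` matrix (bio3d layout) or
#'   a list of `(n_atoms x 3)` matrices.
#' @param times frame times in ps, strictly increasing; default `0:(n-1)`.
#' @return object of class `pltrajectory`.
#' @export
pltrajectory <- function(topology, xyz, times = NULL) {
  if (is.list(xyz) && !is.matrix(xyz))
    xyz <- do.call(rbind, lapply(xyz, function(m) as.numeric(t(m))))
  xyz <- matrix(xyz, ncol = 3L * nrow(topology$atoms))
  if (is.null(times)) times <- seq_len(nrow(xyz)) - 1
  if (length(times) != nrow(xyz))
    stop("times length differs from frame count")
  if (nrow(xyz) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(topology = topology, xyz = xyz, times = as.numeric(times)),
            class = "pltrajectory")
}

#' @export
print.pltrajectory <- function(x, ...) {
  cat("pltrajectory:", nrow(x$xyz), "frames x",
      nrow(x$topology$atoms), "atoms; t =",
      x$times[1], "...", x$times[length(x$times)], "ps\n")
  invisible(x)
}

n_frames <- function(traj) nrow(traj$xyz)

# Complex with coordinates of frame f.
frame_complex <- function(traj, f) set_coords(traj$topology, traj$xyz[f, ])

#' Read a multi-model PDB trajectory
#'
#' Every MODEL/ENDMDL block must contain the topology's atom count in the
#' topology's atom order (validated by a pre-scan that names the offending
#' model). Frame times come from per-MODEL `REMARK   TIME <ps>` lines when
#' present, else 0, 1, 2, ... ps.
#'
#' @param path multi-model PDB file.
#' @param topology `plcomplex` giving atom identities for every frame.
#' @return a \code{\link{pltrajectory}}.
#' @export
read_trajectory <- function(path, topology) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  n_top <- nrow(topology$atoms)
  if (length(model_starts)) {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL blocks")
    counts <- mapply(function(s, e) sum(is_atom[s:e]), model_starts, model_ends)
    bad <- which(counts != n_top)
    if (length(bad))
      stop("model ", bad[1], " has ", counts[bad[1]],
           " atoms; topology has ", n_top)
  } else if (sum(is_atom) != n_top) {
    stop("file has ", sum(is_atom), " atoms; topology has ", n_top)
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  xyz <- matrix(pdb$xyz, ncol = 3L * n_top)
  nf <- nrow(xyz)
  tm <- .remark_times(lines)
  if (is.null(tm)) tm <- seq_len(nf) - 1
  if (length(tm) != nf)
    stop("found ", length(tm), " REMARK TIME lines for ", nf, " models")
  pltrajectory(topology, xyz, tm)
}

.remark_times <- function(lines) {
  tl <- grep("^REMARK\\s+TIME\\s", lines, value = TRUE)
  if (!length(tl)) return(NULL)
  as.numeric(sub("^REMARK\\s+TIME\\s+([-0-9.eE+]+).*$", "\\1", tl))
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame, each preceded by a
#' `REMARK   TIME <ps>` line; deterministic fixed-column output.
#'
#' @param traj a `pltrajectory`.
#' @param path output file.
#' @param remarks optional leading REMARK lines (e.g. generator seed).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, remarks = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(remarks)) writeLines(paste("REMARK  ", remarks), con)
  at <- traj$topology$atoms
  for (f in seq_len(n_frames(traj))) {
    m <- matrix(traj$xyz[f, ], ncol = 3, byrow = TRUE)
    at$x <- m[, 1]; at$y <- m[, 2]; at$z <- m[, 3]
    writeLines(sprintf("REMARK   TIME %.4f", traj$times[f]), con)
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(.pdb_atom_lines(at), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
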