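# The plcomplex container: one annotated protein-ligand(-water) complex.
# Atoms live in a flat data.frame (one row per atom); residues are implicit
# in (chain, resno, resid). Chemistry perception attaches a second list (see
# perceive.R).

WATER_NAMES <- c("HOH", "WAT", "TIP", "TIP3", "TIP4", "SOL", "H2O")
BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")

#' Construct a protein-ligand complex
#'
#' @param atoms data.frame with columns `eleno` (serial, unique), `elety`
#'   (atom name), `elesy` (element symbol), `resid` (3-letter residue code),
#'   `chain`, `resno`, `x`, `y`, `z`, and optionally `formal_charge`
#'   (integer, default 0). Moiety assignment: the residue matching
#'   `ligand` is the ligand, residues named in `WATER_NAMES` are waters,
#'   everything else is protein.
#' @param ligand ligand selector: a residue name (e.g. `"LIG"`) or a
#'   `"chain:resno"` string. Must match exactly one residue.
#' @return object of class `plcomplex`: list with `atoms` (the data.frame,
#'   plus `moiety`, `is_h`, `parent`, `residue_key` columns), `chemistry`
#'   (NULL until \code{\link{perceive}} is run) and `termini_ionized` flag.
#' @export
plcomplex <- function(atoms, ligand) {
  need <- c("eleno", "elety", "elesy", "resid", "chain", "resno",
            "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  atoms$resno <- as.integer(atoms$resno)
  atoms$eleno <- as.integer(atoms$eleno)
  if (is.null(atoms$formal_charge)) atoms$formal_charge <- 0L
  atoms$formal_charge[is.na(atoms$formal_charge)] <- 0L
  if (anyDuplicated(atoms$eleno))
    stop("atom serial numbers (eleno) must be unique within a complex")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")

  rk <- paste0(toupper(atoms$resid), atoms$resno)
  # disambiguate residues duplicated across chains
  full <- paste(atoms$chain, rk)
  if (length(unique(full[!duplicated(paste(atoms$chain, atoms$resno, atoms$resid))])) >
      length(unique(rk[!duplicated(paste(atoms$chain, atoms$resno, atoms$resid))]))) {
    dup_rk <- unique(rk[ave(seq_along(rk), rk, FUN = function(i)
      length(unique(atoms$chain[i])))[seq_along(rk)] > 1])
    sel <- rk %in% dup_rk
    rk[sel] <- paste0(rk[sel], "_", atoms$chain[sel])
  }
  atoms$residue_key <- rk

  lig_mask <- .match_ligand(atoms, ligand)
  atoms$moiety <- ifelse(lig_mask, "ligand",
                  ifelse(toupper(atoms$resid) %in% WATER_NAMES, "water",
                         "protein"))
  atoms$is_h <- toupper(atoms$elesy) == "H"
  atoms$parent <- NA_integer_
  cx <- structure(list(atoms = atoms, chemistry = NULL,
                       termini_ionized = FALSE),
                  class = "plcomplex")
  cx <- .assign_h_parents(cx)
  cx
}

# Resolve a ligand selector to a per-atom logical mask; exactly one residue.
.match_ligand <- function(atoms, ligand) {
  res_id <- paste(atoms$chain, atoms$resno, toupper(atoms$resid))
  if (grepl(":", ligand, fixed = TRUE)) {
    parts <- strsplit(ligand, ":", fixed = TRUE)[[1]]
    mask <- atoms$chain == parts[1] & atoms$resno == as.integer(parts[2])
  } else {
    mask <- toupper(atoms$resid) == toupper(ligand)
  }
  n_res <- length(unique(res_id[mask]))
  if (n_res == 0L)
    stop("ligand selector '", ligand, "' matches no residue")
  if (n_res > 1L)
    stop("ligand selector '", ligand, "' is ambiguous: matches ",
         n_res, " residues")
  mask
}

# Link every hydrogen to its covalently bonded heavy atom (nearest heavy
# within 1.2 A); CONECT records are optional in PDB so distance is the rule.
.assign_h_parents <- function(cx) {
  at <- cx$atoms
  hs <- which(at$is_h)
  if (!length(hs)) return(cx)
  heavies <- which(!at$is_h)
  if (!length(heavies)) stop("complex contains hydrogens but no heavy atoms")
  hxyz <- as.matrix(at[hs, c("x", "y", "z")])
  gxyz <- as.matrix(at[heavies, c("x", "y", "z")])
  dm <- cross_dist(hxyz, gxyz)
  nearest <- apply(dm, 1, which.min)
  dmin <- dm[cbind(seq_along(hs), nearest)]
  bad <- dmin > 1.2 + .EPS
  if (any(bad))
    stop("hydrogen(s) with no heavy atom within 1.2 A: serial ",
         paste(at$eleno[hs[bad]], collapse = ", "))
  at$parent[hs] <- at$eleno[heavies[nearest]]
  cx$atoms <- at
  cx
}

#' @export
print.plcomplex <- function(x, ...) {
  at <- x$atoms
  n_res <- function(m) length(unique(at$residue_key[at$moiety == m]))
  cat("plcomplex:", nrow(at), "atoms |",
      n_res("protein"), "protein residues |",
      sum(at$moiety == "ligand"), "ligand atoms (",
      unique(at$residue_key[at$moiety == "ligand"]), ") |",
      n_res("water"), "waters |",
      if (is.null(x$chemistry)) "chemistry: not perceived" else "chemistry: perceived",
      "\n")
  invisible(x)
}

# Coordinate accessors -------------------------------------------------------

coords_of <- function(cx, serials) {
  idx <- match(serials, cx$atoms$eleno)
  if (anyNA(idx)) stop("unknown atom serial(s): ",
                       paste(serials[is.na(idx)], collapse = ", "))
  as.matrix(cx$atoms[idx, c("x", "y", "z"), drop = FALSE])
}

#' Replace all coordinates of a complex (e.g. with one trajectory frame)
#'
#' @param cx a `plcomplex`.
#' @param xyz numeric vector of length `3 * n_atoms` (x1,y1,z1,x2,...) or an
#'   `(n_atoms x 3)` matrix, in the complex's atom order.
#' @return the complex with updated coordinates; perceived chemistry
#'   memberships remain valid (geometric quantities are recomputed by the
#'   detectors from current coordinates).
#' @export
set_coords <- function(cx, xyz) {
  n <- nrow(cx$atoms)
  m <- if (is.matrix(xyz)) xyz else matrix(xyz, ncol = 3, byrow = TRUE)
  if (nrow(m) != n) stop("coordinate set has ", nrow(m),
                         " atoms, complex has ", n)
  cx$atoms$x <- m[, 1]; cx$atoms$y <- m[, 2]; cx$atoms$z <- m[, 3]
  cx
}

# Flat xyz vector (bio3d order: x1,y1,z1,x2,...).
flat_coords <- function(cx) {
  as.numeric(t(as.matrix(cx$atoms[, c("x", "y", "z")])))
}

# Residue table: one row per residue with moiety and atom index list.
residue_table <- function(cx) {
  at <- cx$atoms
  idx <- split(seq_len(nrow(at)), at$residue_key)
  keys <- names(idx)
  ord <- order(vapply(idx, min, 1L))
  keys <- keys[ord]; idx <- idx[ord]
  data.frame(residue_key = keys,
             chain = vapply(idx, function(i) at$chain[i[1]], ""),
             resno = vapply(idx, function(i) as.integer(at$resno[i[1]]), 1L),
             resid = vapply(idx, function(i) at$resid[i[1]], ""),
             moiety = vapply(idx, function(i) at$moiety[i[1]], ""),
             first_atom = vapply(idx, min, 1L),
             row.names = NULL)
}
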