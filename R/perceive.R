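# Chemistry perception: annotate a complex with the roles the geometric
# interaction criteria consume -- H-bond donors/acceptors, aromatic rings,
# charged groups, hydrophobic atoms -- plus termini ionisation and binding
# pocket extraction.
#
# Protein roles come from a fixed lookup over the 20 standard residues (+
# water); ligand roles from element/connectivity heuristics on a
# distance-derived bond graph. His is neutral by default (both ring N
# acceptors); set `his_protonated` for the doubly protonated form.

#' Perception options
#'
#' @param explicit_h expect explicit hydrogens; when TRUE, polar atoms that
#'   should donate but carry no H trigger a warning (never an error).
#' @param his_protonated treat histidine as doubly protonated (+1 charged
#'   group, ring N donors when H present) instead of the neutral acceptor
#'   form.
#' @param planarity_tol max RMS out-of-plane deviation (A) for a 5/6-membered
#'   ligand ring to count as aromatic. The 0.1 A default separates planar
#'   (hetero)aromatic rings from puckered aliphatic ones on idealized
#'   geometries.
#' @return list of class `perception_options`.
#' @export
perception_options <- function(explicit_h = TRUE, his_protonated = FALSE,
                               planarity_tol = 0.1) {
  structure(list(explicit_h = explicit_h, his_protonated = his_protonated,
                 planarity_tol = planarity_tol),
            class = "perception_options")
}

# Sidechain acceptor atom names per residue (neutral His handled separately).
.SC_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", MET = "SD"
)

# Aromatic ring member atom names per residue.
.RING_ATOMS <- list(
  PHE = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
  TYR = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CE2", "CD2", "CE3", "CZ3", "CH2", "CZ2")),
  HIS = list(c("CG", "ND1", "CE1", "NE2", "CD2"))
)

# Hydrophobic sidechain heavy atoms: C/S of apolar sidechains, Tyr ring
# carbons, Cys SG.
.HYDROPHOBIC_SC <- list(
  ALA = "CB", VAL = c("CB", "CG1", "CG2"), LEU = c("CB", "CG", "CD1", "CD2"),
  ILE = c("CB", "CG1", "CG2", "CD1"), PRO = c("CB", "CG", "CD"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CB", "CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  CYS = "SG"
)

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

#' Perceive interaction chemistry of a complex
#'
#' Assigns H-bond donors (heavy atom + attached hydrogen pairs), acceptors
#' with their bonded neighbors (the X of the H...A-X acceptor angle),
#' aromatic rings (with centroid/normal computed from current coordinates),
#' positively/negatively charged groups, and hydrophobic atoms.
#'
#' Ligand heuristics: N/O bearing a hydrogen donate; pyridinic N (no H,
#' <= 2 heavy neighbors) and any O accept; 5/6-membered planar rings whose
#' members are all sp2-like (<= 3 neighbors) are aromatic; carbons bonded
#' only to C/H/S are hydrophobic; formal charges come from the input file
#' annotations (no pKa model).
#'
#' Deterministic and idempotent: re-perceiving replaces the annotation with
#' an identical one.
#'
#' @param cx a \code{\link{plcomplex}}.
#' @param options a \code{\link{perception_options}} list.
#' @return the complex with a `chemistry` element: list with `donors`
#'   (data.frame d, h, owner, residue_key), `acceptors` (a, owner,
#'   residue_key), `acceptor_neighbors` (a, x), `rings` (list: members,
#'   owner, residue_key, id), `charges` (data.frame id, sign, owner,
#'   residue_key + list-column site_atoms), `hydrophobic` (serial, owner,
#'   residue_key), `bonds` (i, j serial pairs).
#' @export
perceive <- function(cx, options = perception_options()) {
  at <- cx$atoms
  bonds <- .heavy_bonds(cx)
  donors <- .perceive_donors(cx, options)
  acceptors <- .perceive_acceptors(cx, bonds, options)
  rings <- .perceive_rings(cx, bonds, options)
  charges <- .perceive_charges(cx, options)
  hydrophobic <- .perceive_hydrophobic(cx, bonds)
  nb <- .acceptor_neighbors(cx, bonds, acceptors)
  cx$chemistry <- list(donors = donors, acceptors = acceptors,
                       acceptor_neighbors = nb, rings = rings,
                       charges = charges, hydrophobic = hydrophobic,
                       bonds = bonds, options = options)
  cx
}

# Heavy-atom bond list from interatomic distances (same moiety only; peptide
# bonds captured by the distance rule). Cutoff 1.75 A, 2.1 A if S/P involved.
.heavy_bonds <- function(cx) {
  at <- cx$atoms
  hv <- which(!at$is_h)
  if (length(hv) < 2)
    return(data.frame(i = integer(), j = integer()))
  xyz <- as.matrix(at[hv, c("x", "y", "z")])
  pr <- neighbor_pairs(xyz, xyz, 2.1)
  pr <- pr[pr$i < pr$j, , drop = FALSE]
  if (!nrow(pr)) return(data.frame(i = integer(), j = integer()))
  ei <- at$elesy[hv[pr$i]]; ej <- at$elesy[hv[pr$j]]
  lim <- ifelse(ei %in% c("S", "P") | ej %in% c("S", "P"), 2.1, 1.75)
  same <- at$moiety[hv[pr$i]] == at$moiety[hv[pr$j]]
  keep <- same & pr$d <= lim + .EPS
  data.frame(i = at$eleno[hv[pr$i[keep]]], j = at$eleno[hv[pr$j[keep]]])
}

# serial -> serials of bonded heavy atoms
.bonded_heavies <- function(bonds, serial) {
  c(bonds$j[bonds$i == serial], bonds$i[bonds$j == serial])
}

.perceive_donors <- function(cx, options) {
  at <- cx$atoms
  hs <- at[at$is_h, , drop = FALSE]
  out <- data.frame(d = integer(), h = integer(), owner = character(),
                    residue_key = character())
  if (nrow(hs)) {
    par_idx <- match(hs$parent, at$eleno)
    polar <- at$elesy[par_idx] %in% c("N", "O", "S")
    if (any(polar)) {
      out <- data.frame(d = hs$parent[polar], h = hs$eleno[polar],
                        owner = at$moiety[par_idx[polar]],
                        residue_key = at$residue_key[par_idx[polar]],
                        stringsAsFactors = FALSE)
    }
  }
  if (options$explicit_h) {
    # polar ligand/protein N-H expected: warn when a ligand N/O has no H at all
    lig <- at[at$moiety == "ligand" & !at$is_h & at$elesy %in% c("N", "O"), ]
    if (nrow(lig) && !any(out$owner == "ligand") && sum(at$is_h) == 0)
      warning("explicit-H mode but no hydrogens found; donor perception empty")
  }
  out
}

.perceive_acceptors <- function(cx, bonds, options) {
  at <- cx$atoms
  acc <- integer(0)
  # protein: backbone O/OXT + sidechain lookup (+ neutral His ring N)
  prot <- at[at$moiety == "protein" & !at$is_h, , drop = FALSE]
  if (nrow(prot)) {
    bb <- prot$eleno[prot$elety %in% c("O", "OXT")]
    sc <- unlist(lapply(seq_len(nrow(prot)), function(k) {
      nm <- toupper(prot$resid[k])
      if (nm == "HIS" && !options$his_protonated &&
          prot$elety[k] %in% c("ND1", "NE2")) return(prot$eleno[k])
      if (prot$elety[k] %in% .SC_ACCEPTORS[[nm]]) return(prot$eleno[k])
      NULL
    }))
    acc <- c(acc, bb, sc)
  }
  # ligand: any O; N without H and <= 2 heavy neighbors (pyridinic)
  lig <- at[at$moiety == "ligand" & !at$is_h, , drop = FALSE]
  if (nrow(lig)) {
    has_h <- lig$eleno %in% at$parent[at$is_h]
    n_heavy <- vapply(lig$eleno, function(s) length(.bonded_heavies(bonds, s)), 1L)
    acc <- c(acc, lig$eleno[lig$elesy == "O"],
             lig$eleno[lig$elesy == "N" & !has_h & n_heavy <= 2])
  }
  # waters: O accepts
  wat <- at[at$moiety == "water" & at$elesy == "O", , drop = FALSE]
  acc <- unique(c(acc, wat$eleno))
  idx <- match(acc, at$eleno)
  data.frame(a = acc, owner = at$moiety[idx], residue_key = at$residue_key[idx],
             stringsAsFactors = FALSE)
}

# X neighbors for the acceptor angle: bonded heavy atoms; for acceptors with
# no bonded heavy (water O) fall back to their own hydrogens; acceptors with
# no neighbor at all pass the angle test vacuously (logged by detectors).
.acceptor_neighbors <- function(cx, bonds, acceptors) {
  at <- cx$atoms
  out <- list()
  for (a in acceptors$a) {
    xs <- .bonded_heavies(bonds, a)
    if (!length(xs)) xs <- at$eleno[at$is_h & at$parent == a & !is.na(at$parent)]
    if (length(xs)) out[[length(out) + 1L]] <- data.frame(a = a, x = xs)
  }
  if (!length(out)) return(data.frame(a = integer(), x = integer()))
  do.call(rbind, out)
}

.perceive_rings <- function(cx, bonds, options) {
  at <- cx$atoms
  rings <- list()
  add <- function(members, owner, rk) {
    rings[[length(rings) + 1L]] <<- list(
      id = length(rings) + 1L, members = members, owner = owner,
      residue_key = rk)
  }
  # protein rings from the residue lookup
  rt <- residue_table(cx)
  for (k in which(rt$moiety == "protein")) {
    nm <- toupper(rt$resid[k])
    for (names_k in .RING_ATOMS[[nm]]) {
      sel <- at$residue_key == rt$residue_key[k] & at$elety %in% names_k
      if (sum(sel) == length(names_k))
        add(at$eleno[sel][match(names_k, at$elety[sel])], "protein",
            rt$residue_key[k])
    }
  }
  # ligand rings: 5/6-cycles of the bond graph, planar, sp2-like members
  lig <- at[at$moiety == "ligand" & !at$is_h, , drop = FALSE]
  if (nrow(lig) >= 5) {
    cycles <- .find_cycles(bonds, lig$eleno, max_len = 6L)
    n_h <- table(factor(at$parent[at$is_h], levels = lig$eleno))
    for (cy in cycles) {
      if (length(cy) < 5) next
      pl <- ring_plane(coords_of(cx, cy))
      if (pl$rms_dev > options$planarity_tol) next
      deg <- vapply(cy, function(s)
        length(.bonded_heavies(bonds, s)) + n_h[as.character(s)], 1)
      if (any(deg > 3)) next
      add(cy, "ligand", unique(at$residue_key[match(cy, at$eleno)]))
    }
  }
  rings
}

# Enumerate simple cycles of length <= max_len among `nodes` (atom serials)
# by bounded DFS; deduplicated by sorted member set. Bond graphs here are
# tiny (ligand heavy atoms), so exhaustive search is exact and cheap.
.find_cycles <- function(bonds, nodes, max_len = 6L) {
  adj <- lapply(stats::setNames(nodes, nodes), function(s)
    intersect(.bonded_heavies(bonds, s), nodes))
  seen <- character(0)
  cycles <- list()
  walk <- function(path) {
    tip <- path[length(path)]
    for (nx in adj[[as.character(tip)]]) {
      if (nx == path[1] && length(path) >= 3) {
        key <- paste(sort(path), collapse = "-")
        if (!(key %in% seen)) {
          seen <<- c(seen, key)
          cycles[[length(cycles) + 1L]] <<- path
        }
      } else if (!(nx %in% path) && length(path) < max_len && nx > path[1]) {
        walk(c(path, nx))
      }
    }
  }
  for (s in nodes) walk(s)
  # drop cycles that are unions of smaller ones (keep 5/6 rings that are
  # chordless): a cycle with a chord is not a ring
  keep <- vapply(cycles, function(cy) {
    n_edges <- sum(vapply(cy, function(s)
      length(intersect(adj[[as.character(s)]], cy)), 1L)) / 2
    n_edges == length(cy)
  }, TRUE)
  cycles[keep]
}

.perceive_charges <- function(cx, options) {
  at <- cx$atoms
  out <- list()
  add <- function(sign, site_atoms, rk, owner) {
    out[[length(out) + 1L]] <<- list(id = length(out) + 1L, sign = sign,
                                    site_atoms = site_atoms,
                                    residue_key = rk, owner = owner)
  }
  rt <- residue_table(cx)
  for (k in which(rt$moiety == "protein")) {
    nm <- toupper(rt$resid[k]); rk <- rt$residue_key[k]
    sel <- function(nms) at$eleno[at$residue_key == rk & at$elety %in% nms]
    if (nm == "LYS" && length(sel("NZ"))) add(+1L, sel("NZ"), rk, "protein")
    if (nm == "ARG" && length(sel(c("NH1", "NH2"))) == 2)
      add(+1L, sel(c("NH1", "NH2")), rk, "protein")
    if (nm == "ASP" && length(sel(c("OD1", "OD2"))) == 2)
      add(-1L, sel(c("OD1", "OD2")), rk, "protein")
    if (nm == "GLU" && length(sel(c("OE1", "OE2"))) == 2)
      add(-1L, sel(c("OE1", "OE2")), rk, "protein")
    if (nm == "HIS" && options$his_protonated &&
        length(sel(c("ND1", "NE2"))) == 2)
      add(+1L, sel(c("ND1", "NE2")), rk, "protein")
  }
  # ionised termini (flag set by ionize_termini)
  if (isTRUE(cx$termini_ionized)) {
    prot <- rt[rt$moiety == "protein", , drop = FALSE]
    for (ch in unique(prot$chain)) {
      rr <- prot[prot$chain == ch, , drop = FALSE]
      rr <- rr[order(rr$first_atom), , drop = FALSE]
      first_rk <- rr$residue_key[1]; last_rk <- rr$residue_key[nrow(rr)]
      n_at <- at$eleno[at$residue_key == first_rk & at$elety == "N"]
      if (length(n_at)) add(+1L, n_at, first_rk, "protein")
      c_at <- at$eleno[at$residue_key == last_rk & at$elety %in% c("O", "OXT")]
      if (length(c_at)) add(-1L, c_at, last_rk, "protein")
    }
  }
  # ligand formal charges from input annotations, one group per charged atom
  lig <- at[at$moiety == "ligand" & at$formal_charge != 0 & !at$is_h, ,
            drop = FALSE]
  for (k in seq_len(nrow(lig)))
    add(as.integer(sign(lig$formal_charge[k])), lig$eleno[k],
        lig$residue_key[k], "ligand")
  out
}

# Current-coordinate charge site: charged-atom position, or midpoint of the
# O/N pair for carboxylate/guanidinium (symmetric treatment for the 3.7 A
# ionic criterion).
charge_site <- function(cx, group)
  unname(colMeans(coords_of(cx, group$site_atoms)))

.perceive_hydrophobic <- function(cx, bonds) {
  at <- cx$atoms
  out <- list()
  prot <- at[at$moiety == "protein" & !at$is_h, , drop = FALSE]
  if (nrow(prot)) {
    keep <- vapply(seq_len(nrow(prot)), function(k)
      prot$elety[k] %in% .HYDROPHOBIC_SC[[toupper(prot$resid[k])]], TRUE)
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(
        serial = prot$eleno[keep], owner = "protein",
        residue_key = prot$residue_key[keep], stringsAsFactors = FALSE)
  }
  lig <- at[at$moiety == "ligand" & !at$is_h & at$elesy == "C", , drop = FALSE]
  if (nrow(lig)) {
    ok <- vapply(lig$eleno, function(s) {
      nb <- .bonded_heavies(bonds, s)
      all(at$elesy[match(nb, at$eleno)] %in% c("C", "S"))
    }, TRUE)
    if (any(ok))
      out[[length(out) + 1L]] <- data.frame(
        serial = lig$eleno[ok], owner = "ligand",
        residue_key = lig$residue_key[ok], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(serial = integer(), owner = character(),
                      residue_key = character()))
  do.call(rbind, out)
}

#' Ionise chain termini
#'
#' Marks the first residue of every protein chain as N-terminally protonated
#' (NH3+, +1 at the backbone N) and the last as deprotonated carboxylate
#' (COO-, -1 centred on O/OXT). A single-residue chain carries both. The
#' charge groups materialise in the perceived chemistry so ionic detection
#' sees them. Idempotent.
#'
#' @param cx a `plcomplex`.
#' @return the complex with the termini flag set (re-perceived if chemistry
#'   was already present).
#' @export
ionize_termini <- function(cx) {
  already <- isTRUE(cx$termini_ionized)
  cx$termini_ionized <- TRUE
  if (!already && !is.null(cx$chemistry))
    cx <- perceive(cx, cx$chemistry$options)
  cx
}

#' Extract the binding-sphere pocket around the ligand
#'
#' Keeps every protein residue and water with at least one atom within
#' `radius` of at least one ligand atom; residues are kept whole; the ligand
#' is always kept. Monotone in radius. Perceived chemistry is recomputed on
#' the subset when it was present.
#'
#' @param cx a `plcomplex`.
#' @param radius sphere radius in Angstrom (> 0); 4 A reproduces the
#'   semi-empirical workflow's pocket truncation.
#' @return a `plcomplex` restricted to the pocket.
#' @export
extract_pocket <- function(cx, radius = 4.0) {
  stopifnot(radius > 0)
  at <- cx$atoms
  lig_xyz <- as.matrix(at[at$moiety == "ligand", c("x", "y", "z")])
  other <- at[at$moiety != "ligand", , drop = FALSE]
  keep_keys <- unique(at$residue_key[at$moiety == "ligand"])
  if (nrow(other)) {
    pr <- neighbor_pairs(as.matrix(other[, c("x", "y", "z")]), lig_xyz, radius)
    keep_keys <- c(keep_keys, unique(other$residue_key[unique(pr$i)]))
  }
  sub <- at[at$residue_key %in% keep_keys, , drop = FALSE]
  out <- cx
  out$atoms <- sub
  out$chemistry <- NULL
  if (!is.null(cx$chemistry)) out <- perceive(out, cx$chemistry$options)
  out
}
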