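# Interaction detectors. Each operates on one perceived complex (a pose or
# a trajectory frame) and returns a tidy data.frame of interaction records,
# one row per detected contact. All geometry is recomputed from the current
# coordinates, so the same perceived topology serves every frame.

RECORD_COLS <- c("kind", "subtype", "lig_atom", "lig_ring", "prot_atom",
                 "prot_ring", "residue_key", "water_key", "distance",
                 "donor_angle", "acceptor_angle", "interplanar_angle",
                 "frame")

empty_records <- function() {
  data.frame(kind = character(), subtype = character(),
             lig_atom = integer(), lig_ring = integer(),
             prot_atom = integer(), prot_ring = integer(),
             residue_key = character(), water_key = character(),
             distance = numeric(), donor_angle = numeric(),
             acceptor_angle = numeric(), interplanar_angle = numeric(),
             frame = integer(), stringsAsFactors = FALSE)
}

.record <- function(kind, residue_key, subtype = NA_character_,
                    lig_atom = NA_integer_, lig_ring = NA_integer_,
                    prot_atom = NA_integer_, prot_ring = NA_integer_,
                    water_key = NA_character_, distance = NA_real_,
                    donor_angle = NA_real_, acceptor_angle = NA_real_,
                    interplanar_angle = NA_real_, frame = NA_integer_) {
  data.frame(kind = kind, subtype = subtype, lig_atom = lig_atom,
             lig_ring = lig_ring, prot_atom = prot_atom,
             prot_ring = prot_ring, residue_key = residue_key,
             water_key = water_key, distance = distance,
             donor_angle = donor_angle, acceptor_angle = acceptor_angle,
             interplanar_angle = interplanar_angle, frame = frame,
             stringsAsFactors = FALSE)
}

.bind_records <- function(rows) {
  if (!length(rows)) return(empty_records())
  do.call(rbind, rows)
}

.need_chemistry <- function(cx) {
  if (is.null(cx$chemistry))
    stop("complex has no perceived chemistry; run perceive() first")
  cx$chemistry
}

#' Docking-stage proton-heteroatom contacts
#'
#' One record per (polar hydrogen, heteroatom) pair across the
#' ligand-protein interface with H...X distance at most
#' `docking_contact_max` (3.2 A default). Polar hydrogens are those bonded
#' to N/O/S; heteroatoms are N/O/S of the partner molecule. Both scan
#' directions are taken; waters are not considered here.
#'
#' @param cx perceived `plcomplex`.
#' @param criteria a \code{\link{geometric_criteria}} list.
#' @return data.frame of records (kind `hbond_contact_docking`), geometry
#'   column `distance` = H...heteroatom distance.
#' @export
detect_hbond_contacts_docking <- function(cx, criteria = geometric_criteria()) {
  .need_chemistry(cx)
  at <- cx$atoms
  if (!any(at$is_h)) {
    warning("no hydrogens in complex; docking-contact scan is empty")
    return(empty_records())
  }
  par_el <- at$elesy[match(at$parent, at$eleno)]
  rows <- list()
  scan <- function(h_moiety, x_moiety) {
    hs <- at[at$is_h & at$moiety == h_moiety & par_el %in% c("N", "O", "S"), ,
             drop = FALSE]
    xs <- at[!at$is_h & at$moiety == x_moiety & at$elesy %in% c("N", "O", "S"), ,
             drop = FALSE]
    if (!nrow(hs) || !nrow(xs)) return()
    pr <- neighbor_pairs(as.matrix(hs[, c("x", "y", "z")]),
                         as.matrix(xs[, c("x", "y", "z")]),
                         criteria$docking_contact_max)
    for (k in seq_len(nrow(pr))) {
      hrow <- hs[pr$i[k], ]; xrow <- xs[pr$j[k], ]
      lig_side <- if (h_moiety == "ligand") hrow else xrow
      prot_side <- if (h_moiety == "ligand") xrow else hrow
      rows[[length(rows) + 1L]] <<- .record(
        "hbond_contact_docking", prot_side$residue_key,
        lig_atom = lig_side$eleno, prot_atom = prot_side$eleno,
        distance = pr$d[k])
    }
  }
  scan("ligand", "protein")
  scan("protein", "ligand")
  .bind_records(rows)
}

# Directional H-bond candidate scan between donors of one moiety and
# acceptors of another, under (d_max, donor angle min, acceptor angle min).
# Returns df(d, h, a, dist, donor_angle, acceptor_angle).
.hb_scan <- function(cx, donor_moiety, acceptor_moiety, d_max, ang_d_min,
                     ang_a_min, quantifier = "every") {
  ch <- cx$chemistry
  don <- ch$donors[ch$donors$owner == donor_moiety, , drop = FALSE]
  acc <- ch$acceptors[ch$acceptors$owner == acceptor_moiety, , drop = FALSE]
  out <- data.frame(d = integer(), h = integer(), a = integer(),
                    dist = numeric(), donor_angle = numeric(),
                    acceptor_angle = numeric())
  if (!nrow(don) || !nrow(acc)) return(out)
  dxyz <- coords_of(cx, don$d)
  axyz <- coords_of(cx, acc$a)
  pr <- neighbor_pairs(dxyz, axyz, d_max)
  pr <- pr[don$d[pr$i] != acc$a[pr$j], , drop = FALSE]
  rows <- list()
  for (k in seq_len(nrow(pr))) {
    dd <- don[pr$i[k], ]; aa <- acc[pr$j[k], ]
    pd <- dxyz[pr$i[k], ]; pa <- axyz[pr$j[k], ]
    ph <- coords_of(cx, dd$h)[1, ]
    dang <- angle3(pd, ph, pa)
    if (dang < ang_d_min - .EPS) next
    xs <- ch$acceptor_neighbors$x[ch$acceptor_neighbors$a == aa$a]
    xs <- setdiff(xs, dd$h)
    if (length(xs)) {
      aang <- vapply(xs, function(x)
        angle3(ph, pa, coords_of(cx, x)[1, ]), 1.0)
      ok <- if (quantifier == "every") all(aang >= ang_a_min - .EPS)
            else any(aang >= ang_a_min - .EPS)
      if (!ok) next
      a_rep <- min(aang)
    } else {
      a_rep <- NA_real_  # no bonded neighbor: acceptor-angle test vacuous
    }
    rows[[length(rows) + 1L]] <- data.frame(
      d = dd$d, h = dd$h, a = aa$a, dist = pr$d[k],
      donor_angle = dang, acceptor_angle = a_rep)
  }
  if (length(rows)) out <- do.call(rbind, rows)
  out
}

#' Hydrogen bonds between ligand and protein
#'
#' A record requires donor-acceptor distance <= `hbond_da_max` (2.5 A),
#' donor angle D-H...A at the hydrogen >= `hbond_donor_angle_min` (120 deg),
#' and acceptor angle H...A-X at the acceptor >= `hbond_acceptor_angle_min`
#' (90 deg) for every bonded neighbor X of A (set `quantifier = "any"` for
#' the permissive reading). Both directions are scanned; waters are handled
#' by \code{\link{detect_water_bridges}}, not here. An acceptor without any
#' bonded neighbor passes the acceptor-angle test vacuously (reported
#' `acceptor_angle` is NA).
#'
#' @param cx perceived `plcomplex`.
#' @param criteria a `geometric_criteria` list.
#' @param quantifier `"every"` (default, stricter) or `"any"`: how the
#'   acceptor-angle condition quantifies over A's neighbors.
#' @return data.frame of records (kind `hbond`).
#' @export
detect_hbonds <- function(cx, criteria = geometric_criteria(),
                          quantifier = c("every", "any")) {
  .need_chemistry(cx)
  quantifier <- match.arg(quantifier)
  at <- cx$atoms
  rows <- list()
  for (dir in list(c("ligand", "protein"), c("protein", "ligand"))) {
    sc <- .hb_scan(cx, dir[1], dir[2], criteria$hbond_da_max,
                   criteria$hbond_donor_angle_min,
                   criteria$hbond_acceptor_angle_min, quantifier)
    for (k in seq_len(nrow(sc))) {
      lig_at <- if (dir[1] == "ligand") sc$d[k] else sc$a[k]
      prot_at <- if (dir[1] == "ligand") sc$a[k] else sc$d[k]
      rows[[length(rows) + 1L]] <- .record(
        "hbond", at$residue_key[match(prot_at, at$eleno)],
        subtype = paste0(dir[1], "_donor"),
        lig_atom = lig_at, prot_atom = prot_at, distance = sc$dist[k],
        donor_angle = sc$donor_angle[k], acceptor_angle = sc$acceptor_angle[k])
    }
  }
  .bind_records(rows)
}

#' Water-bridged hydrogen bonds
#'
#' One record per (ligand atom, protein residue, water) triple in which the
#' water simultaneously forms a relaxed-criteria H-bond (`wb_da_max` 2.8 A,
#' donor angle >= 110 deg, acceptor angle >= 90 deg) with >= 1 ligand atom
#' and >= 1 protein atom. The water may donate or accept on each side
#' independently. `distance` stores the longer of the two legs.
#'
#' @param cx perceived `plcomplex` (waters present; explicit H on waters
#'   when they donate).
#' @param criteria a `geometric_criteria` list.
#' @param quantifier acceptor-angle quantifier, as in
#'   \code{\link{detect_hbonds}}.
#' @return data.frame of records (kind `water_bridge`).
#' @export
detect_water_bridges <- function(cx, criteria = geometric_criteria(),
                                 quantifier = c("every", "any")) {
  .need_chemistry(cx)
  quantifier <- match.arg(quantifier)
  at <- cx$atoms
  leg <- function(side) {
    a <- .hb_scan(cx, "water", side, criteria$wb_da_max,
                  criteria$wb_donor_angle_min, criteria$wb_acceptor_angle_min,
                  quantifier)
    b <- .hb_scan(cx, side, "water", criteria$wb_da_max,
                  criteria$wb_donor_angle_min, criteria$wb_acceptor_angle_min,
                  quantifier)
    rbind(
      if (nrow(a)) data.frame(partner = a$a, water = a$d, dist = a$dist),
      if (nrow(b)) data.frame(partner = b$d, water = b$a, dist = b$dist))
  }
  lig_legs <- leg("ligand")
  prot_legs <- leg("protein")
  if (is.null(lig_legs) || is.null(prot_legs) ||
      !nrow(lig_legs) || !nrow(prot_legs)) return(empty_records())
  lig_legs$water_key <- at$residue_key[match(lig_legs$water, at$eleno)]
  prot_legs$water_key <- at$residue_key[match(prot_legs$water, at$eleno)]
  rows <- list()
  for (w in intersect(lig_legs$water_key, prot_legs$water_key)) {
    ll <- lig_legs[lig_legs$water_key == w, , drop = FALSE]
    pp <- prot_legs[prot_legs$water_key == w, , drop = FALSE]
    for (i in seq_len(nrow(ll))) for (j in seq_len(nrow(pp))) {
      rows[[length(rows) + 1L]] <- .record(
        "water_bridge", at$residue_key[match(pp$partner[j], at$eleno)],
        lig_atom = ll$partner[i], prot_atom = pp$partner[j], water_key = w,
        distance = max(ll$dist[i], pp$dist[j]))
    }
  }
  rec <- .bind_records(rows)
  # one record per (ligand atom, residue, water): keep the shortest geometry
  if (nrow(rec)) {
    key <- paste(rec$lig_atom, rec$residue_key, rec$water_key)
    rec <- rec[order(key, rec$distance), , drop = FALSE]
    rec <- rec[!duplicated(paste(rec$lig_atom, rec$residue_key, rec$water_key)), ,
               drop = FALSE]
    rownames(rec) <- NULL
  }
  rec
}

#' Aromatic pi-pi stacking
#'
#' For each (ligand ring, protein ring) pair the centroid distance c and the
#' unsigned interplanar angle theta (between ring normals, folded to
#' \[0, 90\] deg) classify the pair: face-to-face when theta <=
#' `pipi_f2f_angle_max` and c <= `pipi_f2f_centroid_max`; edge-to-face when
#' theta >= 60 deg (the folded image of the 60-120 band) and c <=
#' `pipi_e2f_centroid_max`.
#'
#' @param cx perceived `plcomplex`.
#' @param criteria a `geometric_criteria` list.
#' @return data.frame of records (kind `pi_pi`, subtype `face_to_face` or
#'   `edge_to_face`).
#' @export
detect_pi_pi <- function(cx, criteria = geometric_criteria()) {
  ch <- .need_chemistry(cx)
  lig <- Filter(function(r) r$owner == "ligand", ch$rings)
  prot <- Filter(function(r) r$owner == "protein", ch$rings)
  e2f_lo <- min(criteria$pipi_e2f_angle_range)
  e2f_lo <- if (e2f_lo > 90) 180 - e2f_lo else e2f_lo
  rows <- list()
  for (rl in lig) for (rp in prot) {
    pl <- ring_plane(coords_of(cx, rl$members))
    pp <- ring_plane(coords_of(cx, rp$members))
    cdist <- vnorm(pl$centroid - pp$centroid)
    theta <- interplanar_angle(pl$normal, pp$normal)
    subtype <- NULL
    if (theta <= criteria$pipi_f2f_angle_max + .EPS &&
        cdist <= criteria$pipi_f2f_centroid_max + .EPS) {
      subtype <- "face_to_face"
    } else if (theta >= e2f_lo - .EPS &&
               cdist <= criteria$pipi_e2f_centroid_max + .EPS) {
      subtype <- "edge_to_face"
    }
    if (!is.null(subtype))
      rows[[length(rows) + 1L]] <- .record(
        "pi_pi", rp$residue_key, subtype = subtype, lig_ring = rl$id,
        prot_ring = rp$id, distance = cdist, interplanar_angle = theta)
  }
  .bind_records(rows)
}

#' Pi-cation contacts
#'
#' A record per (aromatic ring, positive charged group) pair with ring
#' centroid to charge site distance <= `pication_max` (4.5 A), in either
#' direction (ligand ring vs protein cation, protein ring vs ligand cation).
#'
#' @param cx perceived `plcomplex`.
#' @param criteria a `geometric_criteria` list.
#' @return data.frame of records (kind `pi_cation`).
#' @export
detect_pi_cation <- function(cx, criteria = geometric_criteria()) {
  ch <- .need_chemistry(cx)
  pos <- Filter(function(g) g$sign > 0, ch$charges)
  rows <- list()
  for (r in ch$rings) for (g in pos) {
    if (r$owner == g$owner) next
    if (!all(c(r$owner, g$owner) %in% c("ligand", "protein"))) next
    pl <- ring_plane(coords_of(cx, r$members))
    d <- vnorm(pl$centroid - charge_site(cx, g))
    if (d <= criteria$pication_max + .EPS) {
      prot_rk <- if (r$owner == "protein") r$residue_key else g$residue_key
      rows[[length(rows) + 1L]] <- .record(
        "pi_cation", prot_rk,
        lig_ring = if (r$owner == "ligand") r$id else NA_integer_,
        prot_ring = if (r$owner == "protein") r$id else NA_integer_,
        lig_atom = if (g$owner == "ligand") g$site_atoms[1] else NA_integer_,
        prot_atom = if (g$owner == "protein") g$site_atoms[1] else NA_integer_,
        distance = d)
    }
  }
  .bind_records(rows)
}

#' Hydrophobic contacts
#'
#' Scans (ligand apolar carbon, protein hydrophobic sidechain atom) pairs
#' within `hydrophobic_max` (3.6 A) and aggregates to one record per protein
#' residue holding the minimum distance and its atom pair.
#'
#' @param cx perceived `plcomplex`.
#' @param criteria a `geometric_criteria` list.
#' @return data.frame of records (kind `hydrophobic`), one row per residue.
#' @export
detect_hydrophobic <- function(cx, criteria = geometric_criteria()) {
  ch <- .need_chemistry(cx)
  hp <- ch$hydrophobic
  lig <- hp[hp$owner == "ligand", , drop = FALSE]
  prot <- hp[hp$owner == "protein", , drop = FALSE]
  if (!nrow(lig) || !nrow(prot)) return(empty_records())
  pr <- neighbor_pairs(coords_of(cx, lig$serial), coords_of(cx, prot$serial),
                       criteria$hydrophobic_max)
  if (!nrow(pr)) return(empty_records())
  pr$residue_key <- prot$residue_key[pr$j]
  pr <- pr[order(pr$residue_key, pr$d), , drop = FALSE]
  best <- pr[!duplicated(pr$residue_key), , drop = FALSE]
  .bind_records(lapply(seq_len(nrow(best)), function(k) .record(
    "hydrophobic", best$residue_key[k],
    lig_atom = lig$serial[best$i[k]], prot_atom = prot$serial[best$j[k]],
    distance = best$d[k])))
}

#' Ionic (polar) contacts
#'
#' A record per pair of oppositely charged groups across the interface whose
#' charge sites lie within `ionic_max` (3.7 A) and whose atoms are not
#' already engaged in a hydrogen bond of this frame (H-bond precedence).
#'
#' @param cx perceived `plcomplex`.
#' @param criteria a `geometric_criteria` list.
#' @param hbonds optional precomputed \code{\link{detect_hbonds}} result for
#'   the same frame; computed on the fly when NULL.
#' @return data.frame of records (kind `ionic`).
#' @export
detect_ionic <- function(cx, criteria = geometric_criteria(), hbonds = NULL) {
  ch <- .need_chemistry(cx)
  if (is.null(hbonds)) hbonds <- detect_hbonds(cx, criteria)
  grp <- Filter(function(g) g$owner %in% c("ligand", "protein"), ch$charges)
  rows <- list()
  for (g1 in grp) for (g2 in grp) {
    if (!(g1$owner == "ligand" && g2$owner == "protein")) next
    if (g1$sign * g2$sign >= 0) next
    d <- vnorm(charge_site(cx, g1) - charge_site(cx, g2))
    if (d > criteria$ionic_max + .EPS) next
    bridged <- FALSE
    if (nrow(hbonds)) {
      a1 <- g1$site_atoms; a2 <- g2$site_atoms
      bridged <- any((hbonds$lig_atom %in% a1 & hbonds$prot_atom %in% a2) |
                     (hbonds$lig_atom %in% a2 & hbonds$prot_atom %in% a1))
    }
    if (bridged) next
    rows[[length(rows) + 1L]] <- .record(
      "ionic", g2$residue_key, lig_atom = g1$site_atoms[1],
      prot_atom = g2$site_atoms[1], distance = d)
  }
  .bind_records(rows)
}

#' Run all six interaction detectors on one complex
#'
#' @param cx perceived `plcomplex`.
#' @param criteria a `geometric_criteria` list.
#' @param include_docking also include the docking-stage proton-heteroatom
#'   contact scan (default FALSE; it is a docking criterion, not an MD one).
#' @param quantifier acceptor-angle quantifier for H-bonds and bridges.
#' @return data.frame of records of all kinds.
#' @export
detect_all <- function(cx, criteria = geometric_criteria(),
                       include_docking = FALSE,
                       quantifier = c("every", "any")) {
  quantifier <- match.arg(quantifier)
  hb <- detect_hbonds(cx, criteria, quantifier)
  parts <- list(
    hb,
    detect_water_bridges(cx, criteria, quantifier),
    detect_pi_pi(cx, criteria),
    detect_pi_cation(cx, criteria),
    detect_hydrophobic(cx, criteria),
    detect_ionic(cx, criteria, hbonds = hb))
  if (include_docking)
    parts <- c(parts, list(detect_hbond_contacts_docking(cx, criteria)))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Re-validate detected records against the criteria
#'
#' Self-check pass: every emitted record's stored geometry must satisfy the
#' thresholds of its kind.
#'
#' @param records record data.frame from a detector.
#' @param criteria the `geometric_criteria` the records were produced with.
#' @return logical vector, one entry per record.
#' @export
validate_records <- function(records, criteria = geometric_criteria()) {
  if (!nrow(records)) return(logical(0))
  e2f_lo <- min(criteria$pipi_e2f_angle_range)
  if (e2f_lo > 90) e2f_lo <- 180 - e2f_lo
  vapply(seq_len(nrow(records)), function(k) {
    r <- records[k, ]
    tol <- .EPS
    switch(r$kind,
      hbond_contact_docking = r$distance <= criteria$docking_contact_max + tol,
      hbond = r$distance <= criteria$hbond_da_max + tol &&
        r$donor_angle >= criteria$hbond_donor_angle_min - tol &&
        (is.na(r$acceptor_angle) ||
           r$acceptor_angle >= criteria$hbond_acceptor_angle_min - tol),
      water_bridge = r$distance <= criteria$wb_da_max + tol,
      pi_pi = if (r$subtype == "face_to_face")
          r$distance <= criteria$pipi_f2f_centroid_max + tol &&
          r$interplanar_angle <= criteria$pipi_f2f_angle_max + tol
        else
          r$distance <= criteria$pipi_e2f_centroid_max + tol &&
          r$interplanar_angle >= e2f_lo - tol,
      pi_cation = r$distance <= criteria$pication_max + tol,
      hydrophobic = r$distance <= criteria$hydrophobic_max + tol,
      ionic = r$distance <= criteria$ionic_max + tol,
      FALSE)
  }, TRUE)
}

#' Minimum-distance contact table for selected residues
#'
#' For each requested residue, one row per detected contact category giving
#' the minimum distance and the atom pair realising it, in deterministic
#' order (residue as requested, then distance).
#'
#' @param cx perceived `plcomplex`.
#' @param residue_keys character vector of residue keys (e.g. `"GLU917"`);
#'   unknown keys raise an error naming them. Empty vector gives an empty
#'   table.
#' @param criteria a `geometric_criteria` list.
#' @param include_docking include docking proton-heteroatom contacts
#'   (default TRUE: this is a pose-analysis table).
#' @return data.frame (residue_key, kind, lig_atom, lig_atom_name,
#'   prot_atom, prot_atom_name, distance).
#' @export
contact_distance_table <- function(cx, residue_keys,
                                   criteria = geometric_criteria(),
                                   include_docking = TRUE) {
  at <- cx$atoms
  known <- unique(at$residue_key[at$moiety != "ligand"])
  bad <- setdiff(residue_keys, known)
  if (length(bad))
    stop("unknown residue key(s): ", paste(bad, collapse = ", "))
  out <- data.frame(residue_key = character(), kind = character(),
                    lig_atom = integer(), lig_atom_name = character(),
                    prot_atom = integer(), prot_atom_name = character(),
                    distance = numeric(), stringsAsFactors = FALSE)
  if (!length(residue_keys)) return(out)
  rec <- detect_all(cx, criteria, include_docking = include_docking)
  rec <- rec[rec$residue_key %in% residue_keys & !is.na(rec$distance), ,
             drop = FALSE]
  if (!nrow(rec)) return(out)
  rec <- rec[order(match(rec$residue_key, residue_keys), rec$kind, rec$distance), ,
             drop = FALSE]
  best <- rec[!duplicated(paste(rec$residue_key, rec$kind)), , drop = FALSE]
  nm <- function(s) ifelse(is.na(s), NA_character_, at$elety[match(s, at$eleno)])
  out <- data.frame(residue_key = best$residue_key, kind = best$kind,
                    lig_atom = best$lig_atom,
                    lig_atom_name = nm(best$lig_atom),
                    prot_atom = best$prot_atom,
                    prot_atom_name = nm(best$prot_atom),
                    distance = best$distance, stringsAsFactors = FALSE)
  out <- out[order(match(out$residue_key, residue_keys), out$distance), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
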