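# Synthetic ground-truth fixtures: toy pockets with interactions planted at
# exact analytic geometries, multi-frame trajectories with prescribed
# Bernoulli contact occupancy, and energy tables with known totals. These
# stand in statistically for undeposited docked poses, MD trajectories and
# quantum-chemistry outputs: every generated scene carries an enumerable
# truth table and regenerates bit-identically from (spec, seed).

PLANT_KINDS <- c("hbond", "water_bridge", "pi_pi", "pi_cation",
                 "hydrophobic", "ionic")

#' Specification of one planted interaction
#'
#' Default geometries sit safely inside the detection thresholds (with
#' margin for jitter); pass explicit `geometry` entries to probe boundaries.
#' Geometry parameter names by kind: `hbond`: distance (D-A, A),
#' donor_angle, acceptor_angle (deg); `water_bridge`: d_lig, d_prot (A);
#' `pi_pi`: centroid_dist (A), tilt (deg); `pi_cation`, `hydrophobic`,
#' `ionic`: distance (A).
#'
#' @param kind one of `r paste(PLANT_KINDS, collapse=", ")`.
#' @param geometry named list overriding the kind's default geometry.
#' @param occupancy_p per-frame Bernoulli presence probability in \[0, 1\]
#'   used by \code{\link{build_trajectory}}.
#' @param jitter_sd extra Gaussian jitter (A) applied to this plant's
#'   ligand-side atoms on "on" frames.
#' @param negate build the plant 1.5 A beyond its criterion instead
#'   (a guaranteed negative).
#' @return list of class `plant_spec`.
#' @export
plant_spec <- function(kind, geometry = list(), occupancy_p = 1.0,
                       jitter_sd = 0, negate = FALSE) {
  kind <- match.arg(kind, PLANT_KINDS)
  defaults <- switch(kind,
    hbond = list(distance = 2.30, donor_angle = 180, acceptor_angle = 120),
    water_bridge = list(d_lig = 2.70, d_prot = 2.70),
    pi_pi = list(centroid_dist = 3.80, tilt = 0),
    pi_cation = list(distance = 4.00),
    hydrophobic = list(distance = 3.40),
    ionic = list(distance = 3.00))
  bad <- setdiff(names(geometry), names(defaults))
  if (length(bad)) stop("unknown geometry parameter(s) for ", kind, ": ",
                        paste(bad, collapse = ", "))
  geometry <- utils::modifyList(defaults, geometry)
  if (negate) {
    dpar <- intersect(c("distance", "centroid_dist", "d_prot"), names(geometry))[1]
    geometry[[dpar]] <- geometry[[dpar]] + 1.5
  }
  stopifnot(occupancy_p >= 0, occupancy_p <= 1, jitter_sd >= 0)
  structure(list(kind = kind, geometry = geometry, occupancy_p = occupancy_p,
                 jitter_sd = jitter_sd, negate = negate),
            class = "plant_spec")
}

# atom-row builder used by all generators
.arow <- function(elety, elesy, resid, chain, resno, xyz, charge = 0L) {
  data.frame(elety = elety, elesy = elesy, resid = resid, chain = chain,
             resno = resno, x = xyz[1], y = xyz[2], z = xyz[3],
             formal_charge = charge, stringsAsFactors = FALSE)
}

.hexagon <- function(center, radius = 1.39, tilt = 0) {
  k <- 0:5
  pts <- cbind(radius * cos(k * pi / 3), radius * sin(k * pi / 3), 0)
  if (tilt != 0) {
    th <- tilt * pi / 180
    rot <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
    pts <- pts %*% t(rot)
  }
  sweep(pts, 2, center, "+")
}

#' Idealised arylsulphonyl-azole ligand scaffold
#'
#' A planar fused 5+6 heteroaromatic system (benzo ring + pyrazole-like
#' 5-ring with one pyrrolic N-H and one pyridinic N) carrying a sulfonyl
#' methyl substituent: the minimal ligand exhibiting donor, acceptor,
#' aromatic and hydrophobic chemistry at once.
#'
#' @param origin 3-vector, scaffold placement.
#' @return data.frame of atom rows (residue LIG, chain L, resno 1).
#' @export
synthetic_azole_ligand <- function(origin = c(0, 0, 0)) {
  hex <- .hexagon(c(0, 0, 0))
  nm6 <- c("C3A", "C7A", "C7", "C6", "C5", "C4")
  p0 <- hex[1, ]; p1 <- hex[2, ]          # fused edge C3A-C7A
  mid <- (p0 + p1) / 2
  u <- mid / vnorm(mid)                   # outward from hexagon center
  s5 <- vnorm(p1 - p0)
  c5 <- mid + u * (s5 / (2 * tan(pi / 5)))  # pentagon center (apothem)
  r5 <- s5 / (2 * sin(pi / 5))
  a0 <- atan2(p0[2] - c5[2], p0[1] - c5[1])
  a1 <- atan2(p1[2] - c5[2], p1[1] - c5[1])
  dirn <- if (sin(a1 - a0) > 0) -1 else 1  # walk away from p1
  angs <- a0 + dirn * (1:3) * 2 * pi / 5
  pent <- cbind(c5[1] + r5 * cos(angs), c5[2] + r5 * sin(angs), 0)
  pos_C3 <- pent[1, ]; pos_N2 <- pent[2, ]; pos_N1 <- pent[3, ]
  out_of <- function(p, center, len) p + (p - center) / vnorm(p - center) * len
  rows <- list()
  add <- function(elety, elesy, xyz, charge = 0L)
    rows[[length(rows) + 1L]] <<- .arow(elety, elesy, "LIG", "L", 1L,
                                        xyz + origin, charge)
  for (k in 1:6) add(nm6[k], "C", hex[k, ])
  add("C3", "C", pos_C3); add("N2", "N", pos_N2); add("N1", "N", pos_N1)
  add("HN1", "H", out_of(pos_N1, c5, 1.01))
  for (k in 3:6) add(paste0("H", nm6[k]), "H", out_of(hex[k, ], c(0, 0, 0), 1.08))
  pos_S <- out_of(pos_C3, c5, 1.77)
  sdir <- (pos_S - pos_C3) / vnorm(pos_S - pos_C3)
  add("S1", "S", pos_S)
  add("O1S", "O", pos_S + 1.44 * (0.55 * sdir + c(0, 0, 0.835)))
  add("O2S", "O", pos_S + 1.44 * (0.55 * sdir + c(0, 0, -0.835)))
  pos_CM <- pos_S + 1.77 * c(sdir[2], -sdir[1], 0)
  add("CM", "C", pos_CM)
  mdir <- (pos_CM - pos_S) / vnorm(pos_CM - pos_S)
  add("HM1", "H", pos_CM + 1.09 * mdir)
  add("HM2", "H", pos_CM + 1.09 * c(0, 0, 1) * 0.9 + 0.3 * mdir)
  add("HM3", "H", pos_CM + 1.09 * c(0, 0, -1) * 0.9 + 0.3 * mdir)
  do.call(rbind, rows)
}

# One planted interaction, built analytically at a station.
# Returns list(lig, prot, wat, info); all coordinates already at the station.
.build_plant <- function(spec, idx, station, resno) {
  g <- spec$geometry
  lig <- list(); prot <- list(); wat <- list()
  addl <- function(elety, elesy, xyz, charge = 0L)
    lig[[length(lig) + 1L]] <<- .arow(elety, elesy, "LIG", "L", 1L,
                                      xyz + station, charge)
  rn <- switch(spec$kind, hbond = "GLY", water_bridge = "GLY", pi_pi = "PHE",
               pi_cation = "LYS", hydrophobic = "LEU", ionic = "GLU")
  addp <- function(elety, elesy, xyz)
    prot[[length(prot) + 1L]] <<- .arow(elety, elesy, rn, "A", resno,
                                        xyz + station)
  addw <- function(elety, elesy, xyz)
    wat[[length(wat) + 1L]] <<- .arow(elety, elesy, "HOH", "W", 300L + idx,
                                      xyz + station)
  water_key <- NA_character_
  if (spec$kind == "hbond") {
    # ligand N-H donor, protein backbone O acceptor with neighbor C
    d <- g$distance
    addl(paste0("ND", idx), "N", c(0, 0, 0))
    addl(paste0("HD", idx), "H", c(1.0, 0, 0))
    phi <- (180 - g$donor_angle) * pi / 180
    u <- c(cos(phi), sin(phi), 0)
    tt <- -cos(phi) + sqrt(cos(phi)^2 - 1 + d^2)
    A <- c(1.0, 0, 0) + tt * u
    v <- (c(1.0, 0, 0) - A); v <- v / vnorm(v)
    w <- c(-v[2], v[1], 0)
    X <- A + 1.33 * (cos(g$acceptor_angle * pi / 180) * v +
                     sin(g$acceptor_angle * pi / 180) * w)
    addp("O", "O", A)
    addp("C", "C", X)
    addp("CA", "C", X + c(0.6, 1.3, 0))
    addp("N", "N", X + c(1.2, 2.6, 0))  # kept > 3.2 A from the ligand proton
  } else if (spec$kind == "water_bridge") {
    # ligand N-H...O(water), water O-H...O=C(protein); both legs collinear
    addl(paste0("NW", idx), "N", c(-g$d_lig, 0, 0))
    addl(paste0("HW", idx), "H", c(-g$d_lig + 1.0, 0, 0))
    addw("OW", "O", c(0, 0, 0))
    addw("HW1", "H", c(0.96, 0, 0))
    h2 <- c(0.5, -0.8, 0.3); h2 <- 0.96 * h2 / vnorm(h2)
    addw("HW2", "H", h2)
    addp("O", "O", c(g$d_prot, 0, 0))
    addp("C", "C", c(g$d_prot + 1.23, 0, 0))
    addp("CA", "C", c(g$d_prot + 1.23, 1.52, 0))
    addp("N", "N", c(g$d_prot + 1.23, 2.98, 0))
    water_key <- paste0("HOH", 300L + idx)
  } else if (spec$kind == "pi_pi") {
    lx <- .hexagon(c(0, 0, 0))
    for (k in 1:6) addl(sprintf("CR%d%s", idx, LETTERS[k]), "C", lx[k, ])
    px <- .hexagon(c(0, 0, g$centroid_dist), tilt = g$tilt)
    nm <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
    for (k in 1:6) addp(nm[k], "C", px[k, ])
    addp("CB", "C", c(0, 3.0, g$centroid_dist + 1.5))
    addp("CA", "C", c(0, 4.2, g$centroid_dist + 2.3))
    addp("N", "N", c(0, 5.6, g$centroid_dist + 2.3))
    addp("C", "C", c(1.3, 4.9, g$centroid_dist + 2.9))
    addp("O", "O", c(1.4, 6.1, g$centroid_dist + 3.2))
  } else if (spec$kind == "pi_cation") {
    lx <- .hexagon(c(0, 0, 0))
    for (k in 1:6) addl(sprintf("CK%d%s", idx, LETTERS[k]), "C", lx[k, ])
    addp("NZ", "N", c(0, 0, g$distance))
    addp("CE", "C", c(0, 0, g$distance + 1.48))
    addp("CD", "C", c(0, 0.8, g$distance + 2.7))
    addp("CG", "C", c(0, 0.8, g$distance + 4.2))
    addp("CB", "C", c(0, 1.6, g$distance + 5.4))
    addp("CA", "C", c(0, 1.6, g$distance + 6.9))
    addp("N", "N", c(1.2, 2.3, g$distance + 7.4))
    addp("C", "C", c(-1.1, 2.3, g$distance + 7.4))
    addp("O", "O", c(-1.2, 3.3, g$distance + 8.1))
  } else if (spec$kind == "hydrophobic") {
    addl(paste0("CH", idx), "C", c(0, 0, 0))
    addp("CD1", "C", c(g$distance, 0, 0))
    addp("CG", "C", c(g$distance + 1.53, 0, 0))
    addp("CD2", "C", c(g$distance + 2.0, 1.45, 0))
    addp("CB", "C", c(g$distance + 2.3, -1.3, 0))
    addp("CA", "C", c(g$distance + 3.6, -2.1, 0))
    addp("N", "N", c(g$distance + 3.5, -3.5, 0))
    addp("C", "C", c(g$distance + 5.0, -1.9, 0.4))
    addp("O", "O", c(g$distance + 5.6, -2.9, 0.8))
  } else if (spec$kind == "ionic") {
    # ligand quaternary-like N+ vs glutamate carboxylate midpoint
    addl(paste0("NQ", idx), "N", c(g$distance, 0, 0), charge = 1L)
    addp("OE1", "O", c(0, 1.1, 0))
    addp("OE2", "O", c(0, -1.1, 0))
    addp("CD", "C", c(-0.62, 0, 0))
    addp("CG", "C", c(-2.12, 0, 0))
    addp("CB", "C", c(-2.9, 1.3, 0))
    addp("CA", "C", c(-4.4, 1.3, 0))
    addp("N", "N", c(-5.1, 2.5, 0))
    addp("C", "C", c(-5.2, 0.1, 0))
    addp("O", "O", c(-6.4, 0.2, 0))
  }
  list(lig = do.call(rbind, lig), prot = do.call(rbind, prot),
       wat = if (length(wat)) do.call(rbind, wat) else NULL,
       residue_key = paste0(rn, resno), water_key = water_key)
}

# idealized decoy residue templates (chemically quiet backgrounds)
.decoy_template <- function(name) {
  base <- rbind(.arow("N", "N", name, "A", 1L, c(0, 0, 0)),
                .arow("CA", "C", name, "A", 1L, c(1.46, 0, 0)),
                .arow("C", "C", name, "A", 1L, c(2.0, 1.4, 0)),
                .arow("O", "O", name, "A", 1L, c(3.2, 1.6, 0)))
  extra <- switch(name,
    ALA = .arow("CB", "C", name, "A", 1L, c(2.0, -0.8, 1.2)),
    SER = rbind(.arow("CB", "C", name, "A", 1L, c(2.0, -0.8, 1.2)),
                .arow("OG", "O", name, "A", 1L, c(1.4, -2.1, 1.2))),
    LEU = rbind(.arow("CB", "C", name, "A", 1L, c(2.0, -0.8, 1.2)),
                .arow("CG", "C", name, "A", 1L, c(1.6, -2.25, 1.4)),
                .arow("CD1", "C", name, "A", 1L, c(2.3, -3.1, 0.4)),
                .arow("CD2", "C", name, "A", 1L, c(1.9, -2.8, 2.8))),
    GLY = NULL)
  rbind(base, extra)
}

.random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Build a toy pocket with planted interactions
#'
#' Plants are placed at stations 16 A apart along x (analytic construction
#' at the exact requested geometry); decoy residues (Ala/Leu/Ser/Gly,
#' idealized geometry, seeded random orientation) sit >= 8 A from every
#' plant; the ligand is a single residue carrying all ligand-side plant
#' atoms plus the \code{\link{synthetic_azole_ligand}} scaffold.
#'
#' @param plants list of \code{\link{plant_spec}} objects.
#' @param n_decoy_residues number of decoy residues (default 4).
#' @param seed integer RNG seed; regeneration from (plants, seed) is
#'   bit-identical.
#' @return object of class `synthetic_scene`: list with `complex` (a
#'   perceived \code{\link{plcomplex}}), `plants` (each with its spec,
#'   ligand-side atom serials, residue_key, water_key), `truth` (data.frame
#'   kind/residue_key/water_key of expected detections), `seed`.
#' @export
build_pocket <- function(plants, n_decoy_residues = 4L, seed = 1L) {
  if (inherits(plants, "plant_spec")) plants <- list(plants)
  stopifnot(all(vapply(plants, inherits, TRUE, "plant_spec")))
  set.seed(seed)
  lig_rows <- list(); prot_rows <- list(); wat_rows <- list()
  info <- list()
  for (i in seq_along(plants)) {
    st <- c(16 * (i - 1), 0, 0)
    pl <- .build_plant(plants[[i]], i, st, 100L + i)
    lig_rows[[i]] <- pl$lig
    prot_rows[[i]] <- pl$prot
    if (!is.null(pl$wat)) wat_rows[[length(wat_rows) + 1L]] <- pl$wat
    info[[i]] <- list(spec = plants[[i]], residue_key = pl$residue_key,
                      water_key = pl$water_key,
                      lig_names = pl$lig$elety)
  }
  # scaffold behind the first station, clear of every plant
  scaf <- synthetic_azole_ligand(origin = c(-18, 0, 0))
  decoy_pool <- c("ALA", "LEU", "SER", "GLY")
  for (j in seq_len(n_decoy_residues)) {
    tpl <- .decoy_template(decoy_pool[(j - 1L) %% 4L + 1L])
    xyz <- as.matrix(tpl[, c("x", "y", "z")]) %*% t(.random_rotation())
    xyz <- sweep(xyz, 2, c(16 * (j - 1) + 5, 14 + stats::runif(1, 0, 2),
                           stats::runif(1, -2, 2)), "+")
    tpl$x <- xyz[, 1]; tpl$y <- xyz[, 2]; tpl$z <- xyz[, 3]
    tpl$resno <- 200L + j
    prot_rows[[length(prot_rows) + 1L]] <- tpl
  }
  prot <- do.call(rbind, prot_rows)
  lig <- rbind(do.call(rbind, lig_rows), scaf)
  wat <- if (length(wat_rows)) do.call(rbind, wat_rows) else NULL
  atoms <- rbind(prot, lig, wat)
  atoms$eleno <- seq_len(nrow(atoms))
  cx <- plcomplex(atoms, ligand = "LIG")
  cx <- perceive(cx)
  for (i in seq_along(info)) {
    info[[i]]$lig_serials <-
      cx$atoms$eleno[cx$atoms$elety %in% info[[i]]$lig_names &
                     cx$atoms$moiety == "ligand"]
  }
  truth <- do.call(rbind, lapply(seq_along(info), function(i) {
    if (plants[[i]]$negate) return(NULL)
    data.frame(kind = plants[[i]]$kind, residue_key = info[[i]]$residue_key,
               water_key = info[[i]]$water_key, stringsAsFactors = FALSE)
  }))
  if (is.null(truth))
    truth <- data.frame(kind = character(), residue_key = character(),
                        water_key = character())
  structure(list(complex = cx, plants = info, truth = truth, seed = seed),
            class = "synthetic_scene")
}

#' Build a jittered trajectory with prescribed contact occupancy
#'
#' Per frame, each plant is "on" with its `occupancy_p` (independent
#' seeded Bernoulli draws). "On" frames keep the exact plant geometry plus
#' the plant's own jitter; "off" frames displace the plant's ligand-side
#' atoms 8 A away from the pocket, far beyond every criterion (>= 1.5 A
#' margin). All atoms then receive background Gaussian jitter.
#'
#' @param scene a `synthetic_scene`.
#' @param n_frames number of frames (>= 1).
#' @param jitter_sd background Gaussian jitter sd (A). Total jitter
#'   (background + per-plant) above 0.05 A would erode the plants' criterion
#'   margins and raises a parameter error.
#' @param seed integer RNG seed (single stream; byte-identical regeneration).
#' @return a \code{\link{pltrajectory}} over the scene's complex.
#' @export
build_trajectory <- function(scene, n_frames, jitter_sd = 0, seed = 1L) {
  stopifnot(inherits(scene, "synthetic_scene"), n_frames >= 1)
  plant_sd <- vapply(scene$plants, function(p) p$spec$jitter_sd, 1.0)
  if (any(jitter_sd + plant_sd > 0.05 + 1e-12))
    stop("jitter_sd too large to preserve the plants' criterion margins ",
         "(background + plant jitter must be <= 0.05 A)")
  set.seed(seed)
  cx <- scene$complex
  base <- as.matrix(cx$atoms[, c("x", "y", "z")])
  n <- nrow(base)
  rows_of <- lapply(scene$plants, function(p) match(p$lig_serials, cx$atoms$eleno))
  xyz <- matrix(NA_real_, n_frames, 3L * n)
  for (f in seq_len(n_frames)) {
    fr <- base
    for (i in seq_along(scene$plants)) {
      p <- scene$plants[[i]]
      on <- stats::runif(1) < p$spec$occupancy_p
      if (!on) {
        fr[rows_of[[i]], 2] <- fr[rows_of[[i]], 2] - 8
      } else if (p$spec$jitter_sd > 0) {
        fr[rows_of[[i]], ] <- fr[rows_of[[i]], ] +
          matrix(stats::rnorm(3 * length(rows_of[[i]]), sd = p$spec$jitter_sd),
                 ncol = 3)
      }
    }
    if (jitter_sd > 0)
      fr <- fr + matrix(stats::rnorm(3 * n, sd = jitter_sd), ncol = 3)
    xyz[f, ] <- as.numeric(t(fr))
  }
  pltrajectory(cx, xyz, times = seq_len(n_frames) - 1)
}

#' Generate energy tables with known totals
#'
#' Components are drawn uniformly in +/- 10 kcal/mol (3 decimals, matching
#' the magnitudes of published decomposition tables); stored totals are the
#' exact component sums except in a prescribed fraction of rows perturbed
#' well beyond the consistency tolerance, whose ids are returned as truth.
#'
#' @param n_ligands,n_residues table dimensions (rows = ligand x residue).
#' @param corrupt_fraction fraction of rows (in \[0, 1)) whose stored total
#'   is corrupted.
#' @param seed integer RNG seed.
#' @return list with `sapt`, `pieda`, `enthalpy` tables and `truth` (list of
#'   corrupted row indices per schema).
#' @export
build_energy_tables <- function(n_ligands = 3L, n_residues = 8L,
                                corrupt_fraction = 0, seed = 1L) {
  stopifnot(corrupt_fraction >= 0, corrupt_fraction < 1)
  set.seed(seed)
  ids <- expand.grid(residue = paste0("RES", seq_len(n_residues)),
                     ligand = paste0("L", seq_len(n_ligands)),
                     stringsAsFactors = FALSE)[, c(2, 1)]
  nr <- nrow(ids)
  rcomp <- function() round(stats::runif(nr, -10, 10), 3)
  sapt <- data.frame(ids, e_elst = rcomp(), e_exch = rcomp(),
                     e_ind = rcomp(), e_disp = rcomp())
  sapt$e_total <- sapt$e_elst + sapt$e_exch + sapt$e_ind + sapt$e_disp
  pieda <- data.frame(ids, e_es = rcomp(), e_ex = rcomp(),
                      e_ct_mix = rcomp(), e_disp = rcomp(), g_sol = rcomp())
  pieda$e_tot <- pieda$e_es + pieda$e_ex + pieda$e_ct_mix + pieda$e_disp +
    pieda$g_sol
  n_corrupt <- round(corrupt_fraction * nr)
  truth <- list(sapt_rows = integer(0), pieda_rows = integer(0))
  if (n_corrupt > 0) {
    truth$sapt_rows <- sort(sample.int(nr, n_corrupt))
    sapt$e_total[truth$sapt_rows] <- sapt$e_total[truth$sapt_rows] +
      sample(c(-1, 1), n_corrupt, TRUE) * stats::runif(n_corrupt, 0.5, 3)
    truth$pieda_rows <- sort(sample.int(nr, n_corrupt))
    pieda$e_tot[truth$pieda_rows] <- pieda$e_tot[truth$pieda_rows] +
      sample(c(-1, 1), n_corrupt, TRUE) * stats::runif(n_corrupt, 0.5, 3)
  }
  hf_p <- round(stats::runif(n_ligands, -500, -300), 3)
  hf_l <- round(stats::runif(n_ligands, -200, -50), 3)
  dh <- round(stats::runif(n_ligands, -30, -1), 3)
  enthalpy <- data.frame(ligand = paste0("L", seq_len(n_ligands)),
                         hf_complex = hf_p + hf_l + dh,
                         hf_protein_in_complex = hf_p,
                         hf_ligand_in_complex = hf_l,
                         stringsAsFactors = FALSE)
  class(sapt) <- c("energy_table", "sapt", "data.frame")
  class(pieda) <- c("energy_table", "pieda", "data.frame")
  class(enthalpy) <- c("energy_table", "enthalpy", "data.frame")
  list(sapt = sapt, pieda = pieda, enthalpy = enthalpy, truth = truth)
}
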