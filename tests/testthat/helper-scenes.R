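# Programmatic fixtures: random polar scenes for oracle-equivalence checks
# and small hand-placed complexes for worked geometric examples.

.mk_atoms <- function(rows) {
  at <- do.call(rbind, rows)
  at$eleno <- seq_len(nrow(at))
  at
}

.atom <- function(elety, elesy, resid, chain, resno, xyz, charge = 0L) {
  data.frame(elety = elety, elesy = elesy, resid = resid, chain = chain,
             resno = resno, x = xyz[1], y = xyz[2], z = xyz[3],
             formal_charge = charge, stringsAsFactors = FALSE)
}

.rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

.rand_hexagon <- function(center) {
  k <- 0:5
  pts <- cbind(1.39 * cos(k * pi / 3), 1.39 * sin(k * pi / 3), 0)
  m <- matrix(stats::rnorm(9), 3)
  q <- qr.Q(qr(m)); if (det(q) < 0) q[, 1] <- -q[, 1]
  sweep(pts %*% t(q), 2, center, "+")
}

# A random scene dense enough to produce contacts of every class: protein
# residues with donors/acceptors/rings/charges/hydrophobics, a multi-group
# ligand, and a handful of waters, all uniformly placed in a box.
random_polar_scene <- function(seed, box = 13, n_prot = 8, n_wat = 4) {
  set.seed(seed)
  rp <- function() stats::runif(3, 0, box)
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r
  for (i in seq_len(n_prot)) {
    kind <- sample(c("polar", "lys", "glu", "phe", "leu"), 1)
    base <- rp()
    resid <- switch(kind, polar = "GLY", lys = "LYS", glu = "GLU",
                    phe = "PHE", leu = "LEU")
    add(.atom("N", "N", resid, "A", i, base))
    add(.atom("H", "H", resid, "A", i, base + .rand_unit() * 1.0))
    add(.atom("CA", "C", resid, "A", i, base + c(1.46, 0, 0)))
    cpos <- base + c(2.0, 1.2, 0)
    add(.atom("C", "C", resid, "A", i, cpos))
    add(.atom("O", "O", resid, "A", i, cpos + .rand_unit() * 1.23))
    if (kind == "lys") {
      add(.atom("NZ", "N", resid, "A", i, rp()))
    } else if (kind == "glu") {
      cd <- rp()
      u <- .rand_unit(); w <- .rand_unit()
      w <- w - sum(w * u) * u; w <- w / sqrt(sum(w^2))
      add(.atom("CD", "C", resid, "A", i, cd))
      add(.atom("OE1", "O", resid, "A", i, cd + 1.25 * (0.55 * u + 0.835 * w)))
      add(.atom("OE2", "O", resid, "A", i, cd + 1.25 * (0.55 * u - 0.835 * w)))
    } else if (kind == "phe") {
      hx <- .rand_hexagon(rp())
      nm <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
      for (k in 1:6) add(.atom(nm[k], "C", resid, "A", i, hx[k, ]))
    } else if (kind == "leu") {
      cg <- rp()
      add(.atom("CG", "C", resid, "A", i, cg))
      add(.atom("CD1", "C", resid, "A", i, cg + .rand_unit() * 1.53))
      add(.atom("CD2", "C", resid, "A", i, cg + .rand_unit() * 1.53))
    }
  }
  # ligand: two donors, two acceptors (carbonyl-like), one ring, two
  # hydrophobic carbons, one positive and one negative site
  nd <- rp(); add(.atom("N1L", "N", "LIG", "L", 1, nd))
  add(.atom("H1L", "H", "LIG", "L", 1, nd + .rand_unit() * 1.0))
  nd2 <- rp(); add(.atom("N2L", "N", "LIG", "L", 1, nd2))
  add(.atom("H2L", "H", "LIG", "L", 1, nd2 + .rand_unit() * 1.0))
  for (t in 1:2) {
    op <- rp()
    add(.atom(paste0("O", t, "L"), "O", "LIG", "L", 1, op))
    add(.atom(paste0("C", t, "L"), "C", "LIG", "L", 1, op + .rand_unit() * 1.23))
  }
  hx <- .rand_hexagon(rp())
  for (k in 1:6) add(.atom(paste0("CR", k), "C", "LIG", "L", 1, hx[k, ]))
  add(.atom("CH1", "C", "LIG", "L", 1, rp()))
  add(.atom("CH2", "C", "LIG", "L", 1, rp()))
  add(.atom("NQ1", "N", "LIG", "L", 1, rp(), charge = 1L))
  add(.atom("OQ1", "O", "LIG", "L", 1, rp(), charge = -1L))
  for (w in seq_len(n_wat)) {
    op <- rp()
    add(.atom("OW", "O", "HOH", "W", 400 + w, op))
    add(.atom("HW1", "H", "HOH", "W", 400 + w, op + .rand_unit() * 0.96))
    add(.atom("HW2", "H", "HOH", "W", 400 + w, op + .rand_unit() * 0.96))
  }
  perceive(plcomplex(.mk_atoms(rows), "LIG"))
}

# Minimal single H-bond geometry: ligand N-H vs protein carbonyl O with
# neighbor X, at caller-given positions.
hbond_fixture <- function(D, H, A, X) {
  rows <- list(
    .atom("N1", "N", "LIG", "L", 1, D),
    .atom("H1", "H", "LIG", "L", 1, H),
    .atom("O", "O", "GLY", "A", 10, A),
    .atom("C", "C", "GLY", "A", 10, X),
    # far-away anchors so the residue looks sane
    .atom("CA", "C", "GLY", "A", 10, X + c(8, 8, 0)),
    .atom("CL1", "C", "LIG", "L", 1, D + c(-8, -8, 0)))
  perceive(plcomplex(.mk_atoms(rows), "LIG"))
}

# applies a rigid rotation + translation to every atom of a complex
rigid_move <- function(cx, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(9), 3)
  q <- qr.Q(qr(m)); if (det(q) < 0) q[, 1] <- -q[, 1]
  tr <- stats::runif(3, -20, 20)
  xyz <- as.matrix(cx$atoms[, c("x", "y", "z")]) %*% t(q)
  xyz <- sweep(xyz, 2, tr, "+")
  set_coords(cx, xyz)
}

# precision/recall of a detector's record set vs a scene's truth rows
planted_pr <- function(records, truth, kind) {
  got <- unique(records$residue_key[records$kind == kind])
  want <- truth$residue_key[truth$kind == kind]
  tp <- length(intersect(got, want))
  c(precision = if (length(got)) tp / length(got) else 1,
    recall = if (length(want)) tp / length(want) else 1)
}

SIX_KINDS <- c("hbond", "water_bridge", "pi_pi", "pi_cation",
               "hydrophobic", "ionic")

# complex with many rigid residues (non-degenerate backbone) + 3-atom ligand
backbone_field <- function(n_res = 22) {
  set.seed(99)
  rows <- list()
  for (i in seq_len(n_res)) {
    base <- c(stats::runif(1, 0, 30), stats::runif(1, 0, 30),
              stats::runif(1, 0, 30))
    rows <- c(rows, list(
      .atom("N", "N", "GLY", "A", i, base),
      .atom("CA", "C", "GLY", "A", i, base + c(1.46, 0, 0)),
      .atom("C", "C", "GLY", "A", i, base + c(2.0, 1.4, 0))))
  }
  rows <- c(rows, list(
    .atom("C1", "C", "LIG", "L", 1, c(40, 0, 0)),
    .atom("C2", "C", "LIG", "L", 1, c(41.5, 0, 0)),
    .atom("C3", "C", "LIG", "L", 1, c(41.9, 1.4, 0.6))))
  perceive(plcomplex(.mk_atoms(rows), "LIG"))
}

six_kind_specs <- function(...) lapply(SIX_KINDS, plant_spec, ...)

detector_for <- function(kind) {
  switch(kind,
         hbond = detect_hbonds,
         water_bridge = detect_water_bridges,
         pi_pi = detect_pi_pi,
         pi_cation = detect_pi_cation,
         hydrophobic = detect_hydrophobic,
         ionic = detect_ionic)
}
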