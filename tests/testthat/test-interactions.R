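# Geometric detectors: worked constructions, inclusive bounds, exclusion
# rules, rigid-motion invariance, and oracle equivalence on random scenes.

cr <- geometric_criteria()

test_that("collinear H-bond construction is measured exactly", {
  cx <- hbond_fixture(D = c(0, 0, 0), H = c(1, 0, 0),
                      A = c(2.4, 0, 0), X = c(2.4, 1, 0))
  hb <- detect_hbonds(cx, cr)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 2.4)
  expect_equal(hb$donor_angle, 180)
  expect_equal(hb$acceptor_angle, 90)
})

test_that("H-bond distance and donor-angle cutoffs reject near misses", {
  far <- hbond_fixture(D = c(0, 0, 0), H = c(1, 0, 0),
                       A = c(2.6, 0, 0), X = c(2.6, 1, 0))
  expect_equal(nrow(detect_hbonds(far, cr)), 0)
  bent <- hbond_fixture(D = c(0, 0, 0), H = c(0, 1, 0),
                        A = c(2.0, 1, 0), X = c(2.0, 2, 0))
  expect_equal(nrow(detect_hbonds(bent, cr)), 0)  # donor angle 90 < 120
})

test_that("acceptor-angle quantifier: 'every' is stricter than 'any'", {
  # second neighbor X2 violates the 90 deg acceptor angle
  rows <- list(
    .atom("N1", "N", "LIG", "L", 1, c(0, 0, 0)),
    .atom("H1", "H", "LIG", "L", 1, c(1, 0, 0)),
    .atom("O", "O", "GLY", "A", 10, c(2.4, 0, 0)),
    .atom("C", "C", "GLY", "A", 10, c(2.4, 1, 0)),
    .atom("CA", "C", "GLY", "A", 10, c(1.9, 0.866, 0)))  # angle at A = 60 deg
  cx <- perceive(plcomplex(.mk_atoms(rows), "LIG"))
  expect_equal(nrow(detect_hbonds(cx, cr, quantifier = "every")), 0)
  expect_equal(nrow(detect_hbonds(cx, cr, quantifier = "any")), 1)
})

test_that("docking proton-heteroatom contact bound is inclusive at 3.2 A", {
  mk <- function(d) hbond_fixture(D = c(0, 0, 0), H = c(1, 0, 0),
                                  A = c(1 + d, 0, 0), X = c(1 + d, 1, 0))
  hit <- detect_hbond_contacts_docking(mk(3.20), cr)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$distance, 3.2)
  expect_equal(nrow(detect_hbond_contacts_docking(mk(3.25), cr)), 0)
})

test_that("docking scan warns and returns empty when no hydrogens exist", {
  rows <- list(.atom("C1", "C", "LIG", "L", 1, c(0, 0, 0)),
               .atom("N1", "N", "LIG", "L", 1, c(1.4, 0, 0)),
               .atom("O", "O", "GLY", "A", 2, c(3.0, 0, 0)),
               .atom("C", "C", "GLY", "A", 2, c(3.0, 1.23, 0)))
  cx <- suppressWarnings(perceive(plcomplex(.mk_atoms(rows), "LIG")))
  expect_warning(out <- detect_hbond_contacts_docking(cx, cr), "no hydrogens")
  expect_equal(nrow(out), 0)
})

test_that("water bridge needs both legs within the relaxed criteria", {
  good <- build_pocket(list(plant_spec("water_bridge")), 0, 1)
  wb <- detect_water_bridges(good$complex, cr)
  expect_equal(nrow(wb), 1)
  expect_equal(wb$residue_key, good$truth$residue_key)
  expect_equal(wb$water_key, good$truth$water_key)
  broken <- build_pocket(list(plant_spec("water_bridge",
                                         geometry = list(d_prot = 2.9))), 0, 1)
  expect_equal(nrow(detect_water_bridges(broken$complex, cr)), 0)
})

test_that("pi-pi stacking: parallel, T-shaped, and distant ring pairs", {
  f2f <- build_pocket(list(plant_spec("pi_pi",
    geometry = list(centroid_dist = 3.4, tilt = 0))), 0, 1)
  r <- detect_pi_pi(f2f$complex, cr)
  expect_equal(r$subtype, "face_to_face")
  expect_equal(r$distance, 3.4)
  expect_equal(r$interplanar_angle, 0, tolerance = 1e-6)
  e2f <- build_pocket(list(plant_spec("pi_pi",
    geometry = list(centroid_dist = 3.7, tilt = 90))), 0, 1)
  r2 <- detect_pi_pi(e2f$complex, cr)
  expect_equal(r2$subtype, "edge_to_face")
  expect_equal(r2$interplanar_angle, 90, tolerance = 1e-6)
  none <- build_pocket(list(plant_spec("pi_pi",
    geometry = list(centroid_dist = 6.0, tilt = 0))), 0, 1)
  expect_equal(nrow(detect_pi_pi(none$complex, cr)), 0)
  # a 4.7 A parallel separation is not a stack
  weak <- build_pocket(list(plant_spec("pi_pi",
    geometry = list(centroid_dist = 4.7, tilt = 0))), 0, 1)
  expect_equal(nrow(detect_pi_pi(weak$complex, cr)), 0)
})

test_that("pi-cation and hydrophobic bounds are inclusive", {
  at44 <- build_pocket(list(plant_spec("pi_cation",
                                       geometry = list(distance = 4.4))), 0, 1)
  expect_equal(nrow(detect_pi_cation(at44$complex, cr)), 1)
  at46 <- build_pocket(list(plant_spec("pi_cation",
                                       geometry = list(distance = 4.6))), 0, 1)
  expect_equal(nrow(detect_pi_cation(at46$complex, cr)), 0)
  h35 <- build_pocket(list(plant_spec("hydrophobic",
                                      geometry = list(distance = 3.5))), 0, 1)
  expect_equal(nrow(detect_hydrophobic(h35$complex, cr)), 1)
  h37 <- build_pocket(list(plant_spec("hydrophobic",
                                      geometry = list(distance = 3.7))), 0, 1)
  expect_equal(nrow(detect_hydrophobic(h37$complex, cr)), 0)
})

test_that("ionic contacts: inclusive 3.7 A bound and H-bond precedence", {
  at37 <- build_pocket(list(plant_spec("ionic",
                                       geometry = list(distance = 3.7))), 0, 1)
  expect_equal(nrow(detect_ionic(at37$complex, cr)), 1)
  at38 <- build_pocket(list(plant_spec("ionic",
                                       geometry = list(distance = 3.8))), 0, 1)
  expect_equal(nrow(detect_ionic(at38$complex, cr)), 0)
  # same charge pair but with a qualifying D-H...A geometry: suppressed
  mk_salt <- function(with_h) {
    rows <- list(
      .atom("NQ1", "N", "LIG", "L", 1, c(0, 0, 0), charge = 1L),
      .atom("OE1", "O", "GLU", "A", 3, c(2.2, 0, 0)),
      .atom("CD", "C", "GLU", "A", 3, c(3.0, 1.0, 0)),
      .atom("OE2", "O", "GLU", "A", 3, c(3.55, 2.1, 0)),
      .atom("C1", "C", "LIG", "L", 1, c(-1.5, 0, 0)))
    if (with_h) rows <- c(rows, list(.atom("HQ1", "H", "LIG", "L", 1, c(1, 0, 0))))
    suppressWarnings(perceive(plcomplex(.mk_atoms(rows), "LIG")))
  }
  plain <- mk_salt(with_h = FALSE)
  expect_equal(nrow(detect_ionic(plain, cr)), 1)
  expect_equal(nrow(detect_hbonds(mk_salt(TRUE), cr)), 1)
  expect_equal(nrow(detect_ionic(mk_salt(TRUE), cr)), 0)
})

test_that("contact table reports per-category minima in deterministic order", {
  # planted backbone H-bond at 2.30 A to a residue labelled GLU917
  rows <- list(
    .atom("N1", "N", "LIG", "L", 1, c(0, 0, 0)),
    .atom("H1", "H", "LIG", "L", 1, c(1, 0, 0)),
    .atom("C2", "C", "LIG", "L", 1, c(-1.4, 0.4, 0)),
    .atom("O", "O", "GLU", "A", 917, c(2.3, 0, 0)),
    .atom("C", "C", "GLU", "A", 917, c(2.9, 1.1, 0)),
    .atom("CA", "C", "GLU", "A", 917, c(4.4, 1.2, 0)))
  cx <- perceive(plcomplex(.mk_atoms(rows), "LIG"))
  tab <- contact_distance_table(cx, "GLU917")
  expect_true("hbond" %in% tab$kind)
  hrow <- tab[tab$kind == "hbond", ]
  expect_equal(hrow$distance, 2.3)
  expect_equal(hrow$lig_atom_name, "N1")
  expect_equal(hrow$prot_atom_name, "O")
  expect_equal(nrow(contact_distance_table(cx, character(0))), 0)
  expect_error(contact_distance_table(cx, "ALA1"), "unknown residue")
})

test_that("detection is invariant under rigid rotation and translation", {
  sc <- build_pocket(six_kind_specs(), n_decoy_residues = 3, seed = 11)
  base <- detect_all(sc$complex, cr, include_docking = TRUE)
  for (seed in 1:3) {
    moved <- rigid_move(sc$complex, seed)
    got <- detect_all(moved, cr, include_docking = TRUE)
    expect_equal(nrow(got), nrow(base))
    ord <- function(r) r[order(r$kind, r$residue_key, r$lig_atom, r$lig_ring), ]
    a <- ord(base); b <- ord(got)
    expect_equal(b$kind, a$kind)
    expect_equal(b$residue_key, a$residue_key)
    expect_equal(b$distance, a$distance, tolerance = 1e-6)
    expect_equal(b$donor_angle, a$donor_angle, tolerance = 1e-6)
    expect_equal(b$interplanar_angle, a$interplanar_angle, tolerance = 1e-6)
  }
})

test_that("every emitted record re-validates against its criteria", {
  sc <- build_pocket(six_kind_specs(), n_decoy_residues = 4, seed = 13)
  rec <- detect_all(sc$complex, cr, include_docking = TRUE)
  expect_true(nrow(rec) >= 6)
  expect_true(all(validate_records(rec, cr)))
  for (seed in 1:5) {
    cx <- random_polar_scene(seed)
    expect_true(all(validate_records(detect_all(cx, cr, TRUE), cr)))
  }
})

test_that("tightening any threshold never adds records", {
  tight <- geometric_criteria(docking_contact_max = 3.0, hbond_da_max = 2.3,
                              hbond_donor_angle_min = 140,
                              hbond_acceptor_angle_min = 100,
                              wb_da_max = 2.6, wb_donor_angle_min = 130,
                              pication_max = 4.0, hydrophobic_max = 3.2,
                              ionic_max = 3.3, pipi_f2f_centroid_max = 4.0,
                              pipi_e2f_centroid_max = 5.0,
                              pipi_f2f_angle_max = 20)
  for (seed in 1:8) {
    cx <- random_polar_scene(seed)
    loose_rec <- detect_all(cx, cr, include_docking = TRUE)
    tight_rec <- detect_all(cx, tight, include_docking = TRUE)
    for (k in unique(tight_rec$kind)) {
      kt <- rec_keys(k, tight_rec[tight_rec$kind == k, ])
      kl <- rec_keys(k, loose_rec[loose_rec$kind == k, ])
      expect_true(all(kt %in% kl),
                  label = paste("tightened", k, "subset of loose, seed", seed))
    }
  }
})

test_that("grid-accelerated detectors match brute-force oracles on random scenes", {
  # the full 100-scene sweep lives in the acceptance suite; spot-check here
  for (seed in 1:10) {
    cx <- random_polar_scene(seed)
    expect_identical(rec_keys("hbond", detect_hbonds(cx, cr)),
                     rec_keys("hbond", oracle_hbonds(cx, cr)))
    expect_identical(
      rec_keys("hydrophobic", detect_hydrophobic(cx, cr)),
      rec_keys("hydrophobic", oracle_hydrophobic(cx, cr)))
  }
})
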