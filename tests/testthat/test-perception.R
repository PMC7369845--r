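# Chemistry perception: standard-residue roles, ligand heuristics, termini
# ionisation, pocket extraction.

lys_glu_fixture <- function() {
  rows <- list(
    # LYS with ammonium hydrogens
    .atom("N", "N", "LYS", "A", 1, c(0, 0, 0)),
    .atom("CA", "C", "LYS", "A", 1, c(1.46, 0, 0)),
    .atom("C", "C", "LYS", "A", 1, c(2.0, 1.4, 0)),
    .atom("O", "O", "LYS", "A", 1, c(3.2, 1.6, 0)),
    .atom("NZ", "N", "LYS", "A", 1, c(0, 4, 0)),
    .atom("HZ1", "H", "LYS", "A", 1, c(0.9, 4.4, 0)),
    .atom("HZ2", "H", "LYS", "A", 1, c(-0.9, 4.4, 0)),
    # GLU with carboxylate
    .atom("N", "N", "GLU", "A", 2, c(8, 0, 0)),
    .atom("CA", "C", "GLU", "A", 2, c(9.46, 0, 0)),
    .atom("C", "C", "GLU", "A", 2, c(10, 1.4, 0)),
    .atom("O", "O", "GLU", "A", 2, c(11.2, 1.6, 0)),
    .atom("CD", "C", "GLU", "A", 2, c(8, 4, 0)),
    .atom("OE1", "O", "GLU", "A", 2, c(8.7, 5.0, 0)),
    .atom("OE2", "O", "GLU", "A", 2, c(8.7, 3.0, 0)),
    .atom("C1", "C", "LIG", "L", 9, c(20, 0, 0)),
    .atom("N1", "N", "LIG", "L", 9, c(21.35, 0, 0)),
    .atom("H1", "H", "LIG", "L", 9, c(22.36, 0, 0)))
  perceive(plcomplex(.mk_atoms(rows), "LIG"))
}

test_that("standard residues get their donor/acceptor/charge roles", {
  cx <- lys_glu_fixture()
  ch <- cx$chemistry
  at <- cx$atoms
  nm <- function(s) at$elety[match(s, at$eleno)]
  # Lys: NZ positive group, NZ-HZ* donor pairs
  pos <- Filter(function(g) g$sign > 0, ch$charges)
  expect_equal(length(pos), 1)
  expect_equal(nm(pos[[1]]$site_atoms), "NZ")
  lys_donors <- ch$donors[ch$donors$residue_key == "LYS1", ]
  expect_setequal(nm(lys_donors$h), c("HZ1", "HZ2"))
  expect_true(all(nm(lys_donors$d) == "NZ"))
  # Glu: OE1/OE2 acceptors, one negative group at the carboxylate midpoint
  glu_acc <- ch$acceptors[ch$acceptors$residue_key == "GLU2", ]
  expect_setequal(nm(glu_acc$a), c("O", "OE1", "OE2"))
  neg <- Filter(function(g) g$sign < 0, ch$charges)
  expect_equal(length(neg), 1)
  expect_equal(pocketmd:::charge_site(cx, neg[[1]]), c(8.7, 4.0, 0))
  # backbone O acceptor has its carbonyl C as neighbor
  o_lys <- at$eleno[at$residue_key == "LYS1" & at$elety == "O"]
  xs <- ch$acceptor_neighbors$x[ch$acceptor_neighbors$a == o_lys]
  expect_equal(nm(xs), "C")
})

test_that("azole-like ligand perception: rings, pyrrolic donor, pyridinic and sulfonyl acceptors", {
  lig <- synthetic_azole_ligand()
  lig$eleno <- seq_len(nrow(lig))
  cx <- perceive(plcomplex(lig, "LIG"))
  ch <- cx$chemistry
  nm <- function(s) cx$atoms$elety[match(s, cx$atoms$eleno)]
  expect_equal(length(ch$rings), 2)
  expect_setequal(vapply(ch$rings, function(r) length(r$members), 1L), c(5L, 6L))
  expect_equal(nm(ch$donors$d), "N1")  # pyrrolic N-H is the only donor
  expect_setequal(nm(ch$acceptors$a), c("N2", "O1S", "O2S"))
  # methyl and benzo carbons are hydrophobic; ring carbons next to N are not
  expect_true(all(c("CM", "C4", "C5") %in% nm(ch$hydrophobic$serial)))
  expect_false(any(c("C7A", "C3") %in% nm(ch$hydrophobic$serial)))
})

test_that("perception is deterministic and idempotent", {
  sc <- build_pocket(six_kind_specs(), n_decoy_residues = 2, seed = 4)
  cx1 <- perceive(sc$complex)
  cx2 <- perceive(cx1)
  expect_identical(cx1$chemistry[names(cx1$chemistry) != "options"],
                   cx2$chemistry[names(cx2$chemistry) != "options"])
})

test_that("termini ionisation adds one +/- pair per chain and is idempotent", {
  cx <- lys_glu_fixture()
  n_pos <- function(c) sum(vapply(c$chemistry$charges, function(g) g$sign > 0, TRUE))
  n_neg <- function(c) sum(vapply(c$chemistry$charges, function(g) g$sign < 0, TRUE))
  expect_equal(c(n_pos(cx), n_neg(cx)), c(1, 1))  # Lys+, Glu- sidechains
  cxi <- ionize_termini(cx)
  expect_equal(c(n_pos(cxi), n_neg(cxi)), c(2, 2))
  expect_equal(c(n_pos(ionize_termini(cxi)), n_neg(ionize_termini(cxi))),
               c(2, 2))
  # the added groups sit on the chain's first N and last O
  term <- cxi$chemistry$charges[3:4]
  keys <- vapply(term, function(g) g$residue_key, "")
  expect_setequal(keys, c("LYS1", "GLU2"))
})

test_that("two chains get two ionised termini pairs", {
  rows <- list()
  for (ch in c("A", "B")) for (r in 1:2) {
    off <- (match(ch, c("A", "B")) - 1) * 30 + r * 8
    rows <- c(rows, list(
      .atom("N", "N", "GLY", ch, r, c(off, 0, 0)),
      .atom("CA", "C", "GLY", ch, r, c(off + 1.46, 0, 0)),
      .atom("C", "C", "GLY", ch, r, c(off + 2, 1.4, 0)),
      .atom("O", "O", "GLY", ch, r, c(off + 3.2, 1.6, 0))))
  }
  rows <- c(rows, list(.atom("C1", "C", "LIG", "L", 1, c(60, 0, 0)),
                       .atom("C2", "C", "LIG", "L", 1, c(61.5, 0, 0)),
                       .atom("C3", "C", "LIG", "L", 1, c(61.9, 1.4, 0))))
  cx <- ionize_termini(perceive(plcomplex(.mk_atoms(rows), "LIG")))
  signs <- vapply(cx$chemistry$charges, function(g) g$sign, 1L)
  expect_equal(sum(signs > 0), 2)
  expect_equal(sum(signs < 0), 2)
})

test_that("pocket extraction keeps whole residues by the nearest-atom rule", {
  mk <- function(d) {
    rows <- list(
      .atom("C1", "C", "LIG", "L", 1, c(0, 0, 0)),
      .atom("C2", "C", "LIG", "L", 1, c(1.5, 0, 0)),
      .atom("C3", "C", "LIG", "L", 1, c(2.0, 1.4, 0)),
      # residue whose nearest atom sits at distance d, the rest further
      .atom("N", "N", "GLY", "A", 5, c(-d, 0, 0)),
      .atom("CA", "C", "GLY", "A", 5, c(-d - 1.46, 0, 0)),
      .atom("C", "C", "GLY", "A", 5, c(-d - 2, 1.4, 0)),
      .atom("O", "O", "GLY", "A", 5, c(-d - 3.2, 1.6, 0)))
    perceive(plcomplex(.mk_atoms(rows), "LIG"))
  }
  near <- extract_pocket(mk(3.9), 4)
  expect_true("GLY5" %in% near$atoms$residue_key)
  expect_equal(sum(near$atoms$residue_key == "GLY5"), 4)  # kept whole
  far <- extract_pocket(mk(4.1), 4)
  expect_false("GLY5" %in% far$atoms$residue_key)
})

test_that("pocket membership matches a brute-force scan and is monotone in radius", {
  for (seed in 1:5) {
    cx <- random_polar_scene(seed)
    at <- cx$atoms
    lig <- as.matrix(at[at$moiety == "ligand", c("x", "y", "z")])
    keys <- character(0)
    for (rk in unique(at$residue_key[at$moiety != "ligand"])) {
      sub <- as.matrix(at[at$residue_key == rk, c("x", "y", "z")])
      dmin <- min(vapply(seq_len(nrow(sub)), function(i)
        min(sqrt(rowSums(sweep(lig, 2, sub[i, ])^2))), 1.0))
      if (dmin <= 5) keys <- c(keys, rk)
    }
    pk <- extract_pocket(cx, 5)
    expect_setequal(setdiff(unique(pk$atoms$residue_key),
                            unique(at$residue_key[at$moiety == "ligand"])),
                    keys)
    inner <- extract_pocket(cx, 3)
    expect_true(all(unique(inner$atoms$residue_key) %in%
                    unique(pk$atoms$residue_key)))
  }
})
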