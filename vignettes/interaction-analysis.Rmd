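---
title: "Geometric interaction analysis of protein-ligand pockets"
author: "pocketmd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric interaction analysis of protein-ligand pockets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketmd)
```

# The problem

Kinase inhibitors such as arylsulphonyl azoles bind in the ATP pocket of
receptor tyrosine kinases (the motivating system is the VEGFR2 pocket, PDB
entry 3ewh) through a small set of recurring contact classes: hydrogen
bonds from pyrrolic ring N-H groups to backbone carbonyls, water-mediated
bridges, pi-pi stacks with pocket phenylalanines, pi-cation contacts with
the catalytic lysine ammonium, nonspecific hydrophobic packing, and ionic
pairs. `pocketmd` detects all six classes with explicit geometric criteria
on single docked poses and on molecular-dynamics trajectories stored as
multi-model PDB, and aggregates the interaction-energy decompositions
(SAPT0, FMO2/PIEDA, semi-empirical heats of formation) that
quantum-chemistry programs produce for such complexes as tables.

Because docked poses and MD trajectories of this kind are rarely deposited,
the package ships a first-class synthetic-data module that *plants*
interactions at exact analytic geometries and generates trajectories with
prescribed per-contact Bernoulli occupancy. Every test of the detection and
statistics machinery runs against that enumerable ground truth.

# Geometric criteria

All thresholds are cutoffs, not targets: distances are maxima, angles are
minima (a band for edge-to-face stacking), and every bound is inclusive.
The defaults, overridable per threshold via `geometric_criteria()` or a
JSON config:

| class | criterion | default |
|---|---|---|
| docking H-contact | proton to heteroatom (N/O/S) distance | <= 3.2 A |
| hydrogen bond | donor-acceptor distance; donor angle D-H...A; acceptor angle H...A-X | <= 2.5 A; >= 120 deg; >= 90 deg |
| water bridge | relaxed H-bond on both sides of one water | <= 2.8 A; >= 110 deg; >= 90 deg |
| pi-pi face-to-face | centroid distance; interplanar angle | <= 4.4 A; <= 30 deg |
| pi-pi edge-to-face | centroid distance; interplanar angle | <= 5.5 A; 60-90 deg (folded) |
| pi-cation | ring centroid to charge site | <= 4.5 A |
| hydrophobic | apolar C/S pair | <= 3.6 A |
| ionic | opposite charge sites, no H-bond between the groups | <= 3.7 A |

Two readings deserved an explicit decision:

* **Docking contact vs MD hydrogen bond.** The docking-stage criterion is a
  proton-heteroatom distance (3.2 A); the MD criterion is a donor-acceptor
  heavy-atom distance with two angle conditions. Both are kept as distinct
  operations (`detect_hbond_contacts_docking()` vs `detect_hbonds()`)
  because they measure different things and one cannot emulate the other.
* **Acceptor-angle quantifier.** When the acceptor A has several bonded
  neighbors X, the H...A-X condition can be required for *every* X or for
  *any* X. The stricter *every* reading is the default; both are
  implemented (`quantifier` argument) since the convention is genuinely
  ambiguous. An acceptor with no neighbor at all (an isolated site) passes
  vacuously.
* **pi-pi centroid cutoffs.** The 4.4/5.5 A centroid bounds and the
  30 / 60-90 degree angle bands are calibration choices: they accept the
  parallel stacks observed around 3.4 A and T-shaped pairs at 3.7 A in
  kinase pockets while rejecting parallel rings at 4.7 A, where stacking is
  negligible. Ring normals have arbitrary sign, so interplanar angles are
  folded to [0, 90] degrees and no downstream result depends on ring
  orientation or atom order.
* **Ionic precedence.** A charge pair already connected by a qualifying
  hydrogen bond is counted as that hydrogen bond, not twice.
* **Inclusive bounds in floating point.** Every comparison uses a 1e-9 A
  epsilon so analytically constructed fixtures sitting exactly on a
  threshold are detected; the epsilon is three orders of magnitude below
  PDB coordinate precision and cannot affect real data.

# Chemistry perception

Protein roles come from a fixed per-residue lookup (20 standard residues
plus water): backbone and sidechain donors/acceptors, aromatic rings for
Phe/Tyr/Trp/His, charged groups for Lys/Arg/Asp/Glu (carboxylate and
guanidinium sites are the midpoint of the O/N pair, a symmetric choice for
the 3.7 A ionic criterion), hydrophobic sidechain carbons/sulfurs for the
apolar residues plus the Tyr ring and Cys SG. Histidine is treated as
neutral (both ring nitrogens accept) unless `his_protonated` is set; the
protonation states of pocket histidines/cysteines are rarely reported, so
the default is documented and overridable rather than guessed per input.

Ligand roles are derived from element and connectivity on a bond graph
built from interatomic distances (1.75 A heavy-heavy, 2.1 A around S/P;
hydrogens attach to the nearest heavy atom within 1.2 A, since CONECT
records are optional): N/O bearing hydrogens donate; any O and pyridinic N
(no H, at most two heavy neighbors) accept; 5/6-membered planar rings
(RMS out-of-plane <= 0.1 A, all members with at most three neighbors)
are aromatic; carbons bonded only to C/H/S are hydrophobic. Ligand formal
charges are read from the input annotations; the package deliberately has
no pKa model.

`ionize_termini()` marks chain termini (NH3+ / COO-) so pocket fragments
prepared for semi-empirical calculations carry the correct charges, and
`extract_pocket()` truncates a complex to the binding sphere: every
protein residue or water with at least one atom within the radius
(default 4 A) of any ligand atom, kept whole. Pocket membership is
residue-granular and monotone in the radius.

# Trajectory statistics

Trajectories are multi-model PDB files over a fixed topology: a
deliberately dependency-light, diffable carrier (frame times ride in
per-MODEL `REMARK TIME` lines). Heavy atoms only enter all statistics;
hydrogen positions are noise-dominated.

* `ligand_rmsd()` has the two conventional alignment modes: superpose each
  frame's protein backbone (N, CA, C) on the reference and measure the
  ligand without further fitting (pocket stability), or superpose the
  ligand on itself (internal fluctuation, zero at the reference frame).
  Superposition is the standard least-squares rigid fit (SVD/Kabsch, via
  bio3d); near-collinear alignment sets are refused rather than silently
  rotated arbitrarily.
* `residue_rmsf()` fits every frame's backbone onto the time-mean
  structure, refining the mean with a second fit iteration (the mean
  structure, not the first frame, is the reference: it is the unique
  choice that makes the statistic independent of frame numbering), then
  reports per-residue root-mean-square displacement over frames and
  backbone atoms.
* `occupancy()` runs all six detectors on every frame and reports, per
  (residue, interaction class), the fraction of frames with at least one
  record. Presence is binary per frame -- multiple simultaneous contacts
  of one class with one residue count once -- which keeps the fractions
  bounded by 1 like the published interaction histograms.

# Energy bookkeeping

The quantum-chemical energies themselves are upstream inputs; the package
owns the arithmetic around them. `sapt_total()` sums the four SAPT0
components (electrostatics, exchange, induction, dispersion);
`pieda_total()` the five PIEDA components (electrostatic, exchange,
charge-transfer+mixed, dispersion, solvation). When a table also stores a
printed total, a consistency checker flags rows deviating beyond a
rounding tolerance (0.005 kcal/mol for 2-decimal SAPT tables,
0.015 kcal/mol for 3-decimal PIEDA tables) -- report-only, never
"corrected", because published tables do contain rows whose stored total
disagrees with their own components by far more than rounding.

`fmo2_total()` assembles the two-body fragment expansion
(sum of dimer energies minus (N-2) times the monomer sum). `tie()` sums
per-residue pair interaction energies over residues with |E_tot| at or
above a threshold (default 3 kcal/mol). The magnitude reading of the
threshold is the package default: the published inclusion rule is stated
as "PIE >= 3 kcal/mol" while every listed contribution is attractive
(negative), so a literal signed reading would include nothing; the
magnitude interpretation is configurable (`magnitude = FALSE` restores the
attractive-only reading). `interaction_enthalpy()` evaluates the
thermodynamic-cycle difference Hf(PL) - [Hf_complex(P) + Hf_complex(L)],
and `rank_ligands()` orders ligands ascending (most favourable first) with
a deterministic lexicographic tie-break.

# The synthetic-data generator

`build_pocket()` places each requested plant at a station on a line, 16 A
apart (comfortably beyond the largest criterion plus margins), builds the
interacting pair analytically at the exact requested geometry -- e.g. an
H-bond with given D-A distance, donor and acceptor angles, or two regular
hexagons with given centroid offset and tilt -- and adds chemically quiet
decoy residues (Ala/Leu/Ser/Gly, idealized geometry, seeded random
orientation) at least 8 A away. The ligand is one residue carrying every
ligand-side plant atom plus an arylsulphonyl-azole-like scaffold (fused
5+6 aromatic system with a pyrrolic N-H, a pyridinic N and a sulfonyl
group), so ligand perception is exercised on realistic chemistry. A scene
regenerates byte-identically from its seed, and its truth table lists
exactly the records each detector must find.

Default planted geometries sit inside the criteria with safety margins
(H-bond at 2.30 A of the 2.5 A bound with ideal angles, hydrophobic pair
at 3.40 of 3.6 A, and so on). In multi-plant scenes the pi-pi plant
defaults to a 3.8 A centroid separation rather than the tighter 3.4 A
observed in real stacks, because parallel rings at 3.4 A are *also* a
genuine hydrophobic contact (carbon pairs under 3.6 A) and the truth-table
tests require each detector to find exactly its own plant; single-plant
fixtures still exercise the observed 3.400/3.700 A geometries.

`build_trajectory()` draws, per frame and plant, an independent Bernoulli
"on" state with the plant's occupancy probability; "off" frames displace
the plant's ligand-side atoms 8 A out of the pocket (at least 1.5 A beyond
every criterion), "on" frames keep the exact geometry, and all atoms
receive background Gaussian jitter. The total jitter standard deviation is
capped at 0.05 A: at that level the tightest criterion margin (0.2 A on
the H-bond distance) is about three standard deviations of the induced
pair-distance noise, which keeps planted recall above 99 percent; a larger
request is a parameter error rather than a silently eroded ground truth.

`build_energy_tables()` draws components uniformly in +/-10 kcal/mol
(matching the magnitudes of published per-residue decompositions), stores
exact component sums as totals, and corrupts a prescribed fraction of rows
well beyond the checker tolerance, returning the corrupted ids as truth.

What the generator does *not* emulate: physically realistic conformational
sampling, correlated motions, force-field energetics, rotamer libraries,
solvent structure. Passing tests therefore demonstrate that the geometric
detectors, occupancy statistics and energy arithmetic are correct and
exactly recover planted ground truth under bounded noise -- not that the
pipeline reproduces any particular physical trajectory.

# Validation strategy and problem sizes

The test suite validates every detector against independent brute-force
oracles (plain all-pairs/all-triples loops with locally defined scalar
geometry) on 100 random scenes of roughly 70 atoms with every role class
present, requiring exact record-set equality; boundary fixtures at each
threshold +/- 0.05 A must flip detection, and fixtures exactly at a
threshold must be detected (inclusive bounds). Occupancy recovery is
checked at p in {0.10, 0.37, 0.62, 0.99} -- values echoing published
interaction histograms -- over 1000 frames against a 3-standard-deviation
binomial bound. RMSD/RMSF nulls (static and rigidly moving trajectories)
must vanish to 1e-6 A and a uniform 1 A ligand displacement must give
exactly 1.0 A. Worked energy decompositions from published tables are
frozen as exact expectations. `scripts/acceptance.R` recomputes all of
these end to end against the installed package under a caller-supplied
seed; the problem sizes above were chosen so the whole suite runs in a
couple of minutes on one CPU while keeping binomial noise well inside the
asserted bounds.

# Known limitations

* Perception is lookup- and heuristic-based: no bond-order perception,
  tautomers, SMARTS patterns or pKa model. Unusual ligand chemotypes may
  need explicit formal-charge annotations in the input PDB.
* Halogen bonds and weak C-H...O contacts are not first-class record
  kinds; the latter are visible through the docking-contact scan and the
  minimum-distance contact table.
* The trajectory carrier is multi-model PDB only (no DCD/XTC); at 3-decimal
  precision, round-trips are exact to 0.001 A.
* Water bridges consider single-water paths only; no two-water chains.
* Frame clustering, PCA of motions and free-energy estimates are out of
  scope.

# A worked example

```{r example, eval = FALSE}
library(pocketmd)

# a six-plant pocket with known truth
scene <- build_pocket(lapply(c("hbond", "water_bridge", "pi_pi",
                               "pi_cation", "hydrophobic", "ionic"),
                             plant_spec),
                      n_decoy_residues = 4, seed = 1)
detect_all(scene$complex)[, c("kind", "residue_key", "distance")]

# occupancy of a 62%-occupied hydrogen bond over 500 frames
sc <- build_pocket(list(plant_spec("hbond", occupancy_p = 0.62)), 2, seed = 1)
traj <- build_trajectory(sc, n_frames = 500, jitter_sd = 0.02, seed = 2)
occupancy_of(occupancy(traj), "GLY101", "hbond")

# energy bookkeeping on published-style tables
sapt_total(sapt_record("8", "ALA866", -5.32, 5.67, -1.48, -5.14))  # -6.27
tie(pieda_record(rep("6", 3), c("PHE918", "GLU917", "LYS838"),
                 0, 0, 0, 0, 0, e_tot = c(-18.82, -4.5, -4.79)))
```
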