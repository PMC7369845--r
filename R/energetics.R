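# Aggregation of externally computed interaction energies: SAPT0 component
# totals, PIEDA totals with consistency checking, FMO2 assembly from
# monomer/dimer energies, total interaction energy (TIE) with a magnitude
# threshold, thermodynamic-cycle interaction enthalpy, and ligand ranking.
# All energies are kcal/mol.

.num_or_stop <- function(df, cols, what) {
  for (cn in cols) {
    v <- df[[cn]]
    if (is.null(v) || anyNA(v) || !is.numeric(v))
      stop(what, ": missing or non-numeric component '", cn, "'")
  }
  invisible(TRUE)
}

#' SAPT0 interaction-energy total
#'
#' Sum of the four SAPT0 components (electrostatics + exchange repulsion +
#' induction + dispersion). When a stored total is present, any discrepancy
#' beyond `tolerance` is reported via warning (the stored value is never
#' "corrected").
#'
#' @param records sapt-schema data.frame (one or more rows).
#' @param tolerance stored-total agreement tolerance, kcal/mol; the 0.005
#'   default absorbs printed rounding of 2-3 decimal tables.
#' @return numeric vector of computed totals, one per row.
#' @export
sapt_total <- function(records, tolerance = 0.005) {
  comp <- c("e_elst", "e_exch", "e_ind", "e_disp")
  .num_or_stop(records, comp, "sapt_total")
  tot <- records$e_elst + records$e_exch + records$e_ind + records$e_disp
  stored <- records$e_total
  if (!is.null(stored)) {
    off <- which(!is.na(stored) & abs(stored - tot) > tolerance)
    if (length(off))
      warning("stored e_total deviates from component sum by > ", tolerance,
              " kcal/mol in row(s): ", paste(off, collapse = ", "))
  }
  tot
}

#' PIEDA pair-interaction-energy total
#'
#' Sum of the five PIEDA components (electrostatic + exchange +
#' charge-transfer/mixed + dispersion + solvation). Consistency with a
#' stored total is report-only, as for \code{\link{sapt_total}}.
#'
#' @param records pieda-schema data.frame.
#' @param tolerance stored-total tolerance, kcal/mol (0.015 default: printed
#'   3-decimal tables carry visible rounding drift).
#' @return numeric vector of computed totals, one per row.
#' @export
pieda_total <- function(records, tolerance = 0.015) {
  comp <- c("e_es", "e_ex", "e_ct_mix", "e_disp", "g_sol")
  .num_or_stop(records, comp, "pieda_total")
  tot <- records$e_es + records$e_ex + records$e_ct_mix + records$e_disp +
    records$g_sol
  stored <- records$e_tot
  if (!is.null(stored)) {
    off <- which(!is.na(stored) & abs(stored - tot) > tolerance)
    if (length(off))
      warning("stored e_tot deviates from component sum by > ", tolerance,
              " kcal/mol in row(s): ", paste(off, collapse = ", "))
  }
  tot
}

#' Flag rows whose stored total disagrees with the component sum
#'
#' Report-only consistency checker for energy tables: rows with a stored
#' total deviating from the component sum by more than `tolerance` are
#' returned, never altered.
#'
#' @param records sapt- or pieda-schema data.frame.
#' @param schema `"sapt"` or `"pieda"`.
#' @param tolerance kcal/mol; defaults 0.005 (sapt) / 0.015 (pieda).
#' @return data.frame of flagged rows with columns of `records` plus
#'   `computed_total` and `discrepancy`.
#' @export
check_energy_totals <- function(records, schema = c("sapt", "pieda"),
                                tolerance = NULL) {
  schema <- match.arg(schema)
  if (is.null(tolerance)) tolerance <- if (schema == "sapt") 0.005 else 0.015
  tot <- suppressWarnings(
    if (schema == "sapt") sapt_total(records, tolerance)
    else pieda_total(records, tolerance))
  stored <- if (schema == "sapt") records$e_total else records$e_tot
  if (is.null(stored)) stored <- rep(NA_real_, nrow(records))
  disc <- abs(stored - tot)
  flag <- !is.na(disc) & disc > tolerance
  out <- as.data.frame(records)[flag, , drop = FALSE]
  out$computed_total <- tot[flag]
  out$discrepancy <- disc[flag]
  rownames(out) <- NULL
  out
}

#' FMO2 total energy from monomer and dimer energies
#'
#' For N fragments, `sum over I>J of E_IJ - (N - 2) * sum over I of E_I`.
#' With N = 2 the monomer term vanishes.
#'
#' @param monomer_energies numeric vector E_I, one per fragment (N >= 2).
#' @param dimer_energies data.frame with columns `i`, `j`, `e` covering
#'   every unordered fragment pair; a missing pair raises an error naming
#'   (I, J).
#' @return the assembled total energy (same units as the inputs).
#' @export
fmo2_total <- function(monomer_energies, dimer_energies) {
  n <- length(monomer_energies)
  if (n < 2) stop("FMO2 assembly needs at least 2 fragments")
  de <- as.data.frame(dimer_energies)
  if (!all(c("i", "j", "e") %in% names(de)))
    stop("dimer_energies needs columns i, j, e")
  key <- paste(pmin(de$i, de$j), pmax(de$i, de$j))
  if (anyDuplicated(key)) stop("duplicate dimer pair(s)")
  want <- utils::combn(n, 2)
  want_key <- paste(want[1, ], want[2, ])
  miss <- setdiff(want_key, key)
  if (length(miss))
    stop("missing dimer energy for pair(s): (",
         paste(sub(" ", ",", miss), collapse = "), ("), ")")
  sum(de$e[key %in% want_key]) - (n - 2) * sum(monomer_energies)
}

#' Total interaction energy (TIE) over a residue threshold
#'
#' Sums the per-residue pair interaction energies E_tot of one ligand over
#' the residues with |E_tot| >= `threshold` (inclusive). The magnitude
#' reading of the inclusion rule is the package default (all headline
#' contributions in the source tables are attractive, so sign-restricted
#' inclusion would be ambiguous); set `magnitude = FALSE` to include by
#' E_tot <= -threshold instead.
#'
#' @param records pieda-schema rows for a single ligand. Stored `e_tot` is
#'   used when present, else the component sum.
#' @param threshold inclusion threshold, kcal/mol (default 3).
#' @param magnitude include by |E_tot| (default) or by E_tot <= -threshold.
#' @return object of class `tie_summary`: list with `ligand_id`, `tie`
#'   (kcal/mol), `included` (data.frame residue, e_tot), `threshold`.
#' @export
tie <- function(records, threshold = 3.0, magnitude = TRUE) {
  stopifnot(threshold >= 0)
  lig <- unique(records$ligand)
  if (length(lig) > 1) stop("tie() expects one ligand's records, got: ",
                            paste(lig, collapse = ", "))
  et <- if (!is.null(records$e_tot) && !anyNA(records$e_tot)) records$e_tot
        else pieda_total(records)
  keep <- if (magnitude) abs(et) >= threshold - 1e-12
          else et <= -threshold + 1e-12
  inc <- data.frame(residue = records$residue[keep], e_tot = et[keep],
                    stringsAsFactors = FALSE)
  structure(list(ligand_id = if (length(lig)) lig else NA_character_,
                 tie = sum(inc$e_tot), included = inc,
                 threshold = threshold),
            class = "tie_summary")
}

#' @export
print.tie_summary <- function(x, ...) {
  cat("TIE(", x$ligand_id, ") = ", sprintf("%.3f", x$tie), " kcal/mol over ",
      nrow(x$included), " residues (|E_tot| >= ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Thermodynamic-cycle interaction enthalpy
#'
#' `dH_int = Hf(PL) - [Hf_complex(P) + Hf_complex(L)]`: the heat of
#' formation of the complex minus those of protein and ligand frozen in the
#' complex conformation.
#'
#' @param records enthalpy-schema data.frame.
#' @return numeric vector of interaction enthalpies, kcal/mol.
#' @export
interaction_enthalpy <- function(records) {
  .num_or_stop(records, c("hf_complex", "hf_protein_in_complex",
                          "hf_ligand_in_complex"), "interaction_enthalpy")
  records$hf_complex -
    (records$hf_protein_in_complex + records$hf_ligand_in_complex)
}

#' Rank ligands by interaction energy
#'
#' Ascending order (most negative, i.e. most favourable, first); ties broken
#' lexicographically on the ligand id. Deterministic.
#'
#' @param energies named numeric vector (names = ligand ids) or data.frame
#'   with columns `ligand` and `energy`.
#' @return data.frame (rank, ligand, energy).
#' @export
rank_ligands <- function(energies) {
  if (is.data.frame(energies)) {
    df <- data.frame(ligand = as.character(energies$ligand),
                     energy = energies$energy, stringsAsFactors = FALSE)
  } else {
    df <- data.frame(ligand = names(energies), energy = unname(energies),
                     stringsAsFactors = FALSE)
  }
  if (!nrow(df)) stop("nothing to rank")
  df <- df[order(df$energy, df$ligand), , drop = FALSE]
  df <- data.frame(rank = seq_len(nrow(df)), df, row.names = NULL)
  df
}
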