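# Delimited energy tables. Upstream quantum-chemistry programs (SAPT0,
# FMO2/PIEDA, semi-empirical heats of formation) are table producers only;
# this package consumes tab-separated files with a header row. All energies
# are plain kcal/mol floats.

ENERGY_SCHEMAS <- list(
  sapt = list(required = c("ligand", "residue", "e_elst", "e_exch",
                           "e_ind", "e_disp"),
              total = "e_total",
              components = c("e_elst", "e_exch", "e_ind", "e_disp")),
  pieda = list(required = c("ligand", "residue", "e_es", "e_ex",
                            "e_ct_mix", "e_disp", "g_sol"),
               total = "e_tot",
               components = c("e_es", "e_ex", "e_ct_mix", "e_disp", "g_sol")),
  enthalpy = list(required = c("ligand", "hf_complex",
                               "hf_protein_in_complex", "hf_ligand_in_complex"),
                  total = NULL,
                  components = c("hf_complex", "hf_protein_in_complex",
                                 "hf_ligand_in_complex"))
)

#' Read a tab-separated energy table
#'
#' Schemas (column names in the header row):
#' \describe{
#'   \item{sapt}{`ligand residue e_elst e_exch e_ind e_disp [e_total]` --
#'     the four SAPT0 components (electrostatics, exchange repulsion,
#'     induction, dispersion) per ligand-residue pair.}
#'   \item{pieda}{`ligand residue e_es e_ex e_ct_mix e_disp g_sol [e_tot]` --
#'     FMO2/PIEDA components (electrostatic, exchange, charge-transfer+mixed,
#'     dispersion, solvation free energy).}
#'   \item{enthalpy}{`ligand hf_complex hf_protein_in_complex
#'     hf_ligand_in_complex` -- heats of formation for the
#'     thermodynamic-cycle interaction enthalpy.}
#' }
#' The optional total column may be absent or NA per row. Non-numeric
#' component values raise a parse error naming the row.
#'
#' @param path TSV file with header.
#' @param schema one of `"sapt"`, `"pieda"`, `"enthalpy"`.
#' @return data.frame with class `c("energy_table", schema)`; zero rows for a
#'   header-only file.
#' @export
read_energy_table <- function(path, schema = c("sapt", "pieda", "enthalpy")) {
  schema <- match.arg(schema)
  sc <- ENERGY_SCHEMAS[[schema]]
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          blank.lines.skip = TRUE)
  miss <- setdiff(sc$required, names(df))
  if (length(miss))
    stop("schema '", schema, "': header is missing column(s): ",
         paste(miss, collapse = ", "))
  numcols <- c(sc$components, intersect(sc$total, names(df)))
  for (cn in numcols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !(df[[cn]] %in% c("", "NA")) )
    if (length(bad))
      stop("schema '", schema, "': non-numeric value '", df[[cn]][bad[1]],
           "' in column ", cn, " at row ", bad[1])
    if (cn %in% sc$components && nrow(df) && anyNA(v))
      stop("schema '", schema, "': missing component in column ", cn,
           " at row ", which(is.na(v))[1])
    df[[cn]] <- v
  }
  if (!is.null(sc$total) && !(sc$total %in% names(df)))
    df[[sc$total]] <- rep(NA_real_, nrow(df))
  class(df) <- c("energy_table", schema, "data.frame")
  df
}

#' Write an energy table as TSV (deterministic column order)
#'
#' @param df data.frame with the schema's columns.
#' @param path output file.
#' @param schema table schema (see \code{\link{read_energy_table}}).
#' @return `path`, invisibly.
#' @export
write_energy_table <- function(df, path, schema = c("sapt", "pieda", "enthalpy")) {
  schema <- match.arg(schema)
  sc <- ENERGY_SCHEMAS[[schema]]
  cols <- c(sc$required, if (!is.null(sc$total) && sc$total %in% names(df)) sc$total)
  utils::write.table(as.data.frame(df)[, cols, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Single energy records
#'
#' Convenience constructors for one ligand-residue decomposition record,
#' returned as one-row tables compatible with the aggregation operations.
#'
#' @param ligand,residue identifiers.
#' @param e_elst,e_exch,e_ind,e_disp SAPT0 components, kcal/mol.
#' @param e_total,e_tot optional stored total, kcal/mol.
#' @return one-row data.frame of the matching schema.
#' @export
sapt_record <- function(ligand, residue, e_elst, e_exch, e_ind, e_disp,
                        e_total = NA_real_) {
  df <- data.frame(ligand = ligand, residue = residue, e_elst = e_elst,
                   e_exch = e_exch, e_ind = e_ind, e_disp = e_disp,
                   e_total = e_total, stringsAsFactors = FALSE)
  class(df) <- c("energy_table", "sapt", "data.frame")
  df
}

#' @rdname sapt_record
#' @param e_es,e_ex,e_ct_mix,g_sol PIEDA components, kcal/mol (`e_disp`
#'   shared with the SAPT signature).
#' @export
pieda_record <- function(ligand, residue, e_es, e_ex, e_ct_mix, e_disp,
                         g_sol, e_tot = NA_real_) {
  df <- data.frame(ligand = ligand, residue = residue, e_es = e_es,
                   e_ex = e_ex, e_ct_mix = e_ct_mix, e_disp = e_disp,
                   g_sol = g_sol, e_tot = e_tot, stringsAsFactors = FALSE)
  class(df) <- c("energy_table", "pieda", "data.frame")
  df
}

#' @rdname sapt_record
#' @param hf_complex heat of formation of the protein-ligand complex,
#'   kcal/mol.
#' @param hf_protein_in_complex,hf_ligand_in_complex heats of formation of
#'   protein and ligand frozen in the complex conformation, kcal/mol.
#' @export
enthalpy_record <- function(ligand, hf_complex, hf_protein_in_complex,
                            hf_ligand_in_complex) {
  df <- data.frame(ligand = ligand, hf_complex = hf_complex,
                   hf_protein_in_complex = hf_protein_in_complex,
                   hf_ligand_in_complex = hf_ligand_in_complex,
                   stringsAsFactors = FALSE)
  class(df) <- c("energy_table", "enthalpy", "data.frame")
  df
}
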