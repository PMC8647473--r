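#' Degree of reduction of a C/H/O compound
#'
#' Electron equivalents released on complete oxidation to CO2 and H2O, per
#' mol of compound: `4*C + H - 2*O`. This is the basis on which all
#' selectivity and balance accounting in the package is expressed
#' (1 e- eq corresponds to 8 g COD).
#'
#' @param c_atoms,h_atoms,o_atoms Non-negative integer atom counts.
#' @return Electron equivalents per mol (numeric, vectorised).
#' @examples
#' degree_of_reduction(6, 12, 2)  # n-caproic acid: 32
#' degree_of_reduction(3, 6, 3)   # lactic acid: 12
#' degree_of_reduction(1, 0, 2)   # CO2: 0
#' @export
degree_of_reduction <- function(c_atoms, h_atoms, o_atoms) {
  counts <- c(c_atoms, h_atoms, o_atoms)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("atom counts must be finite and non-negative")
  }
  if (any(abs(counts - round(counts)) > 1e-9)) {
    stop("atom counts must be integers")
  }
  4 * c_atoms + h_atoms - 2 * o_atoms
}

# Standard atomic weights used for the registry sanity check.
.atomic_weights <- c(C = 12.011, H = 1.008, O = 15.999)

#' COD equivalent of one electron equivalent
#'
#' One mol O2 (32 g) accepts 4 electrons, so 1 e- eq corresponds to 8 g O2.
#' @export
COD_PER_ELECTRON_EQ <- 8

#' Compound registry
#'
#' A registry maps compound names to their formula (C/H/O counts), molar
#' mass, carbon count, electron equivalents per mol, acid dissociation
#' constant (pKa, `NA` for non-acids) and whether the compound partitions
#' into a vegetable-oil solvent phase. The shipped default covers the
#' substrates, fermentation products and gases of lactate-based chain
#' elongation (lactate, acetate, propionate, n-butyrate through
#' n-caprylate, H2, CH4) plus CO2.
#'
#' Carboxylates are represented by the free acid's formula and molar mass;
#' a "carboxylate" concentration always means the sum of dissociated and
#' undissociated forms.
#'
#' @param path Path to a registry TSV with columns
#'   `name formula_C formula_H formula_O molar_mass n_carbon electron_eq
#'   pKa extractable`.
#' @return A `compound_registry`, a data.frame with one row per compound.
#' @examples
#' reg <- default_registry()
#' get_compound(reg, "n_caproate")$electron_eq  # 32
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_registry(df)
}

#' @rdname read_registry
#' @export
default_registry <- function() {
  read_registry(system.file("extdata", "compounds.tsv", package = "caproext",
                            mustWork = TRUE))
}

#' @rdname read_registry
#' @param df A data.frame with the registry columns (see `read_registry`).
#' @export
validate_registry <- function(df) {
  required <- c("name", "formula_C", "formula_H", "formula_O", "molar_mass",
                "n_carbon", "electron_eq", "pKa", "extractable")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("registry is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$name)) {
    stop("registry names must be unique: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  }
  dor <- degree_of_reduction(df$formula_C, df$formula_H, df$formula_O)
  bad <- df$name[dor != df$electron_eq]
  if (length(bad) > 0) {
    stop("electron_eq does not match 4C+H-2O for: ", paste(bad, collapse = ", "))
  }
  if (any(df$n_carbon != df$formula_C)) {
    stop("n_carbon must equal formula_C")
  }
  mw_calc <- df$formula_C * .atomic_weights[["C"]] +
    df$formula_H * .atomic_weights[["H"]] +
    df$formula_O * .atomic_weights[["O"]]
  rel <- abs(df$molar_mass - mw_calc) / mw_calc
  if (any(rel > 0.005)) {
    stop("molar_mass deviates >0.5% from formula for: ",
         paste(df$name[rel > 0.005], collapse = ", "))
  }
  df$extractable <- as.logical(df$extractable)
  class(df) <- c("compound_registry", "data.frame")
  df
}

#' @rdname read_registry
#' @param registry A `compound_registry`.
#' @param name Compound name to look up.
#' @export
get_compound <- function(registry, name) {
  stopifnot(inherits(registry, "compound_registry"), length(name) == 1)
  i <- match(name, registry$name)
  if (is.na(i)) {
    stop("unknown compound: '", name, "' (registry has: ",
         paste(registry$name, collapse = ", "), ")")
  }
  as.list(registry[i, , drop = FALSE])
}

#' @export
print.compound_registry <- function(x, ...) {
  cat("<compound_registry> ", nrow(x), " compounds\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Names of the medium-chain carboxylates (C6-C12) in a registry
#' @param registry A `compound_registry`.
#' @return Character vector of compound names with 6-12 carbons that are
#'   carboxylic acids (have a pKa).
#' @export
mcc_names <- function(registry) {
  registry$name[!is.na(registry$pKa) &
                  registry$n_carbon >= 6 & registry$n_carbon <= 12]
}

#' Unit conversions between mass, electron-equivalent, COD and carbon bases
#'
#' All conversions are linear in concentration and exact inverses of each
#' other where applicable.
#'
#' `g_per_l_to_emeq()` converts a mass concentration (g/L) to electron
#' milliequivalents per litre: `conc / molar_mass * electron_eq * 1000`.
#' `emeq_to_g_per_l()` is its inverse. `emeq_to_cod()` converts e- meq/L to
#' g COD/L using 8 g O2 per e- eq. `conc_to_carbon_mmol()` converts g/L to
#' mmol C/L. `mm_to_g_per_l()` and `g_per_l_to_mm()` convert between molar
#' (mM) and mass concentration.
#'
#' @param conc Concentration in g/L (non-negative).
#' @param compound Compound name.
#' @param registry A `compound_registry` (default: the shipped registry).
#' @return Numeric, same length as the concentration input.
#' @examples
#' reg <- default_registry()
#' g_per_l_to_emeq(3.43, "n_caproate", reg)   # ~945 e- meq/L
#' emeq_to_g_per_l(1421, "n_caproate", reg)   # ~5.16 g/L
#' emeq_to_cod(1437.5)                        # 11.5 g COD/L
#' @export
g_per_l_to_emeq <- function(conc, compound, registry = default_registry()) {
  if (any(conc < 0, na.rm = TRUE)) stop("concentration must be >= 0")
  cmp <- get_compound(registry, compound)
  conc / cmp$molar_mass * cmp$electron_eq * 1000
}

#' @rdname g_per_l_to_emeq
#' @param emeq Concentration in e- meq/L.
#' @export
emeq_to_g_per_l <- function(emeq, compound, registry = default_registry()) {
  if (any(emeq < 0, na.rm = TRUE)) stop("e- meq must be >= 0")
  cmp <- get_compound(registry, compound)
  if (cmp$electron_eq == 0) stop("compound has zero electron equivalents: ", compound)
  emeq / cmp$electron_eq * cmp$molar_mass / 1000
}

#' @rdname g_per_l_to_emeq
#' @export
emeq_to_cod <- function(emeq) {
  if (any(emeq < 0, na.rm = TRUE)) stop("e- meq must be >= 0")
  emeq * COD_PER_ELECTRON_EQ / 1000
}

#' @rdname g_per_l_to_emeq
#' @export
conc_to_carbon_mmol <- function(conc, compound, registry = default_registry()) {
  if (any(conc < 0, na.rm = TRUE)) stop("concentration must be >= 0")
  cmp <- get_compound(registry, compound)
  conc / cmp$molar_mass * cmp$n_carbon * 1000
}

#' @rdname g_per_l_to_emeq
#' @param mm Concentration in mmol/L (mM).
#' @export
mm_to_g_per_l <- function(mm, compound, registry = default_registry()) {
  cmp <- get_compound(registry, compound)
  mm * cmp$molar_mass / 1000
}

#' @rdname g_per_l_to_emeq
#' @export
g_per_l_to_mm <- function(conc, compound, registry = default_registry()) {
  cmp <- get_compound(registry, compound)
  conc / cmp$molar_mass * 1000
}
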