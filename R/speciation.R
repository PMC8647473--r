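#' Acid speciation (Henderson-Hasselbalch)
#'
#' Fraction of a monoprotic carboxylic acid present in the undissociated
#' (protonated) form at a given pH:
#' `f_HA = 1 / (1 + 10^(pH - pKa))`.
#'
#' The undissociated species is the membrane-permeant, solvent-extractable
#' form; its concentration drives the product-inhibition thresholds used
#' throughout the package (n-caproic acid becomes rate-limiting around
#' 26 mM and fully inhibitory around 37 mM in lactate-fed chain
#' elongation).
#'
#' @param pH,pKa Finite numerics (vectorised).
#' @return Fraction in (0, 1); 0.5 when `pH == pKa`; strictly decreasing
#'   in pH.
#' @examples
#' undissociated_fraction(4.88, 4.88)  # 0.5
#' undissociated_fraction(5.0, 4.88)   # ~0.43
#' @export
undissociated_fraction <- function(pH, pKa) {
  if (any(!is.finite(pH)) || any(!is.finite(pKa))) {
    stop("pH and pKa must be finite")
  }
  1 / (1 + 10^(pH - pKa))
}

#' Undissociated-acid concentration
#'
#' Multiplies a total (dissociated + undissociated) carboxylate
#' concentration by the undissociated fraction at the given pH, using the
#' compound's registry pKa. Accepts and returns either mass (g/L) or molar
#' (mM) units; `unit` only matters when converting between the two via
#' [mm_to_g_per_l()].
#'
#' @param total Total carboxylate concentration (g/L or mM), >= 0.
#' @param pH Broth pH.
#' @param compound Compound name; must have a pKa in the registry.
#' @param registry A `compound_registry`.
#' @return Undissociated concentration in the same unit as `total`.
#' @examples
#' reg <- default_registry()
#' undissociated_conc(6.5, 5.0, "n_caproate", reg)  # ~2.8 g/L
#' @export
undissociated_conc <- function(total, pH, compound,
                               registry = default_registry()) {
  if (any(total < 0, na.rm = TRUE)) stop("total concentration must be >= 0")
  cmp <- get_compound(registry, compound)
  if (is.na(cmp$pKa)) stop("compound has no pKa: ", compound)
  total * undissociated_fraction(pH, cmp$pKa)
}
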