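#' Liquid-liquid extraction performance metrics
#'
#' Metrics used to characterise carboxylate partitioning between a
#' fermentation broth and a solvent overlay.
#'
#' * `distribution_ratio()` - K_D, the total-concentration ratio
#'   organic/aqueous at sampling pH.
#' * `partition_coefficient()` - P, implemented as the undissociated
#'   aqueous fraction divided by K_D. A small P means the solvent holds
#'   the compound well relative to the extractable (protonated) aqueous
#'   pool. This definition reproduces the reference food-waste values for
#'   nC4/nC5/nC6/nC8 at final pH 4.8 with the shipped pKa table.
#' * `recovery()` - percentage of a compound's total mass residing in the
#'   organic phase. Always computed from measured amounts, never derived
#'   from K_D and nominal volumes (sampling changes the volumes).
#' * `specificity()` - each compound's share (%) of the total carboxylate
#'   mass in the organic phase; sums to 100 over the compounds supplied.
#'
#' @param c_org,c_aq Concentrations in the organic and aqueous phase (g/L).
#' @return `distribution_ratio`: K_D (dimensionless, >= 0).
#' @examples
#' distribution_ratio(16.25, 6.5)                      # 2.5
#' partition_coefficient(2.5, 4.8, "n_caproate")       # ~0.22
#' recovery(33.3, 66.7)                                # 33.3
#' specificity(c(n_butyrate = 30.3, n_caproate = 54.9))
#' @export
distribution_ratio <- function(c_org, c_aq) {
  if (any(c_org < 0) || any(c_aq < 0)) stop("concentrations must be >= 0")
  if (any(c_aq == 0)) stop("K_D undefined: aqueous concentration is zero")
  c_org / c_aq
}

#' @rdname distribution_ratio
#' @param k_d Distribution ratio (> 0).
#' @param pH Sampling pH.
#' @param compound Compound name (must have a pKa).
#' @param registry A `compound_registry`.
#' @export
partition_coefficient <- function(k_d, pH, compound,
                                  registry = default_registry()) {
  if (any(k_d <= 0)) stop("partition coefficient undefined for K_D <= 0")
  cmp <- get_compound(registry, compound)
  if (is.na(cmp$pKa)) stop("compound has no pKa: ", compound)
  undissociated_fraction(pH, cmp$pKa) / k_d
}

#' @rdname distribution_ratio
#' @param amount_org,amount_aq Mass (g) of the compound in each phase.
#' @export
recovery <- function(amount_org, amount_aq) {
  if (any(amount_org < 0) || any(amount_aq < 0)) stop("amounts must be >= 0")
  total <- amount_org + amount_aq
  if (any(total == 0)) stop("recovery undefined: compound absent from both phases")
  100 * amount_org / total
}

#' @rdname distribution_ratio
#' @param org_amounts Named numeric vector of per-compound mass (g) in the
#'   organic phase.
#' @export
specificity <- function(org_amounts) {
  if (length(org_amounts) == 0 || is.null(names(org_amounts))) {
    stop("org_amounts must be a named vector")
  }
  if (any(org_amounts < 0)) stop("amounts must be >= 0")
  total <- sum(org_amounts)
  if (total == 0) stop("specificity undefined: organic phase holds no carboxylates")
  100 * org_amounts / total
}

#' Back-extraction concentration arithmetic
#'
#' Carboxylates in an oil sample are quantified after transfer into an
#' alkaline aqueous phase (e.g. 0.5 M sodium borate at a 1:4
#' oil-to-alkali volume ratio). Assuming complete transfer, the oil-phase
#' concentration is the measured back-extract concentration scaled by the
#' volume ratio: `C_oil = C_back * V_alkali / V_oil`.
#'
#' @param c_back Concentration measured in the alkaline back-extract (g/L).
#' @param v_alkali,v_oil Alkali and oil sample volumes (any common unit,
#'   > 0).
#' @return Concentration in the oil (g/L).
#' @examples
#' back_extraction_conc(18, 2, 0.5)  # 72 g/L in oil
#' @export
back_extraction_conc <- function(c_back, v_alkali, v_oil) {
  if (any(c_back < 0)) stop("concentration must be >= 0")
  if (any(v_alkali <= 0) || any(v_oil <= 0)) stop("volumes must be > 0")
  c_back * v_alkali / v_oil
}

#' MCC-enriched-oil composition report
#'
#' Expresses medium-chain carboxylate concentrations in a vegetable oil as
#' the composition measures used to assess an MCC-enriched oil product:
#'
#' * per-compound percentage of the oil's total carboxylic acids
#'   (`pct_of_ca`), assuming carboxylic acids make up a fraction `f_ca`
#'   (default 0.97) of the oil by weight:
#'   `100 * C_i / (density * 1000 * f_ca)`;
#' * `wt_pct_mcc`: MCC weight percent of the whole oil, computed as the
#'   sum of MCC `pct_of_ca` times `f_ca` (identically
#'   `100 * sum(C_mcc) / (density * 1000)`, the whole-oil basis);
#' * `nc8_to_nc6_molc_pct`: the n-caprylate-to-n-caproate carbon ratio in
#'   % mol C.
#'
#' Either oil concentrations (`conc`, g/L) or already-computed percentages
#' of total carboxylic acids (`pct_of_ca`) may be supplied.
#'
#' @param conc Named vector of MCC concentrations in the oil (g/L).
#' @param pct_of_ca Named vector of per-compound % of total carboxylic
#'   acids (alternative input).
#' @param density Oil density (kg/L), default 0.902 (sunflower oil at room
#'   temperature).
#' @param f_ca Carboxylic-acid mass fraction of the oil, default 0.97.
#' @param registry A `compound_registry`.
#' @return An `oil_composition_report` list with elements `pct_of_ca`,
#'   `wt_pct_mcc`, `wt_pct_whole_oil`, `nc8_to_nc6_molc_pct`, `density`,
#'   `f_ca`.
#' @examples
#' oil_composition_report(conc = c(n_caproate = 72, n_caprylate = 3))
#' @export
oil_composition_report <- function(conc = NULL, pct_of_ca = NULL,
                                   density = 0.902, f_ca = 0.97,
                                   registry = default_registry()) {
  if (is.null(conc) == is.null(pct_of_ca)) {
    stop("supply exactly one of 'conc' (g/L) or 'pct_of_ca' (%)")
  }
  if (density <= 0) stop("density must be > 0")
  if (f_ca <= 0 || f_ca > 1) stop("f_ca must be in (0, 1]")
  if (is.null(pct_of_ca)) {
    if (is.null(names(conc))) stop("'conc' must be named by compound")
    if (any(conc < 0)) stop("concentrations must be >= 0")
    pct_of_ca <- 100 * conc / (density * 1000 * f_ca)
  } else {
    if (is.null(names(pct_of_ca))) stop("'pct_of_ca' must be named by compound")
    if (any(pct_of_ca < 0)) stop("percentages must be >= 0")
    # back out oil concentrations for the mol-C ratio
    conc <- pct_of_ca / 100 * density * 1000 * f_ca
  }
  mcc <- intersect(names(pct_of_ca), mcc_names(registry))
  wt_pct_mcc <- sum(pct_of_ca[mcc]) * f_ca
  wt_pct_whole_oil <- 100 * sum(conc[mcc]) / (density * 1000)

  nc8_to_nc6 <- NA_real_
  if (all(c("n_caproate", "n_caprylate") %in% names(conc))) {
    c6 <- conc[["n_caproate"]]
    c8 <- conc[["n_caprylate"]]
    if (c6 <= 0) stop("nC8-to-nC6 ratio undefined: no n-caproate in oil")
    nc8_to_nc6 <- 100 * conc_to_carbon_mmol(c8, "n_caprylate", registry) /
      conc_to_carbon_mmol(c6, "n_caproate", registry)
  }
  structure(
    list(pct_of_ca = pct_of_ca,
         wt_pct_mcc = wt_pct_mcc,
         wt_pct_whole_oil = wt_pct_whole_oil,
         nc8_to_nc6_molc_pct = nc8_to_nc6,
         density = density, f_ca = f_ca),
    class = "oil_composition_report")
}

#' @export
print.oil_composition_report <- function(x, ...) {
  cat("<oil_composition_report>\n")
  cat("  % of total carboxylic acids:\n")
  for (nm in names(x$pct_of_ca)) {
    cat(sprintf("    %-12s %6.2f %%\n", nm, x$pct_of_ca[[nm]]))
  }
  cat(sprintf("  wt%% MCC of oil:        %.2f (f_CA = %.2f)\n",
              x$wt_pct_mcc, x$f_ca))
  cat(sprintf("  wt%% MCC (whole-oil):   %.2f (density %.3f kg/L)\n",
              x$wt_pct_whole_oil, x$density))
  if (!is.na(x$nc8_to_nc6_molc_pct)) {
    cat(sprintf("  nC8-to-nC6:            %.1f %% mol C\n", x$nc8_to_nc6_molc_pct))
  }
  invisible(x)
}

#' Extraction metrics from a batch two-phase experiment table
#'
#' Takes a tidy table of end-point (or time-course) concentrations in both
#' phases of a closed two-phase bottle and emits the per-compound
#' extraction metrics (K_D, P, recovery, specificity) at the final
#' timepoint.
#'
#' @param df Data frame with columns `time_d`, `phase`
#'   (`"aqueous"`/`"organic"`), `compound`, `conc_g_per_L` and `pH`.
#' @param v_aq,v_org Phase volumes (L), used to convert concentrations to
#'   amounts for recovery/specificity.
#' @param registry A `compound_registry`.
#' @return A data.frame with one row per compound found in the organic
#'   phase: `compound, K_D, P, recovery_pct, specificity_pct, pH`.
#' @export
batch_extraction_metrics <- function(df, v_aq, v_org,
                                     registry = default_registry()) {
  required <- c("time_d", "phase", "compound", "conc_g_per_L", "pH")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("input is missing columns: ", paste(missing, collapse = ", "))
  }
  if (v_aq <= 0 || v_org <= 0) stop("volumes must be > 0")
  bad <- setdiff(unique(df$compound), registry$name)
  if (length(bad) > 0) stop("unknown compound(s): ", paste(bad, collapse = ", "))
  tf <- max(df$time_d)
  fin <- df[df$time_d == tf, , drop = FALSE]
  ph <- fin$pH[[1]]
  compounds <- sort(unique(fin$compound))
  conc_of <- function(cmp, phase) {
    v <- fin$conc_g_per_L[fin$compound == cmp & fin$phase == phase]
    if (length(v) == 0) 0 else v[[1]]
  }
  c_aq <- vapply(compounds, conc_of, numeric(1), phase = "aqueous")
  c_org <- vapply(compounds, conc_of, numeric(1), phase = "organic")
  keep <- c_org > 0
  if (!any(keep)) stop("no compound detected in the organic phase")
  spec <- specificity(c_org[keep] * v_org)
  out <- data.frame(
    compound = compounds[keep],
    K_D = distribution_ratio(c_org[keep], c_aq[keep]),
    P = NA_real_,
    recovery_pct = recovery(c_org[keep] * v_org, c_aq[keep] * v_aq),
    specificity_pct = as.numeric(spec),
    pH = ph,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(out))) {
    cmp <- get_compound(registry, out$compound[i])
    if (!is.na(cmp$pKa) && out$K_D[i] > 0) {
      out$P[i] <- partition_coefficient(out$K_D[i], ph, out$compound[i], registry)
    }
  }
  rownames(out) <- NULL
  out
}
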