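#' Period-averaged production rate of a compound
#'
#' Net volumetric production rate of a carboxylate over an operating
#' period, counting both phases and normalising to the aqueous working
#' volume:
#' `r = D * (C_aq_mean - C_feed) + dM_org / (V_aq * dt)`.
#'
#' The rate is computed per sampling interval inside the period (interval
#' mean aqueous concentration; organic-phase mass increment over the
#' interval) and the per-interval rates are averaged arithmetically, the
#' first timepoint of the period serving as baseline. Negative organic
#' increments (re-solubilisation from the solvent back into the broth)
#' enter with their sign and are not clipped.
#'
#' @param ts A `reactor_timeseries`.
#' @param cfg A `reactor_config`.
#' @param period Numeric `c(t_start, t_end)` in days (inclusive).
#' @param compound Compound name present in the series.
#' @param registry A `compound_registry`.
#' @param unit `"g_per_l_d"` (default) or `"emeq_per_l_d"`.
#' @return Net production rate (negative = net consumption).
#' @export
production_rate <- function(ts, cfg, period, compound,
                            registry = default_registry(),
                            unit = c("g_per_l_d", "emeq_per_l_d")) {
  unit <- match.arg(unit)
  if (!compound %in% ts_compounds(ts)) {
    stop("compound missing from series: ", compound)
  }
  sub <- .period_rows(ts, period)
  caq <- .aq(sub, compound)
  corg <- .org(sub, compound)
  feed <- if (compound %in% names(cfg$feed)) cfg$feed[[compound]] else 0
  dt <- diff(sub$time_d)
  caq_mid <- (caq[-1] + caq[-length(caq)]) / 2
  r_aq <- cfg$dilution_rate * (caq_mid - feed)
  r_org <- diff(corg) * cfg$v_org / (cfg$v_aq * dt)
  r <- mean(r_aq + r_org)
  if (unit == "emeq_per_l_d") r <- g_per_l_to_emeq(abs(r), compound, registry) * sign(r)
  r
}

.period_rows <- function(ts, period) {
  if (length(period) != 2 || period[1] >= period[2]) {
    stop("period must be c(t_start, t_end) with t_start < t_end")
  }
  sub <- ts[ts$time_d >= period[1] & ts$time_d <= period[2], , drop = FALSE]
  if (nrow(sub) < 2) {
    stop("period [", period[1], ", ", period[2], "] contains fewer than 2 timepoints")
  }
  sub
}

# Time-weighted (trapezoidal) mean of a column over the period rows.
.tw_mean <- function(time, x) {
  if (length(time) < 2) return(x[1])
  dt <- diff(time)
  sum((x[-1] + x[-length(x)]) / 2 * dt) / sum(dt)
}

#' Net production rates of every compound in a series
#'
#' @inheritParams production_rate
#' @return Named numeric vector of net rates over the period.
#' @export
production_rates <- function(ts, cfg, period, registry = default_registry(),
                             unit = c("g_per_l_d", "emeq_per_l_d")) {
  unit <- match.arg(unit)
  cmps <- ts_compounds(ts)
  vapply(cmps, function(cmp) {
    production_rate(ts, cfg, period, cmp, registry, unit)
  }, numeric(1))
}

#' Period-averaged gas production rate
#'
#' @inheritParams production_rate
#' @param gas One of `"h2"`, `"ch4"`, `"co2"`.
#' @param per_litre If `TRUE` (default) normalise the per-reactor mmol/d
#'   column to the aqueous working volume (mmol/L/d).
#' @return Mean gas production rate over the period; 0 when the column is
#'   absent.
#' @export
gas_rate <- function(ts, cfg, period, gas = c("h2", "ch4", "co2"),
                     per_litre = TRUE) {
  gas <- match.arg(gas)
  col <- paste0("gas_", gas, "_mmol_per_d")
  sub <- .period_rows(ts, period)
  if (!col %in% names(sub)) return(0)
  r <- .tw_mean(sub$time_d, sub[[col]])
  if (per_litre) r / cfg$v_aq else r
}

#' Extraction flux into the solvent phase
#'
#' Mass transferred to the organic phase per unit broth volume and time,
#' from the cumulative organic-phase inventory between contiguous
#' sampling points. Negative values (re-solubilisation) are retained.
#'
#' @inheritParams production_rate
#' @return Flux in g/L_broth/d.
#' @export
extraction_flux <- function(ts, cfg, period, compound) {
  sub <- .period_rows(ts, period)
  corg <- .org(sub, compound)
  mean(diff(corg) * cfg$v_org / (cfg$v_aq * diff(sub$time_d)))
}

#' Areal extraction flux across the broth-solvent interface
#'
#' Converts a volumetric flux (g per litre of broth per day) to a flux
#' per interface area, using the vessel cross-section
#' `A = pi * diameter^2 / 4`: `flux * V_aq / A`.
#'
#' @param volumetric_flux Flux in g/L_broth/d.
#' @param cfg A `reactor_config`.
#' @return Flux in g/m2/d.
#' @examples
#' areal_flux(1.881, reactor_config())  # ~260.7 g/m2/d
#' @export
areal_flux <- function(volumetric_flux, cfg) {
  volumetric_flux * cfg$v_aq / cfg$interface_area_m2
}

#' Electron selectivity of net-produced species
#'
#' Shares each net-produced species' electron-equivalent rate against the
#' total over all net products (carboxylates with a positive net rate
#' plus H2 and CH4). Net-consumed substrates (negative rates) are
#' excluded from the denominator; acetate therefore counts as a substrate
#' when net-consumed and as a product when net-produced.
#'
#' @param rates Named vector of net rates in e- meq/L/d (products
#'   positive, substrates negative).
#' @param registry A `compound_registry` (used to identify the MCC pool).
#' @return List with `per_product` (named %, summing to 100 over the
#'   products) and `mcc` (% of product electrons in C6-C12 carboxylates).
#' @export
electron_selectivity <- function(rates, registry = default_registry()) {
  if (is.null(names(rates))) stop("rates must be named")
  prod <- rates[rates > 0]
  if (length(prod) == 0) stop("no net-produced species: all rates <= 0")
  sel <- 100 * prod / sum(prod)
  list(per_product = sel,
       mcc = sum(sel[names(sel) %in% mcc_names(registry)]))
}

#' Carbon selectivity and conversion efficiency
#'
#' Carbon selectivity of a product is its carbon rate over the total
#' product carbon rate (including CO2); carbon conversion efficiency is
#' its carbon rate over the substrate carbon consumed. Both are returned
#' for every product supplied.
#'
#' @param product_rates_mmolc Named vector of product carbon rates
#'   (mmol C/L/d), CO2 included under the name `"co2"` when measured.
#' @param substrate_mmolc Substrate carbon consumption rate (mmol C/L/d,
#'   > 0).
#' @return List with `selectivity_pct` and `efficiency_pct` (named, CO2
#'   excluded from the named outputs but included in the selectivity
#'   denominator).
#' @export
carbon_selectivity_and_efficiency <- function(product_rates_mmolc,
                                              substrate_mmolc) {
  if (is.null(names(product_rates_mmolc))) stop("product rates must be named")
  if (any(product_rates_mmolc < 0)) stop("product carbon rates must be >= 0")
  if (substrate_mmolc <= 0) stop("substrate carbon consumption must be > 0")
  total <- sum(product_rates_mmolc)
  if (total == 0) stop("no product carbon")
  keep <- setdiff(names(product_rates_mmolc), "co2")
  list(selectivity_pct = 100 * product_rates_mmolc[keep] / total,
       efficiency_pct = 100 * product_rates_mmolc[keep] / substrate_mmolc)
}

#' Acid dose per mol of MCC produced
#'
#' Converts an acid dosing rate and a set of MCC production rates into
#' mol H+ dosed per mol MCC produced. Each MCC's molar rate uses its own
#' electron equivalents (`r_i / e_i`), not an n-caproate lump.
#'
#' @param acid_rate Acid dose in mmol H+/L/d.
#' @param mcc_rates_emeq Named vector of MCC production rates
#'   (e- meq/L/d).
#' @param registry A `compound_registry`.
#' @return mol H+ per mol MCC (0 when no acid is dosed).
#' @examples
#' acid_dose_metrics(76, c(n_caproate = 969))  # ~2.51
#' @export
acid_dose_metrics <- function(acid_rate, mcc_rates_emeq,
                              registry = default_registry()) {
  if (is.null(names(mcc_rates_emeq))) stop("MCC rates must be named")
  e <- vapply(names(mcc_rates_emeq), function(nm) {
    get_compound(registry, nm)$electron_eq
  }, numeric(1))
  molar <- sum(mcc_rates_emeq / e)  # mmol MCC/L/d
  if (molar <= 0) stop("MCC molar production rate must be > 0")
  acid_rate / molar
}

#' Electron and carbon balance closure over a period
#'
#' Computes the relative gap `(inflow - outflow - accumulation) / inflow`
#' on both the electron-equivalent and the carbon-mol basis. Inflow is
#' the feed; outflow is the effluent (period-mean aqueous
#' concentrations), the organic-phase accumulation and the gas ledger;
#' aqueous accumulation over the period is accounted separately. A
#' positive gap is the fraction of the incoming electrons/carbon not
#' found in tracked pools, conventionally assigned to biomass; negative
#' gaps are reported as-is (flagged by sign).
#'
#' @inheritParams production_rate
#' @return List with `electron_gap_pct`, `carbon_gap_pct` and the
#'   underlying rates (`electron` and `carbon` sublists, e- meq/L/d and
#'   mmol C/L/d).
#' @export
balance_closure <- function(ts, cfg, period, registry = default_registry()) {
  sub <- .period_rows(ts, period)
  cmps <- ts_compounds(ts)
  dt_total <- diff(range(sub$time_d))
  basis <- function(conv) {
    inflow <- sum(vapply(names(cfg$feed), function(cmp) {
      cfg$dilution_rate * conv(cfg$feed[[cmp]], cmp)
    }, numeric(1)))
    if (inflow == 0) stop("zero inflow: balance gap undefined")
    out_aq <- sum(vapply(cmps, function(cmp) {
      cfg$dilution_rate * conv(.tw_mean(sub$time_d, .aq(sub, cmp)), cmp)
    }, numeric(1)))
    out_org <- sum(vapply(cmps, function(cmp) {
      corg <- .org(sub, cmp)
      conv(corg[length(corg)] - corg[1], cmp) * cfg$v_org / (cfg$v_aq * dt_total)
    }, numeric(1)))
    acc_aq <- sum(vapply(cmps, function(cmp) {
      caq <- .aq(sub, cmp)
      conv(caq[length(caq)] - caq[1], cmp) / dt_total
    }, numeric(1)))
    list(inflow = inflow, out_aq = out_aq, out_org = out_org, acc_aq = acc_aq)
  }
  e_conv <- function(x, cmp) g_per_l_to_emeq(abs(x), cmp, registry) * sign(x)
  c_conv <- function(x, cmp) conc_to_carbon_mmol(abs(x), cmp, registry) * sign(x)
  el <- basis(e_conv)
  ca <- basis(c_conv)
  # gases: electrons for H2/CH4, carbon for CH4/CO2 (per-L rates)
  el$gas <- gas_rate(ts, cfg, period, "h2") * 2 +
    gas_rate(ts, cfg, period, "ch4") * 8
  ca$gas <- gas_rate(ts, cfg, period, "ch4") +
    gas_rate(ts, cfg, period, "co2")
  gap <- function(b) 100 * (b$inflow - b$out_aq - b$out_org - b$acc_aq - b$gas) / b$inflow
  list(electron_gap_pct = gap(el), carbon_gap_pct = gap(ca),
       electron = el, carbon = ca)
}

#' Stoichiometric summary of a period
#'
#' Molar consumption/production ratios used to characterise the
#' lactate-elongating stoichiometry: the lactate-to-acetate molar
#' consumption ratio and the n-caproate yield on lactate
#' (mol nC6 per mol lactate consumed).
#'
#' @inheritParams production_rate
#' @return List with `lactate_mmol_per_l_d` and `acetate_mmol_per_l_d`
#'   (consumption, positive), `nc6_mmol_per_l_d` (production),
#'   `lactate_to_acetate` and `nc6_yield_mol_mol`.
#' @export
stoichiometric_summary <- function(ts, cfg, period,
                                   registry = default_registry()) {
  molar <- function(cmp) {
    r <- production_rate(ts, cfg, period, cmp, registry)
    g_per_l_to_mm(abs(r), cmp, registry) * sign(r)  # mmol/L/d, signed
  }
  lac <- -molar("lactate")
  if (lac <= 0) stop("no net lactate consumption in period")
  ace <- -molar("acetate")
  ratio <- if (ace <= 0) {
    warning("no net acetate consumption: lactate-to-acetate ratio undefined")
    NA_real_
  } else lac / ace
  nc6 <- if ("n_caproate" %in% ts_compounds(ts)) molar("n_caproate") else 0
  list(lactate_mmol_per_l_d = lac, acetate_mmol_per_l_d = ace,
       nc6_mmol_per_l_d = nc6,
       lactate_to_acetate = ratio,
       nc6_yield_mol_mol = nc6 / lac)
}

#' Full performance summary over one or more periods
#'
#' Runs the period-level accounting (net rates in both unit systems,
#' electron and carbon selectivities, conversion efficiency, acid-dose
#' metrics, balance gaps) for each labelled period.
#'
#' When no measured CO2 column is present, the CO2 carbon rate used in
#' the carbon-selectivity denominator is estimated from the lactate
#' consumption stoichiometry (1 CO2 per lactate oxidised in the
#' elongation steps) and the estimate is flagged in the output.
#'
#' @param ts A `reactor_timeseries`.
#' @param cfg A `reactor_config`.
#' @param periods Named list of `c(t_start, t_end)` vectors.
#' @param registry A `compound_registry`.
#' @return A `performance_summary` list with elements `rates` (long
#'   data.frame: period, compound, rate in g/L/d and e- meq/L/d,
#'   electron selectivity) and `summary` (one row per period).
#' @export
performance_summary <- function(ts, cfg, periods,
                                registry = default_registry()) {
  if (is.null(names(periods)) || any(names(periods) == "")) {
    stop("periods must be a named list")
  }
  rates_rows <- list()
  summary_rows <- list()
  for (label in names(periods)) {
    period <- periods[[label]]
    r_g <- production_rates(ts, cfg, period, registry)
    r_e <- vapply(names(r_g), function(cmp) {
      g_per_l_to_emeq(abs(r_g[[cmp]]), cmp, registry) * sign(r_g[[cmp]])
    }, numeric(1))
    gases <- c(h2 = gas_rate(ts, cfg, period, "h2") * 2,
               ch4 = gas_rate(ts, cfg, period, "ch4") * 8)
    esel <- electron_selectivity(c(r_e, gases), registry)
    sel_of <- function(nm) {
      if (nm %in% names(esel$per_product)) esel$per_product[[nm]] else 0
    }
    rates_rows[[label]] <- data.frame(
      period = label, compound = names(r_g),
      rate_g_per_L_d = as.numeric(r_g),
      rate_emeq_per_L_d = as.numeric(r_e),
      electron_selectivity_pct = vapply(names(r_g), sel_of, numeric(1)),
      stringsAsFactors = FALSE)

    # carbon accounting
    prod_c <- r_g[r_g > 0]
    prod_mmolc <- vapply(names(prod_c), function(cmp) {
      conc_to_carbon_mmol(prod_c[[cmp]], cmp, registry)
    }, numeric(1))
    lac_mmol <- g_per_l_to_mm(-min(r_g[["lactate"]], 0), "lactate", registry)
    co2_measured <- paste0("gas_co2_mmol_per_d") %in% names(ts)
    co2_mmolc <- if (co2_measured) gas_rate(ts, cfg, period, "co2") else lac_mmol
    subs <- r_g[r_g < 0]
    sub_mmolc <- sum(vapply(names(subs), function(cmp) {
      conc_to_carbon_mmol(-subs[[cmp]], cmp, registry)
    }, numeric(1)))
    cs <- carbon_selectivity_and_efficiency(
      c(prod_mmolc, co2 = co2_mmolc), sub_mmolc)

    acid_rate <- if ("acid_mmol_per_d" %in% names(ts)) {
      .tw_mean(.period_rows(ts, period)$time_d,
               .period_rows(ts, period)$acid_mmol_per_d) / cfg$v_aq
    } else NA_real_
    mcc <- intersect(names(r_e)[r_e > 0], mcc_names(registry))
    acid_per_mcc <- if (!is.na(acid_rate) && length(mcc) > 0) {
      acid_dose_metrics(acid_rate, r_e[mcc], registry)
    } else NA_real_
    bc <- balance_closure(ts, cfg, period, registry)
    stoich <- tryCatch(
      suppressWarnings(stoichiometric_summary(ts, cfg, period, registry)),
      error = function(e) list(lactate_to_acetate = NA_real_,
                               nc6_yield_mol_mol = NA_real_))

    summary_rows[[label]] <- data.frame(
      period = label, t_start = period[1], t_end = period[2],
      nc6_rate_g_per_L_d = if ("n_caproate" %in% names(r_g)) r_g[["n_caproate"]] else NA_real_,
      mcc_rate_emeq_per_L_d = sum(r_e[mcc]),
      nc6_electron_selectivity_pct = sel_of("n_caproate"),
      mcc_electron_selectivity_pct = esel$mcc,
      nc6_carbon_selectivity_pct =
        if ("n_caproate" %in% names(cs$selectivity_pct)) cs$selectivity_pct[["n_caproate"]] else NA_real_,
      nc6_carbon_efficiency_pct =
        if ("n_caproate" %in% names(cs$efficiency_pct)) cs$efficiency_pct[["n_caproate"]] else NA_real_,
      co2_estimated = !co2_measured,
      acid_mmol_per_L_d = acid_rate,
      acid_mol_per_mol_mcc = acid_per_mcc,
      lactate_to_acetate = stoich$lactate_to_acetate,
      nc6_yield_mol_mol = stoich$nc6_yield_mol_mol,
      electron_gap_pct = bc$electron_gap_pct,
      carbon_gap_pct = bc$carbon_gap_pct,
      stringsAsFactors = FALSE)
  }
  structure(
    list(rates = do.call(rbind, c(rates_rows, list(make.row.names = FALSE))),
         summary = do.call(rbind, c(summary_rows, list(make.row.names = FALSE)))),
    class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat("<performance_summary> ", nrow(x$summary), " period(s)\n", sep = "")
  cols <- c("period", "nc6_rate_g_per_L_d", "nc6_electron_selectivity_pct",
            "mcc_electron_selectivity_pct", "electron_gap_pct")
  print.data.frame(x$summary[, cols], row.names = FALSE, digits = 3)
  invisible(x)
}
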