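#' Reactor configuration
#'
#' Geometry, hydraulics and feed of a (two-phase) chain-elongation
#' reactor. Defaults are a 1.2-L working-volume CSTR of 10.5 cm diameter
#' at a hydraulic retention time (HRT) of 2 d, fed l-lactate at 40 g/L
#' (electron donor) and acetate at 5 g/L (electron acceptor) at pH 5.0,
#' with a static solvent overlay of 20% v/v when `v_org > 0`.
#'
#' @param v_aq Aqueous working volume (L).
#' @param v_org Organic (solvent) phase volume (L); 0 for single-phase
#'   operation.
#' @param hrt Hydraulic retention time (d). The dilution rate is
#'   `D = 1/hrt` (for batch operation use `hrt = Inf`, giving `D = 0`).
#' @param diameter Vessel inner diameter (m); sets the broth-solvent
#'   interface area `pi * diameter^2 / 4` used for areal fluxes.
#' @param feed Named vector of feed concentrations (g/L).
#' @param ph_setpoint Controlled broth pH.
#' @return A `reactor_config` list, with derived fields `dilution_rate`
#'   (1/d) and `interface_area_m2`.
#' @examples
#' cfg <- reactor_config()
#' cfg$dilution_rate      # 0.5 /d
#' cfg$interface_area_m2  # ~8.66e-3 m2
#' @export
reactor_config <- function(v_aq = 1.2, v_org = 0.24, hrt = 2,
                           diameter = 0.105,
                           feed = c(lactate = 40, acetate = 5),
                           ph_setpoint = 5.0) {
  if (v_aq <= 0) stop("v_aq must be > 0")
  if (v_org < 0) stop("v_org must be >= 0")
  if (hrt <= 0) stop("hrt must be > 0")
  if (diameter <= 0) stop("diameter must be > 0")
  if (length(feed) > 0 && (is.null(names(feed)) || any(feed < 0))) {
    stop("feed must be a named vector of non-negative g/L values")
  }
  structure(
    list(v_aq = v_aq, v_org = v_org, hrt = hrt,
         dilution_rate = 1 / hrt,
         diameter = diameter,
         interface_area_m2 = pi * diameter^2 / 4,
         feed = feed, ph_setpoint = ph_setpoint),
    class = "reactor_config")
}

#' @export
print.reactor_config <- function(x, ...) {
  cat("<reactor_config>\n")
  cat(sprintf("  V_aq %.3g L | V_org %.3g L | HRT %.3g d (D = %.3g /d)\n",
              x$v_aq, x$v_org, x$hrt, x$dilution_rate))
  cat(sprintf("  diameter %.3g m (interface %.3g m2) | pH setpoint %.2f\n",
              x$diameter, x$interface_area_m2, x$ph_setpoint))
  if (length(x$feed) > 0) {
    cat("  feed (g/L):", paste(sprintf("%s %.3g", names(x$feed), x$feed),
                               collapse = ", "), "\n")
  }
  invisible(x)
}

# Column naming scheme of a reactor time series.
.aq_col <- function(cmp) paste0(cmp, "_aq_g_per_L")
.org_col <- function(cmp) paste0(cmp, "_org_g_per_L")

#' Reactor time series
#'
#' Validates a per-timepoint table of reactor observations and tags it as
#' a `reactor_timeseries`. Columns are `time_d` (strictly increasing),
#' `pH`, optional `acid_mmol_per_d` (acid dosed per reactor),
#' `gas_h2_mmol_per_d`/`gas_ch4_mmol_per_d`/`gas_co2_mmol_per_d`
#' (per-reactor gas production), and per-compound concentrations named
#' `<compound>_aq_g_per_L` / `<compound>_org_g_per_L`. Compound names must
#' exist in the registry; the offending column is named otherwise.
#'
#' @param df A data.frame with the columns above.
#' @param registry A `compound_registry`.
#' @return A `reactor_timeseries` (data.frame).
#' @export
reactor_timeseries <- function(df, registry = default_registry()) {
  if (!"time_d" %in% names(df)) stop("missing required column: time_d")
  if (!"pH" %in% names(df)) stop("missing required column: pH")
  if (nrow(df) > 1 && any(diff(df$time_d) <= 0)) {
    i <- which(diff(df$time_d) <= 0)[1]
    stop("time_d must be strictly increasing (violated at row ", i + 1, ")")
  }
  conc_cols <- grep("_(aq|org)_g_per_L$", names(df), value = TRUE)
  cmps <- unique(sub("_(aq|org)_g_per_L$", "", conc_cols))
  bad <- setdiff(cmps, registry$name)
  if (length(bad) > 0) {
    stop("unknown compound column(s): ",
         paste(conc_cols[sub("_(aq|org)_g_per_L$", "", conc_cols) %in% bad],
               collapse = ", "))
  }
  for (col in conc_cols) {
    if (any(df[[col]] < 0, na.rm = TRUE)) {
      stop("negative concentration in column ", col)
    }
  }
  class(df) <- unique(c("reactor_timeseries", class(df)))
  df
}

#' @rdname reactor_timeseries
#' @param ts A `reactor_timeseries`.
#' @export
ts_compounds <- function(ts) {
  conc_cols <- grep("_(aq|org)_g_per_L$", names(ts), value = TRUE)
  unique(sub("_(aq|org)_g_per_L$", "", conc_cols))
}

# Aqueous / organic concentration vectors; zeros when the column is absent
# (e.g. organic phase of a non-extractable compound or single-phase run).
.aq <- function(ts, cmp) {
  col <- .aq_col(cmp)
  if (col %in% names(ts)) ts[[col]] else rep(0, nrow(ts))
}
.org <- function(ts, cmp) {
  col <- .org_col(cmp)
  if (col %in% names(ts)) ts[[col]] else rep(0, nrow(ts))
}

#' @export
print.reactor_timeseries <- function(x, ...) {
  cat("<reactor_timeseries> ", nrow(x), " timepoints, t = ",
      min(x$time_d), "..", max(x$time_d), " d; compounds: ",
      paste(ts_compounds(x), collapse = ", "), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 4), row.names = FALSE)
  if (nrow(x) > 4) cat("  ... ", nrow(x) - 4, " more rows\n", sep = "")
  invisible(x)
}
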