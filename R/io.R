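#' Read / write a reactor time series CSV
#'
#' The on-disk format is a UTF-8 comma-separated file with a mandatory
#' header, `.` as decimal mark and time in days as a float:
#' `time_d, pH, acid_mmol_per_d, gas_*_mmol_per_d,
#' <compound>_aq_g_per_L, <compound>_org_g_per_L`. Reading validates the
#' table (strictly increasing time, non-negative concentrations, known
#' compounds) via [reactor_timeseries()].
#'
#' @param path CSV path.
#' @param registry A `compound_registry`.
#' @return `read_timeseries()`: a `reactor_timeseries`.
#' @export
read_timeseries <- function(path, registry = default_registry()) {
  if (!file.exists(path)) stop("time-series file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  reactor_timeseries(df, registry)
}

#' @rdname read_timeseries
#' @param ts A `reactor_timeseries`.
#' @export
write_timeseries <- function(ts, path) {
  utils::write.csv(as.data.frame(ts), path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a pipeline run configuration
#'
#' YAML file with blocks: `reactor` (arguments of [reactor_config()]),
#' `periods` (list of `{label, t_start, t_end}`), optional `simulator`
#' (arguments of [sim_params()] plus `t_end`, `dt_out`, `noise_sd`),
#' optional `timeseries` (path to a CSV instead of simulating), optional
#' `registry` (path to a registry TSV), `seed`, and `oil` (`density`,
#' `f_ca`).
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config A list with the structure above.
#' @export
validate_run_config <- function(config) {
  if (is.null(config$timeseries) && is.null(config$simulator)) {
    stop("config needs either a 'timeseries' path or a 'simulator' block")
  }
  periods <- config$periods
  if (!is.null(periods)) {
    for (p in periods) {
      if (is.null(p$label) || is.null(p$t_start) || is.null(p$t_end)) {
        stop("each period needs label, t_start, t_end")
      }
      if (p$t_start >= p$t_end) {
        stop("period '", p$label, "': t_start must be < t_end")
      }
    }
    labs <- vapply(periods, `[[`, character(1), "label")
    if (anyDuplicated(labs)) stop("period labels must be unique")
    iv <- cbind(vapply(periods, `[[`, numeric(1), "t_start"),
                vapply(periods, `[[`, numeric(1), "t_end"))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2])) {
      stop("periods must not overlap")
    }
  }
  if (is.null(config$seed)) config$seed <- 1
  structure(config, class = "run_config")
}

.periods_as_list <- function(config) {
  if (is.null(config$periods)) return(list())
  out <- lapply(config$periods, function(p) c(p$t_start, p$t_end))
  names(out) <- vapply(config$periods, `[[`, character(1), "label")
  out
}

#' Run the full analysis pipeline
#'
#' Obtains a reactor time series (from a CSV or by running the
#' simulator per the config), then executes the speciation/extraction
#' and performance stages for each configured period. Deterministic
#' given the config and inputs.
#'
#' @param config A `run_config` (or a list accepted by
#'   [validate_run_config()]).
#' @return A `report_bundle` list: `performance` (a
#'   `performance_summary`), `extraction` (per-period K_D/recovery table,
#'   `NULL` without an organic phase), `oil_composition`
#'   (an `oil_composition_report` from the final solvent sample),
#'   `flux_table` (source/target/mmol C/d triplets per period),
#'   `closure` (per-period balance gaps), `provenance`.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(unclass(config))
  registry <- if (!is.null(config$registry)) {
    read_registry(config$registry)
  } else default_registry()

  rc_args <- config$reactor
  cfg <- if (is.null(rc_args)) reactor_config() else {
    if (!is.null(rc_args$feed)) rc_args$feed <- unlist(rc_args$feed)
    do.call(reactor_config, rc_args)
  }

  sim <- NULL
  if (!is.null(config$timeseries)) {
    ts <- read_timeseries(config$timeseries, registry)
  } else {
    sp_args <- config$simulator
    t_end <- sp_args$t_end %||% 120
    dt_out <- sp_args$dt_out %||% 0.5
    noise_sd <- sp_args$noise_sd %||% 0
    sp_args[c("t_end", "dt_out", "noise_sd")] <- NULL
    for (nm in c("q_max", "k_d", "ka", "init")) {
      if (!is.null(sp_args[[nm]])) sp_args[[nm]] <- unlist(sp_args[[nm]])
    }
    params <- do.call(sim_params, sp_args)
    sim <- simulate_cstr(params, cfg, t_end = t_end, dt_out = dt_out)
    ts <- sim$ts
    if (noise_sd > 0) ts <- add_measurement_noise(ts, noise_sd, config$seed)
  }

  periods <- .periods_as_list(config)
  if (length(periods) == 0) {
    periods <- list(global = range(ts$time_d))
  }
  perf <- performance_summary(ts, cfg, periods, registry)

  has_org <- any(grepl("_org_g_per_L$", names(ts)))
  extraction <- NULL
  oil <- NULL
  if (has_org) {
    extraction <- do.call(rbind, lapply(names(periods), function(label) {
      period <- periods[[label]]
      sub <- .period_rows(ts, period)
      last <- sub[nrow(sub), , drop = FALSE]
      cmps <- ts_compounds(ts)
      corg <- vapply(cmps, function(cmp) .org(last, cmp), numeric(1))
      caq <- vapply(cmps, function(cmp) .aq(last, cmp), numeric(1))
      keep <- corg > 0
      if (!any(keep)) return(NULL)
      spec <- specificity(corg[keep] * cfg$v_org)
      data.frame(period = label, compound = cmps[keep],
                 K_D = ifelse(caq[keep] > 0, corg[keep] / caq[keep], NA_real_),
                 recovery_pct = recovery(corg[keep] * cfg$v_org,
                                         caq[keep] * cfg$v_aq),
                 specificity_pct = as.numeric(spec),
                 stringsAsFactors = FALSE)
    }))
    oil_density <- config$oil$density %||% 0.902
    oil_fca <- config$oil$f_ca %||% 0.97
    final <- ts[nrow(ts), , drop = FALSE]
    conc <- vapply(ts_compounds(ts), function(cmp) .org(final, cmp), numeric(1))
    conc <- conc[conc > 0]
    if (length(conc) > 0) {
      oil <- oil_composition_report(conc = conc, density = oil_density,
                                    f_ca = oil_fca, registry = registry)
    }
  }

  flux <- do.call(rbind, lapply(names(periods), function(label) {
    carbon_flux_table(ts, cfg, periods[[label]], registry, label = label)
  }))

  closure <- do.call(rbind, lapply(names(periods), function(label) {
    bc <- balance_closure(ts, cfg, periods[[label]], registry)
    data.frame(period = label,
               electron_gap_pct = bc$electron_gap_pct,
               carbon_gap_pct = bc$carbon_gap_pct,
               stringsAsFactors = FALSE)
  }))

  structure(
    list(performance = perf, extraction = extraction,
         oil_composition = oil, flux_table = flux, closure = closure,
         ts = ts, sim = sim,
         provenance = list(
           package_version = as.character(utils::packageVersion("caproext")),
           seed = config$seed,
           periods = names(periods))),
    class = "report_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Carbon flux table for Sankey rendering
#'
#' Period-averaged carbon flows in `source, target, mmolC_per_d` triplet
#' form: feed carbon into the broth per substrate; broth carbon out to
#' each net product (both phases), to the residual substrates in the
#' effluent, to CO2, and the unassigned remainder to biomass (the
#' missing-carbon convention). Inflows equal outflows by construction.
#'
#' @inheritParams production_rate
#' @param label Period label written into the table.
#' @return Data frame `period, source, target, mmolC_per_d` (per
#'   reactor).
#' @export
carbon_flux_table <- function(ts, cfg, period, registry = default_registry(),
                              label = "period") {
  sub <- .period_rows(ts, period)
  rows <- list()
  add <- function(source, target, mmolc) {
    rows[[length(rows) + 1]] <<- data.frame(
      period = label, source = source, target = target,
      mmolC_per_d = mmolc, stringsAsFactors = FALSE)
  }
  inflow_total <- 0
  for (cmp in names(cfg$feed)) {
    f <- cfg$dilution_rate * conc_to_carbon_mmol(cfg$feed[[cmp]], cmp, registry) *
      cfg$v_aq
    inflow_total <- inflow_total + f
    add(paste0("feed:", cmp), "broth", f)
  }
  out_total <- 0
  rates <- production_rates(ts, cfg, period, registry)
  for (cmp in names(rates)) {
    r <- rates[[cmp]]
    if (r > 0) {
      f <- conc_to_carbon_mmol(r, cmp, registry) * cfg$v_aq
      add("broth", paste0("product:", cmp), f)
      out_total <- out_total + f
    }
  }
  # residual (unconsumed) substrate carbon leaving with the effluent
  for (cmp in names(cfg$feed)) {
    cbar <- .tw_mean(sub$time_d, .aq(sub, cmp))
    resid <- cfg$dilution_rate * conc_to_carbon_mmol(cbar, cmp, registry) *
      cfg$v_aq
    if (rates[[cmp]] > 0) {
      # net-produced "substrate": its effluent carbon is already counted
      # in the product flux plus feed passthrough
      resid <- cfg$dilution_rate *
        conc_to_carbon_mmol(cfg$feed[[cmp]], cmp, registry) * cfg$v_aq
    }
    add("broth", paste0("effluent:", cmp), resid)
    out_total <- out_total + resid
  }
  gas_c <- (gas_rate(ts, cfg, period, "co2") +
              gas_rate(ts, cfg, period, "ch4")) * cfg$v_aq
  if (gas_c > 0) {
    add("broth", "gas:CO2+CH4", gas_c)
    out_total <- out_total + gas_c
  }
  add("broth", "biomass (missing carbon)", inflow_total - out_total)
  do.call(rbind, rows)
}

#' Render a report bundle to files
#'
#' Writes the bundle's tables as CSVs plus a plain-text summary:
#' `performance_summary.csv`, `rates.csv`, `extraction_metrics.csv`,
#' `oil_composition.csv`, `carbon_flux.csv`, `balance_closure.csv`,
#' `summary.txt`. Re-rendering into the same directory is idempotent.
#' All columns carry their units in the header.
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param outdir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
render_reports <- function(bundle, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(bundle$performance$summary, "performance_summary.csv")
  wr(bundle$performance$rates, "rates.csv")
  if (!is.null(bundle$extraction)) wr(bundle$extraction, "extraction_metrics.csv")
  if (!is.null(bundle$oil_composition)) {
    oc <- bundle$oil_composition
    wr(data.frame(compound = c(names(oc$pct_of_ca), "MCC_total", "MCC_total"),
                  measure = c(rep("pct_of_carboxylic_acids", length(oc$pct_of_ca)),
                              "wt_pct_of_oil", "nc8_to_nc6_molC_pct"),
                  value = c(as.numeric(oc$pct_of_ca), oc$wt_pct_mcc,
                            oc$nc8_to_nc6_molc_pct)),
       "oil_composition.csv")
  }
  wr(bundle$flux_table, "carbon_flux.csv")
  wr(bundle$closure, "balance_closure.csv")

  p <- file.path(outdir, "summary.txt")
  con <- file(p, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("caproext %s | seed %s | periods: %s",
            bundle$provenance$package_version, bundle$provenance$seed,
            paste(bundle$provenance$periods, collapse = ", ")),
    "", "Per-period performance:",
    utils::capture.output(print(
      bundle$performance$summary[, c("period", "nc6_rate_g_per_L_d",
                                     "nc6_electron_selectivity_pct",
                                     "mcc_electron_selectivity_pct",
                                     "electron_gap_pct", "carbon_gap_pct")],
      row.names = FALSE, digits = 4))), con)
  paths <- c(paths, p)
  invisible(paths)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> periods: ",
      paste(x$provenance$periods, collapse = ", "), "\n", sep = "")
  print(x$performance)
  invisible(x)
}
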