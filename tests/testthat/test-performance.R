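test_that("production rate combines dilution and organic accumulation", {
  cfg <- reactor_config(v_org = 0, feed = c(lactate = 40))
  # steady aqueous n-caproate, no feed, no oil: r = D * C
  ts <- reactor_timeseries(data.frame(
    time_d = 0:4, pH = 5, n_caproate_aq_g_per_L = 6.86,
    lactate_aq_g_per_L = 20), reg)
  expect_equal(production_rate(ts, cfg, c(0, 4), "n_caproate", reg),
               0.5 * 6.86)
  # feed == effluent -> zero net rate
  ts2 <- reactor_timeseries(data.frame(
    time_d = 0:4, pH = 5, lactate_aq_g_per_L = 40), reg)
  expect_equal(production_rate(ts2, cfg, c(0, 4), "lactate", reg), 0)
  # pure extraction: aqueous constant at feed, organic gains 2.28 g over 1 d
  cfg3 <- reactor_config(v_org = 0.48, feed = c(n_caproate = 5))
  ts3 <- reactor_timeseries(data.frame(
    time_d = c(0, 1), pH = 5, n_caproate_aq_g_per_L = 5,
    n_caproate_org_g_per_L = c(0, 2.28 / 0.48)), reg)
  expect_equal(production_rate(ts3, cfg3, c(0, 1), "n_caproate", reg), 1.9)
  # negative organic increments (re-solubilisation) keep their sign
  ts4 <- reactor_timeseries(data.frame(
    time_d = c(0, 1), pH = 5, n_caproate_aq_g_per_L = 5,
    n_caproate_org_g_per_L = c(2.28 / 0.48, 0)), reg)
  expect_equal(production_rate(ts4, cfg3, c(0, 1), "n_caproate", reg), -1.9)
  expect_error(production_rate(ts, cfg, c(0, 0.1), "n_caproate", reg),
               "fewer than 2")
  expect_error(production_rate(ts, cfg, c(0, 4), "n_valerate", reg),
               "missing from series")
})

test_that("steady-state production rate is window-length invariant", {
  ts <- steady_ts()
  cfg <- steady_cfg()
  r_full <- production_rate(ts, cfg, c(0, 16), "n_caproate", reg)
  r_half <- production_rate(ts, cfg, c(8, 16), "n_caproate", reg)
  expect_equal(r_full, r_half, tolerance = 1e-12)
})

test_that("areal flux scales a volumetric flux by V_aq over the cross-section", {
  cfg <- reactor_config()  # 1.2 L, d = 0.105 m
  expect_equal(cfg$interface_area_m2, 8.659e-3, tolerance = 1e-4)
  expect_equal(areal_flux(1.881, cfg), 260.7, tolerance = 0.01 * 260.7)
  expect_equal(areal_flux(0, cfg), 0)
  expect_equal(areal_flux(2 * 1.881, cfg), 2 * areal_flux(1.881, cfg))
})

test_that("electron selectivity shares net products only", {
  rates <- c(n_caproate = 740, n_butyrate = 100, h2 = 100, propionate = 20,
             n_heptylate = 20, n_caprylate = 20, lactate = -2000)
  s <- electron_selectivity(rates, reg)
  expect_equal(s$per_product[["n_caproate"]], 74)
  expect_equal(s$mcc, 78)
  expect_equal(sum(s$per_product), 100)
  # substrates never enter the denominator
  expect_false("lactate" %in% names(s$per_product))
  expect_equal(unname(electron_selectivity(c(n_caproate = 3))$per_product), 100)
  # scale invariance
  expect_equal(electron_selectivity(5 * rates, reg)$per_product,
               s$per_product)
  expect_error(electron_selectivity(c(lactate = -1)), "no net-produced")
})

test_that("carbon selectivity and efficiency are consistent", {
  cs <- carbon_selectivity_and_efficiency(
    c(n_caproate = 138.75, n_butyrate = 31.6, co2 = 60), 250)
  expect_equal(cs$selectivity_pct[["n_caproate"]], 60.2, tolerance = 0.05)
  expect_equal(cs$efficiency_pct[["n_caproate"]], 100 * 138.75 / 250)
  # efficiency <= selectivity whenever product carbon <= substrate carbon
  expect_true(all(cs$efficiency_pct <= cs$selectivity_pct))
  one <- carbon_selectivity_and_efficiency(c(n_caproate = 10), 10)
  expect_equal(unname(one$selectivity_pct), 100)
  expect_error(carbon_selectivity_and_efficiency(c(a = 1), 0), "> 0")
})

test_that("acid dose per MCC uses per-compound electron equivalents", {
  expect_equal(acid_dose_metrics(76, c(n_caproate = 969), reg), 2.51,
               tolerance = 0.005)
  expect_equal(acid_dose_metrics(0, c(n_caproate = 969), reg), 0)
  # homogeneous of degree zero
  expect_equal(acid_dose_metrics(2 * 76, 2 * c(n_caproate = 969), reg),
               acid_dose_metrics(76, c(n_caproate = 969), reg))
  # a caprylate electron is worth fewer mols than a caproate electron
  expect_gt(acid_dose_metrics(76, c(n_caprylate = 969), reg),
            acid_dose_metrics(76, c(n_caproate = 969), reg))
  expect_error(acid_dose_metrics(10, c(n_caproate = 0), reg), "> 0")
})

test_that("stoichiometric summary returns molar consumption ratios", {
  # build a steady series: lactate 64 mmol/L/d and acetate 10 mmol/L/d
  # consumed, nC6 produced at 19.2 mmol/L/d (D = 0.5)
  cfg <- reactor_config(v_org = 0, feed = c(lactate = 40, acetate = 5))
  lac_resid <- 40 - mm_to_g_per_l(64 / 0.5, "lactate", reg)
  ace_resid <- 5 - mm_to_g_per_l(10 / 0.5, "acetate", reg)
  nc6 <- mm_to_g_per_l(19.2 / 0.5, "n_caproate", reg)
  ts <- reactor_timeseries(data.frame(
    time_d = 0:4, pH = 5,
    lactate_aq_g_per_L = lac_resid, acetate_aq_g_per_L = ace_resid,
    n_caproate_aq_g_per_L = nc6), reg)
  st <- stoichiometric_summary(ts, cfg, c(0, 4), reg)
  expect_equal(st$lactate_to_acetate, 6.4, tolerance = 1e-9)
  expect_equal(st$nc6_yield_mol_mol, 0.30, tolerance = 1e-9)
  # zero acetate consumption is signalled
  ts2 <- reactor_timeseries(data.frame(
    time_d = 0:4, pH = 5, lactate_aq_g_per_L = lac_resid,
    acetate_aq_g_per_L = 5, n_caproate_aq_g_per_L = nc6), reg)
  expect_warning(st2 <- stoichiometric_summary(ts2, cfg, c(0, 4), reg),
                 "undefined")
  expect_true(is.na(st2$lactate_to_acetate))
})

test_that("balance closure finds an imposed electron sink", {
  cfg <- steady_cfg()
  # conservative series: zero gap
  bc0 <- balance_closure(steady_ts(0), cfg, c(0, 16), reg)
  expect_equal(bc0$electron_gap_pct, 0, tolerance = 1e-6)
  # 5% of feed electrons to an untracked sink
  bc5 <- balance_closure(steady_ts(0.05), cfg, c(0, 16), reg)
  expect_equal(bc5$electron_gap_pct, 5, tolerance = 1e-6)
  expect_error(balance_closure(steady_ts(), reactor_config(feed = c(lactate = 0)),
                               c(0, 16), reg), "zero inflow")
})

test_that("performance summary assembles per-period accounting", {
  sim <- sim_nonextractive()
  ps <- performance_summary(sim$ts, sim$cfg, list(adapt = c(5, 20),
                                                  steady = c(40, 60)))
  expect_s3_class(ps, "performance_summary")
  expect_equal(nrow(ps$summary), 2)
  steady <- ps$summary[ps$summary$period == "steady", ]
  expect_gt(steady$nc6_rate_g_per_L_d, 1)
  expect_gt(steady$mcc_electron_selectivity_pct, 50)
  expect_lt(steady$mcc_electron_selectivity_pct, 100)
  # electron gap reflects the biomass electron yield (7%)
  expect_equal(steady$electron_gap_pct, 7, tolerance = 2)
  expect_true(all(c("rate_g_per_L_d", "rate_emeq_per_L_d") %in%
                    names(ps$rates)))
  expect_error(performance_summary(sim$ts, sim$cfg, list(c(0, 10))), "named")
})
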