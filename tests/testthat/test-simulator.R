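test_that("simulated campaigns conserve electrons and carbon", {
  for (sim in list(sim_nonextractive(), sim_extractive())) {
    expect_lt(electron_closure(sim), 1e-6)
    expect_lt(carbon_closure(sim), 1e-6)
  }
  # batch bottle, biotic
  sb <- simulate_batch(sim_params(init = c(lactate = 3, acetate = 0.5),
                                  x0 = 20,
                                  k_d = c(n_caproate = 2.5),
                                  ka = c(n_caproate = 0.05)),
                       t_end = 20)
  expect_lt(electron_closure(sb), 1e-6)
  expect_lt(carbon_closure(sb), 1e-6)
})

test_that("simulation is deterministic", {
  a <- simulate_cstr(sim_params(), reactor_config(), t_end = 10, dt_out = 0.5)
  b <- simulate_cstr(sim_params(), reactor_config(), t_end = 10, dt_out = 0.5)
  expect_identical(a$ts, b$ts)
  expect_identical(a$ledger, b$ledger)
})

test_that("abiotic mode extracts only compounds with a distribution ratio", {
  # synthetic-effluent saturation run: no biomass, no reactions
  feed <- c(lactate = 11, acetate = 2.6, n_butyrate = 1.3, n_caproate = 6.1)
  cfg <- reactor_config(feed = feed)
  sim <- simulate_cstr(sim_params(x0 = 0, y_x = 0, init = feed), cfg,
                       t_end = 20, dt_out = 0.5)
  ts <- sim$ts
  last <- ts[nrow(ts), ]
  # n-caproate accumulates in the oil; n-butyrate (K_D = 0) does not
  expect_gt(last$n_caproate_org_g_per_L, 1)
  expect_equal(last$n_butyrate_org_g_per_L, 0)
  # aqueous substrates pass through unchanged (no reactions)
  expect_equal(last$lactate_aq_g_per_L, 11, tolerance = 1e-6)
  expect_equal(last$acetate_aq_g_per_L, 2.6, tolerance = 1e-6)
  expect_lt(electron_closure(sim), 1e-6)
})

test_that("zero distribution ratios reduce to the single-phase model", {
  p_off <- sim_params(k_d = c(n_caproate = 0, n_caprylate = 0))
  two_phase <- simulate_cstr(p_off, reactor_config(), t_end = 15, dt_out = 0.5)
  one_phase <- simulate_cstr(p_off, reactor_config(v_org = 0), t_end = 15,
                             dt_out = 0.5)
  expect_equal(two_phase$ts$n_caproate_org_g_per_L,
               rep(0, nrow(two_phase$ts)))
  expect_equal(two_phase$ts$n_caproate_aq_g_per_L,
               one_phase$ts$n_caproate_aq_g_per_L, tolerance = 1e-8)
})

test_that("undissociated n-caproic acid attenuates and then stops production", {
  # closed bottles at pH 5 seeded with increasing n-caproate backgrounds
  lac_consumed <- vapply(c(0, 4, 7, 9, 11), function(nc6_0) {
    sim <- simulate_batch(sim_params(init = c(lactate = 10, acetate = 2,
                                              n_caproate = nc6_0),
                                     x0 = 50, k_d = c(n_caproate = 0)),
                          t_end = 2, dt_out = 0.5)
    ts <- sim$ts
    ts$lactate_aq_g_per_L[1] - ts$lactate_aq_g_per_L[nrow(ts)]
  }, numeric(1))
  # production is non-increasing in the imposed acid background
  expect_true(all(diff(lac_consumed) <= 1e-9))
  # 11 g/L total at pH 5 is ~41 mM undissociated: above the stop
  # threshold, conversion ceases
  expect_gt(g_per_l_to_mm(undissociated_conc(11, 5, "n_caproate", reg),
                          "n_caproate", reg), 37)
  expect_lt(lac_consumed[5], 1e-8)
  expect_gt(lac_consumed[1], 0.5)
})

test_that("in-situ extraction relieves inhibition and raises cumulative nC6", {
  p_on <- sim_params()
  p_off <- sim_params(k_d = c(n_caproate = 0, n_caprylate = 0))
  cfg <- reactor_config()
  cum_nc6 <- function(p) {
    sim <- simulate_cstr(p, cfg, t_end = 60, dt_out = 0.5)
    l <- sim$ledger
    tail(l$cr2 - l$cr3, 1)  # net mol nC6 produced per litre
  }
  expect_gte(cum_nc6(p_on), cum_nc6(p_off))
})

test_that("batch mode with no reactions conserves per-compound mass", {
  sim <- simulate_batch(sim_params(x0 = 0, y_x = 0,
                                   init = c(n_caproate = 6.5, lactate = 11),
                                   k_d = c(n_caproate = 2.5),
                                   ka = c(n_caproate = 0.05)),
                        t_end = 30)
  ts <- sim$ts
  total <- ts$n_caproate_aq_g_per_L * 0.04 + ts$n_caproate_org_g_per_L * 0.008
  expect_equal(total, rep(total[1], length(total)), tolerance = 1e-7)
  expect_equal(ts$lactate_aq_g_per_L, rep(11, nrow(ts)), tolerance = 1e-8)
})

test_that("batch equilibrium recovery approaches the closed-form limit", {
  # kA t >> 1: recovery -> 100 K r / (1 + K r)
  sim <- simulate_batch(sim_params(x0 = 0, y_x = 0,
                                   init = c(n_caproate = 6.5),
                                   k_d = c(n_caproate = 2.5),
                                   ka = c(n_caproate = 0.1)),
                        t_end = 60)
  ts <- sim$ts
  last <- ts[nrow(ts), ]
  rec <- recovery(last$n_caproate_org_g_per_L * 0.008,
                  last$n_caproate_aq_g_per_L * 0.04)
  expect_equal(rec, 100 * 2.5 * 0.2 / (1 + 2.5 * 0.2), tolerance = 1e-6)
})

test_that("measurement noise is seeded, unbiased in CV and clipped at zero", {
  ts <- sim_extractive()$ts
  expect_identical(add_measurement_noise(ts, 0, seed = 3), ts)
  n1 <- add_measurement_noise(ts, 0.05, seed = 7)
  n2 <- add_measurement_noise(ts, 0.05, seed = 7)
  expect_identical(n1, n2)
  expect_false(identical(n1, add_measurement_noise(ts, 0.05, seed = 8)))
  expect_true(all(n1$n_caproate_aq_g_per_L >= 0))
  # empirical CV of 1e4 replicated noise draws ~ 5%
  const <- reactor_timeseries(data.frame(
    time_d = seq_len(10000), pH = 5,
    n_caproate_aq_g_per_L = 1), reg)
  noisy <- add_measurement_noise(const, 0.05, seed = 42)
  cv <- sd(noisy$n_caproate_aq_g_per_L) / mean(noisy$n_caproate_aq_g_per_L)
  expect_equal(cv, 0.05, tolerance = 0.1)
  # named sd map touches only the mapped column
  sel <- add_measurement_noise(ts, c(n_caproate_aq_g_per_L = 0.05), seed = 1)
  expect_identical(sel$lactate_aq_g_per_L, ts$lactate_aq_g_per_L)
})

test_that("distribution-ratio recovery from simulated series", {
  p <- sim_params(x0 = 0, y_x = 0, init = c(n_caproate = 6.5),
                  k_d = c(n_caproate = 2.5), ka = c(n_caproate = 0.05))
  sim <- simulate_batch(p, t_end = 30)
  fit <- fit_kd(sim$ts, "n_caproate")
  expect_equal(fit$estimate, 2.5, tolerance = 0.02)
  # zero-K_D series recovers zero
  p0 <- sim_params(x0 = 0, y_x = 0, init = c(n_caproate = 6.5),
                   k_d = c(n_caproate = 0))
  expect_equal(fit_kd(simulate_batch(p0, t_end = 10)$ts, "n_caproate")$estimate,
               0)
  # 5% measurement noise, 30 timepoints: within 10%
  sim30 <- simulate_batch(p, t_end = 30, dt_out = 1)
  noisy <- add_measurement_noise(sim30$ts, 0.05, seed = 5)
  fitn <- fit_kd(noisy, "n_caproate")
  expect_equal(fitn$estimate, 2.5, tolerance = 0.10)
  expect_error(fit_kd(sim$ts, "lactate"), "lacks both phases")
})

test_that("analysis pipeline recovers the simulator's imposed stoichiometry", {
  sim <- sim_nonextractive()
  period <- c(40, 60)
  truth <- sim_true_rates(sim, period)  # e- meq/L/d from exact extents
  sel_truth <- electron_selectivity(truth[truth > 0], reg)
  rates_g <- production_rates(sim$ts, sim$cfg, period, reg)
  rates_e <- vapply(names(rates_g), function(cmp) {
    g_per_l_to_emeq(abs(rates_g[[cmp]]), cmp, reg) * sign(rates_g[[cmp]])
  }, numeric(1))
  h2 <- gas_rate(sim$ts, sim$cfg, period, "h2") * 2
  sel_est <- electron_selectivity(c(rates_e, h2 = h2), reg)
  expect_setequal(names(sel_truth$per_product), names(sel_est$per_product))
  for (nm in names(sel_truth$per_product)) {
    expect_lt(abs(sel_est$per_product[[nm]] - sel_truth$per_product[[nm]]),
              0.5)
  }
  expect_lt(abs(sel_est$mcc - sel_truth$mcc), 0.5)
})

test_that("parameter validation rejects impossible settings", {
  expect_error(sim_params(y_x = 1), "y_x")
  expect_error(sim_params(inhib_start_mm = 40, inhib_stop_mm = 37), "<")
  expect_error(sim_params(q_max = c(elong_c4 = 1)), "must name")
  expect_error(simulate_cstr(sim_params(), reactor_config(), t_end = -1),
               "t_end")
  expect_error(simulate_cstr(sim_params(init = c(ethanol = 1)),
                             reactor_config()), "not modelled")
})
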