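# Shared fixtures. Simulations are cheap (<1 s) but reused across tests.
reg <- default_registry()

# memoised simulation runs
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(key, fun) {
  if (!exists(key, envir = .sim_cache)) assign(key, fun(), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

sim_nonextractive <- function() cached_sim("nonext", function() {
  simulate_cstr(sim_params(k_d = c(n_caproate = 0)),
                reactor_config(v_org = 0), t_end = 60, dt_out = 0.5)
})

sim_extractive <- function() cached_sim("ext", function() {
  simulate_cstr(sim_params(), reactor_config(), t_end = 60, dt_out = 0.5)
})

# hand-built steady-state series: lactate partially converted to
# n-caproate with exact electron conservation, plus an optional fraction
# of feed electrons routed to an untracked sink
steady_ts <- function(sink_frac = 0, n = 9) {
  feed_lac <- 40                                    # g/L
  consumed <- 2                                     # g lactate/L converted
  e_feed <- g_per_l_to_emeq(feed_lac, "lactate", reg)
  e_consumed <- g_per_l_to_emeq(consumed, "lactate", reg)
  # n-caproate carries the consumed electrons; sink_frac of the feed
  # electrons vanish from the residual (an untracked sink)
  resid_e <- (e_feed - e_consumed) - sink_frac * e_feed
  nc6 <- emeq_to_g_per_l(e_consumed, "n_caproate", reg)
  df <- data.frame(
    time_d = seq(0, by = 2, length.out = n),
    pH = 5,
    lactate_aq_g_per_L = emeq_to_g_per_l(resid_e, "lactate", reg),
    n_caproate_aq_g_per_L = nc6)
  reactor_timeseries(df, reg)
}

steady_cfg <- function() {
  reactor_config(v_org = 0, feed = c(lactate = 40))
}
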