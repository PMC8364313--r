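# Shared simulations, built once per test run and cached.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .sim_cache))
    assign(name, force(expr), envir = .sim_cache)
  get(name, envir = .sim_cache)
}

# Free ideal chain (no LEFs), all monomers recorded. Many replicate chains
# with short windows: large-scale structure is ensemble-sampled from the
# exact ideal-chain initial draw (one window cannot time-average the slow
# Rouse modes), while short scales are engine-relaxed.
free_chain_sim <- function() cached("free_chain", {
  cfg <- sim_config(loading_rate = 0, n_samples = 100, burn_in_steps = 0,
                    sample_interval = 50, seed = 11)
  run_ensemble(cfg, n_replicates = 50)
})

# Default loop domain at the calibrated scale: 10 replicate chains x 5000
# samples = 5e4 pooled conformations, with the anchors and the 10 kb outward
# tether monomers recorded.
default_loop_sim <- function() cached("loop50k", {
  cfg <- sim_config(n_samples = 5000, seed = 1)
  run_ensemble(cfg, n_replicates = 10, monomers = c(41, 43, 45, 255, 257, 259))
})

# Matched smaller ensembles across seeds for the tether-sweep bimodality check.
bimod_sweep_sims <- function() cached("bimod_sweep", {
  lapply(1:5, function(sd) {
    cfg <- sim_config(n_samples = 2000, seed = sd)
    run_ensemble(cfg, n_replicates = 10, monomers = c(41, 45, 255, 259))
  })
})

# Tag pair at the anchors with symmetric outward tether (bp), point labels.
anchor_tags <- function(mapping, tether_bp = 0) {
  list(tag_spec(mapping$anchor_A * mapping$bp_per_monomer,
                tether_offset_bp = -tether_bp, channel = "ch1"),
       tag_spec(mapping$anchor_B * mapping$bp_per_monomer,
                tether_offset_bp = tether_bp, channel = "ch2"))
}

# random-walk track as a data.frame for pairing tests
random_track <- function(times, origin, step_sd = 20) {
  n <- length(times)
  p <- matrix(origin, n, 3, byrow = TRUE) +
    apply(matrix(rnorm(n * 3, sd = step_sd), n, 3), 2, cumsum)
  data.frame(time_s = times, x = p[, 1], y = p[, 2], z = p[, 3])
}
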