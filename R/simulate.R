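#' Simulation configuration for the loop-domain generator
#'
#' Bundles the chain mapping, loop-extrusion rates, CTCF layout, integrator
#' settings and seed. The packaged defaults reproduce the reference scenario:
#' a 525 kb CTCF loop domain whose anchors sit within the 50 nm contact radius
#' about 5% of the time. The default loading rate was calibrated once with
#' [calibrate_loop_occupancy()] against that 5% figure and then frozen.
#'
#' @param mapping a [chain_mapping()].
#' @param loading_rate LEF loading rate per unoccupied monomer per second.
#' @param velocity extrusion speed per arm, monomers/s.
#' @param unbinding_rate LEF unbinding rate, 1/s.
#' @param ctcf_prob CTCF capture probability at both anchors.
#' @param lef_stiffness LEF bridge spring constant as a multiple of the
#'   backbone bond constant. The default 3 holds a bridged anchor pair at
#'   ~23 nm RMS — inside the 50 nm contact radius ~97% of the time — so the
#'   "looped configuration" coincides with the contact definition; a value of
#'   1 would leave the bridge as loose as one backbone bond (~40 nm RMS).
#' @param timestep_s integrator step; per-step RMS free-monomer displacement
#'   `sqrt(6 * mobility * dt)` must stay below `bond_length / 2`.
#' @param burn_in_steps steps discarded before sampling. The initial chain is
#'   an exact ideal-chain equilibrium draw, so burn-in only has to relax the
#'   extrusion state; the default covers ~20 LEF lifetimes.
#' @param sample_interval steps between retained samples.
#' @param n_samples number of retained conformations.
#' @param seed integer seed; the full trajectory is bit-reproducible from it.
#' @param excluded_volume enable soft-core repulsion (off for the default
#'   ideal-chain statistics).
#' @param mobility_nm2_s temperature-scaled monomer mobility (= diffusion
#'   coefficient at kT = 1), nm^2/s.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(mapping = chain_mapping(),
                       loading_rate = 2.05e-5,
                       velocity = 20,
                       unbinding_rate = 0.06,
                       ctcf_prob = 1,
                       lef_stiffness = 3,
                       timestep_s = 0.01,
                       burn_in_steps = 50000,
                       sample_interval = 50,
                       n_samples = 2000,
                       seed = 1,
                       excluded_volume = FALSE,
                       mobility_nm2_s = 1000) {
  if (!inherits(mapping, "chain_mapping")) stopf("mapping must be a chain_mapping")
  if (!is_count(n_samples) || n_samples < 1) stopf("n_samples must be >= 1")
  if (!is_count(burn_in_steps)) stopf("burn_in_steps must be a non-negative integer")
  if (!is_count(sample_interval) || sample_interval < 1)
    stopf("sample_interval must be >= 1")
  rms_step <- sqrt(6 * mobility_nm2_s * timestep_s)
  if (rms_step >= mapping$bond_length_nm / 2)
    stopf("timestep too large: per-step RMS displacement %.1f nm >= bond_length/2",
          rms_step)
  if (velocity * timestep_s > 1)
    stopf("rate overflow: velocity * timestep = %g > 1", velocity * timestep_s)
  if (!is_count(abs(seed)) || abs(seed) >= 2^31) stopf("seed must be a 32-bit integer")
  if (lef_stiffness <= 0) stopf("lef_stiffness must be > 0")
  structure(list(mapping = mapping,
                 loading_rate = loading_rate, velocity = velocity,
                 unbinding_rate = unbinding_rate, ctcf_prob = ctcf_prob,
                 lef_stiffness = lef_stiffness,
                 timestep_s = timestep_s,
                 burn_in_steps = as.integer(burn_in_steps),
                 sample_interval = as.integer(sample_interval),
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed),
                 excluded_volume = isTRUE(excluded_volume),
                 mobility_nm2_s = mobility_nm2_s),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  chain: %d monomers x %d bp, b = %g nm, anchors %d/%d\n",
              x$mapping$n_monomers, x$mapping$bp_per_monomer,
              x$mapping$bond_length_nm, x$mapping$anchor_A, x$mapping$anchor_B))
  cat(sprintf("  LEF: load %.3g /site/s, v %g mon/s, unbind %g /s (processivity %g mon)\n",
              x$loading_rate, x$velocity, x$unbinding_rate,
              2 * x$velocity / x$unbinding_rate))
  cat(sprintf("  integrator: dt %g s, mobility %g nm^2/s, EV %s\n",
              x$timestep_s, x$mobility_nm2_s, x$excluded_volume))
  cat(sprintf("  sampling: burn-in %d, every %d steps x %d samples, seed %d\n",
              x$burn_in_steps, x$sample_interval, x$n_samples, x$seed))
  invisible(x)
}

#' Run the loop-extrusion polymer simulation
#'
#' Initializes the chain from the ideal-chain ensemble, runs the fused
#' extrusion + Langevin engine, discards the burn-in and returns `n_samples`
#' snapshots at `sample_interval` spacing. The whole trajectory is
#' bit-reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @param monomers 0-based indices of monomers whose positions are recorded at
#'   every sample (`NULL` = all). Recording only the loci you need keeps
#'   50,000-sample runs small.
#' @return an object of class `loop_sim` with elements `times` (s), `positions`
#'   (array `n_samples x length(monomers) x 3`, nm), `bridged` (logical: some
#'   LEF stalled at both CTCF anchors), `n_lefs`, `monomers`, `config`, and
#'   `final` (closing `conformation` plus LEF arm matrix).
#' @export
run_simulation <- function(config, monomers = NULL) {
  if (!inherits(config, "sim_config")) stopf("config must be a sim_config")
  m <- config$mapping
  if (is.null(monomers)) monomers <- 0:(m$n_monomers - 1)
  monomers <- as.integer(monomers)
  if (any(monomers < 0) || any(monomers >= m$n_monomers))
    stopf("recorded monomers outside [0, n_monomers)")

  conf0 <- init_chain(m, seed = config$seed)
  ctcf <- default_ctcf(m, prob = config$ctcf_prob)
  res <- cpp_run_sim(conf0$positions,
                     m$anchor_A, m$anchor_B,
                     ctcf$site, ctcf$dir, ctcf$prob,
                     matrix(integer(), ncol = 2),
                     config$loading_rate, config$velocity,
                     config$unbinding_rate,
                     m$bond_length_nm, config$lef_stiffness,
                     config$mobility_nm2_s,
                     config$timestep_s,
                     config$burn_in_steps, config$sample_interval,
                     config$n_samples,
                     monomers,
                     as.double(config$seed),
                     config$excluded_volume, 0.8 * m$bond_length_nm, 10)

  structure(list(config = config, monomers = monomers,
                 times = res$times,
                 positions = res$positions,
                 bridged = as.logical(res$bridged),
                 n_lefs = res$n_lefs,
                 final = list(conformation = conformation(res$final_positions,
                                                          max(res$times)),
                              lefs = res$final_lefs)),
            class = "loop_sim")
}

#' Pool replicate loop-domain trajectories into one sample ensemble
#'
#' Runs `n_replicates` independent simulations (seeds derived from
#' `config$seed`) and pools their samples. One trajectory cannot average the
#' slowest Rouse modes of the chain within a desk-scale run (the slowest
#' relaxation time of the default 300-mer is ~5000 s), so single-window
#' distance histograms have unstable bulk shapes; pooling replicate chains,
#' each initialized from the exact ideal-chain ensemble, emulates what imaging
#' experiments do when they pool loci across cells. Loop-extrusion episodes
#' are fast and average within each window.
#'
#' @param config a [sim_config()]; `config$n_samples` is the number of samples
#'   *per replicate*.
#' @param n_replicates number of independent chains.
#' @param monomers 0-based monomer indices to record (`NULL` = all).
#' @return a `loop_sim` whose samples are the pooled replicates, with an extra
#'   `replicate` index vector.
#' @export
run_ensemble <- function(config, n_replicates = 10, monomers = NULL) {
  stopifnot(n_replicates >= 1)
  runs <- lapply(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- as.integer((config$seed + (r - 1) * 100003) %% .Machine$integer.max)
    run_simulation(cfg, monomers = monomers)
  })
  pooled <- runs[[1]]
  np <- vapply(runs, function(x) length(x$times), integer(1))
  pooled$times <- unlist(lapply(runs, `[[`, "times"))
  pooled$positions <- do.call(abind3, lapply(runs, `[[`, "positions"))
  pooled$bridged <- unlist(lapply(runs, `[[`, "bridged"))
  pooled$n_lefs <- unlist(lapply(runs, `[[`, "n_lefs"))
  pooled$replicate <- rep(seq_len(n_replicates), np)
  pooled$final <- runs[[length(runs)]]$final
  pooled
}

# bind arrays [n_i x k x 3] along the first dimension
abind3 <- function(...) {
  parts <- list(...)
  k <- dim(parts[[1]])[2]
  out <- array(NA_real_, c(sum(vapply(parts, function(p) dim(p)[1], integer(1))),
                           k, 3))
  at <- 0
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' @export
print.loop_sim <- function(x, ...) {
  cat(sprintf("<loop_sim> %d samples x %d recorded monomers; bridged %.1f%% of samples\n",
              length(x$times), length(x$monomers), 100 * mean(x$bridged)))
  invisible(x)
}

#' Positions of one recorded monomer across samples
#' @param sim a `loop_sim`.
#' @param monomer 0-based monomer index (must have been recorded).
#' @return `n_samples x 3` matrix, nm.
#' @export
monomer_positions <- function(sim, monomer) {
  k <- match(as.integer(monomer), sim$monomers)
  if (is.na(k))
    stopf("monomer %d was not recorded in this simulation", monomer)
  sim$positions[, k, , drop = TRUE]
}

#' Extract one sample as a conformation (requires all monomers recorded)
#' @param sim a `loop_sim`.
#' @param i sample index (1-based).
#' @export
get_frame <- function(sim, i) {
  if (length(sim$monomers) != sim$config$mapping$n_monomers)
    stopf("get_frame needs a simulation with all monomers recorded")
  conformation(sim$positions[i, , ], time_s = sim$times[i])
}

#' True anchor-anchor 3D distances of a simulation
#' @param sim a `loop_sim` whose recording includes both anchors.
#' @return a [distance_series()] with provenance `"true"`.
#' @export
anchor_distances <- function(sim) {
  m <- sim$config$mapping
  a <- monomer_positions(sim, m$anchor_A)
  b <- monomer_positions(sim, m$anchor_B)
  distance_series(sim$times, sqrt(rowSums((a - b)^2)), provenance = "true")
}

#' Calibrate LEF loading to a target anchor-contact fraction
#'
#' Bisection on the (log) loading rate until the fraction of samples with
#' anchor-anchor 3D distance below `r_c_nm` matches `target_fraction`. The
#' contact fraction is monotone non-decreasing in the loading rate (more LEFs,
#' more bridged time), which makes bisection valid; the scan trace is returned
#' so that monotonicity can be inspected.
#'
#' @param config starting [sim_config()].
#' @param target_fraction desired contact fraction, in `(0, 0.5)` (target 0 is
#'   accepted only with loading rate already 0).
#' @param tol_fraction absolute tolerance on the achieved fraction.
#' @param n_samples total samples per evaluation, split across
#'   `n_replicates` pooled chains (calibration accuracy is limited by the
#'   Monte Carlo error of the loop-episode count).
#' @param n_replicates replicate chains pooled per evaluation.
#' @param r_c_nm contact radius, nm.
#' @param rate_bounds loading-rate search bracket, per site per second.
#' @param max_iter bisection iterations.
#' @return list with `config` (loading rate replaced by the calibrated value),
#'   `achieved` fraction, and the scan `trace` (data.frame rate/fraction).
#' @export
calibrate_loop_occupancy <- function(config, target_fraction = 0.05,
                                     tol_fraction = 0.01,
                                     n_samples = 10000, n_replicates = 10,
                                     r_c_nm = 50,
                                     rate_bounds = c(1e-7, 2e-3),
                                     max_iter = 12) {
  if (target_fraction == 0 && config$loading_rate == 0) {
    return(list(config = config, achieved = 0,
                trace = data.frame(rate = 0, fraction = 0)))
  }
  if (target_fraction <= 0 || target_fraction >= 0.5)
    stopf("target_fraction must lie in (0, 0.5)")

  eval_rate <- function(rate) {
    cfg <- config
    cfg$loading_rate <- rate
    cfg$n_samples <- as.integer(ceiling(n_samples / n_replicates))
    sim <- run_ensemble(cfg, n_replicates = n_replicates,
                        monomers = c(config$mapping$anchor_A,
                                     config$mapping$anchor_B))
    contact_fraction(anchor_distances(sim), r_c_nm)
  }

  lo <- rate_bounds[1]; hi <- rate_bounds[2]
  f_lo <- eval_rate(lo); f_hi <- eval_rate(hi)
  trace <- data.frame(rate = c(lo, hi), fraction = c(f_lo, f_hi))
  if (f_lo > target_fraction || f_hi < target_fraction)
    stopf(paste0("calibration failure: target %.3f not bracketed; ",
                 "fraction is %.4f at rate %.3g and %.4f at rate %.3g"),
          target_fraction, f_lo, lo, f_hi, hi)

  rate <- NA_real_; achieved <- NA_real_
  for (it in seq_len(max_iter)) {
    rate <- sqrt(lo * hi)  # bisect in log space
    achieved <- eval_rate(rate)
    trace <- rbind(trace, data.frame(rate = rate, fraction = achieved))
    if (abs(achieved - target_fraction) <= tol_fraction) break
    if (achieved < target_fraction) lo <- rate else hi <- rate
  }
  out <- config
  out$loading_rate <- rate
  list(config = out, achieved = achieved, trace = trace[order(trace$rate), ])
}
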