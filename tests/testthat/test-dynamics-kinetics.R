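test_that("two-color pairing minimizes summed frame-by-frame distance", {
  times <- 0:19
  set.seed(19)
  a1 <- random_track(times, c(0, 0, 0))
  # 1 vs 1: trivially paired
  res <- pair_two_color(list(a1), list(a1))
  expect_equal(res$pairs$track1, 1)
  expect_equal(res$pairs$track2, 1)

  # crossed 2x2 with distances {10, 900; 850, 12}: identity pairing wins
  mk <- function(offset) data.frame(time_s = times, x = offset, y = 0, z = 0)
  res2 <- pair_two_color(list(mk(0), mk(850)), list(mk(10), mk(862)))
  expect_equal(res2$pairs$track2[order(res2$pairs$track1)], c(1, 2))

  # no shared frames at all is a pairing-impossible error
  b <- data.frame(time_s = times + 100, x = 0, y = 0, z = 0)
  expect_error(pair_two_color(list(a1), list(b)), "pairing impossible")
})

test_that("optimal assignment equals brute force on random 4x4 instances", {
  set.seed(20)
  times <- 0:9
  for (rep in 1:100) {
    t1 <- lapply(1:4, function(i) random_track(times, runif(3, -500, 500)))
    t2 <- lapply(1:4, function(i) random_track(times, runif(3, -500, 500)))
    res <- pair_two_color(t1, t2, min_overlap = 5)
    # independent oracle: recompute the cost matrix and enumerate all 24
    cost <- sapply(t2, function(b) sapply(t1, function(a)
      mean(sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2))))
    perms <- loopscope:::permutations(4)
    best <- min(apply(perms, 1, function(p) sum(cost[cbind(1:4, p)])))
    expect_equal(res$total_cost, best, tolerance = 1e-9)
  }
})

test_that("the Hungarian solver matches exhaustive search beyond 6 tracks", {
  set.seed(21)
  for (rep in 1:10) {
    cost <- matrix(runif(49, 0, 100), 7, 7)
    perm <- loopscope:::assignment_hungarian(cost)
    got <- sum(cost[cbind(1:7, perm)])
    perms <- loopscope:::permutations(7)
    best <- min(apply(perms, 1, function(p) sum(cost[cbind(1:7, p)])))
    expect_equal(got, best, tolerance = 1e-9)
  }
})

test_that("MSD is exact for static and ballistic motion and ~t^0.5 for Rouse", {
  static <- matrix(5, 50, 3)
  expect_true(all(msd(static, 1:10)$msd_nm2 == 0))

  t <- 0:99
  ball <- cbind(3 * t, 0, 0)
  mm <- msd(ball, c(1, 5, 10), dt_s = 1)
  expect_equal(mm$msd_nm2, (3 * mm$lag_s)^2, tolerance = 1e-12)
  expect_warning(msd(ball, c(5, 200)), "dropping")

  # tagged monomer in the ideal chain: intermediate-time MSD slope ~0.5
  cfg <- sim_config(mapping = chain_mapping(n_monomers = 150, anchor_A = 10,
                                            anchor_B = 140),
                    loading_rate = 0, n_samples = 2000, burn_in_steps = 0,
                    sample_interval = 50, seed = 22)
  sim <- run_simulation(cfg, monomers = 75)
  mid <- monomer_positions(sim, 75)
  curve <- msd(mid, 1:40, dt_s = 0.5)
  fit <- lm(log(msd_nm2) ~ log(lag_s), data = curve)
  slope <- unname(coef(fit)[2])
  expect_gt(slope, 0.4)
  expect_lt(slope, 0.6)
})

test_that("velocity autocorrelation distinguishes ballistic, noise and confinement", {
  t <- 0:199
  ball <- cbind(2 * t, -t, 0.5 * t)
  vac_b <- velocity_autocorrelation(ball, 0:5)
  expect_equal(vac_b$vac, rep(1, 6), tolerance = 1e-9)

  set.seed(23)
  noise <- matrix(rnorm(3 * 5000), ncol = 3)  # white-noise positions
  vac_n <- velocity_autocorrelation(noise, 0:3)
  expect_equal(vac_n$vac[vac_n$lag_frames == 1], -0.5, tolerance = 0.04)

  # confined (mean-reverting) motion: negative at short lags
  x <- matrix(0, 2000, 3)
  for (i in 2:2000) x[i, ] <- 0.8 * x[i - 1, ] + rnorm(3)
  vac_c <- velocity_autocorrelation(x, 0:3)
  expect_lt(vac_c$vac[vac_c$lag_frames == 1], 0)
})

test_that("MS2 reporter delay is hairpin position over elongation rate", {
  expect_equal(ms2_delay(reporter_spec(10000, 10000, 10)), 1000)
  expect_equal(ms2_delay(reporter_spec(10000, 10000, 60)), 10000 / 60)
  expect_equal(ms2_delay(reporter_spec(10000, 0, 10)), 0)  # 5' tag
  # additive in hairpin position, inversely proportional to rate (exact)
  r1 <- reporter_spec(20000, 4000, 25)
  r2 <- reporter_spec(20000, 6000, 25)
  r12 <- reporter_spec(20000, 10000, 25)
  expect_identical(ms2_delay(r1) + ms2_delay(r2), ms2_delay(r12))
  r_fast <- reporter_spec(20000, 10000, 50)
  expect_identical(ms2_delay(r12), 2 * ms2_delay(r_fast))
  expect_error(reporter_spec(10000, 10000, 0), "rate")
  expect_error(reporter_spec(10000, 20000, 10), "hairpin")
})

test_that("three-state simulation matches its stationary distribution", {
  # all rates zero: the state never changes
  frozen <- kinetic_model_3state(0, 0, 0, 0, 0, 0)
  s0 <- simulate_three_state(frozen, 100, 0.5, seed = 24, initial_state = 2)
  expect_true(all(s0$states == 2L))
  expect_length(s0$initiation_times, 0)

  # symmetric two-state submodel: 50/50 occupancy within 3 sigma binomial
  k <- 0.05
  sym <- kinetic_model_3state(k_pair = k, k_unpair = k, k_on = 0, k_off = 0,
                              k_on_unpair = 0, k_init = 0)
  ss <- simulate_three_state(sym, 10000, 1, seed = 25)
  occ1 <- mean(ss$states == 1)
  n_switch <- sum(diff(ss$states) != 0)
  expect_lt(abs(occ1 - 0.5), 3 * 0.5 / sqrt(n_switch))

  # general generator: empirical occupancy equals the analytic null space
  model <- kinetic_model_3state()
  expect_equal(unname(rowSums(model$Q)), rep(0, 3))  # valid generator
  pi_an <- stationary_distribution(model)
  sim3 <- simulate_three_state(model, 30000, 0.25, seed = 26)
  occ <- tabulate(sim3$states, 3) / length(sim3$states)
  expect_true(all(abs(occ - pi_an) < 0.02))

  # initiations are Poisson with mean k_init * time in ON
  t_on <- sum(sim3$states == 3) * sim3$dt_s
  lam <- model$k_init * t_on
  expect_lt(abs(length(sim3$initiation_times) - lam), 4 * sqrt(lam))

  expect_error(simulate_three_state(model, 100, 1), "unstable dt")
})

test_that("proximity-transcription correlation recovers the reporter delay", {
  model <- kinetic_model_3state()
  sim3 <- simulate_three_state(model, 30000, 0.25, seed = 27)
  every <- 8L  # 2 s frames
  idx <- seq(1, length(sim3$times), by = every)
  frame_dt <- sim3$dt_s * every
  dist <- three_state_distances(sim3, seed = 28)$dist_nm[idx]

  # stable detection (zero delay, short dwell): peak at lag ~ 0
  sig0 <- detected_signal(sim3$initiation_times, sim3$times[idx],
                          delay_s = 0, dwell_s = frame_dt)
  xc0 <- proximity_transcription_correlation(dist, sig0, frame_dt, 200)
  expect_lte(abs(correlation_peak_lag(xc0)), 2 * frame_dt)

  # hit-and-run with a 3' tag delay D: peak at ~ -D (proximity precedes signal)
  D <- 100
  sigD <- detected_signal(sim3$initiation_times, sim3$times[idx],
                          delay_s = D, dwell_s = frame_dt)
  xcD <- proximity_transcription_correlation(dist, sigD, frame_dt, 300)
  expect_lte(abs(correlation_peak_lag(xcD) + D), 2 * frame_dt)

  # independent series: no correlation anywhere
  set.seed(29)
  ind <- rbinom(length(idx), 1, 0.1)
  xci <- proximity_transcription_correlation(dist, ind, frame_dt, 100)
  expect_lt(max(abs(xci$r)), 4.5 / sqrt(length(idx)))

  expect_error(proximity_transcription_correlation(rep(1, 100), sig0[1:100],
                                                   frame_dt, 10),
               "constant")
})
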