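#' Optimal two-color track pairing
#'
#' Assigns each channel-1 track to at most one channel-2 track by minimizing
#' the summed frame-by-frame distance over shared frames, normalized by the
#' number of shared frames (so short overlaps are not favored). Pairs with
#' fewer than `min_overlap` shared frames are infeasible. Up to 6 tracks per
#' channel the assignment is found by exhaustive enumeration; beyond that a
#' shortest-augmenting-path (Hungarian) solver gives the same optimum in
#' O(n^3).
#'
#' @param tracks_ch1,tracks_ch2 lists of data.frames with columns `time_s`,
#'   `x`, `y`, `z` (nm).
#' @param min_overlap minimum number of shared frames for a feasible pair.
#' @param time_tol_s times closer than this count as the same frame.
#' @return list with `pairs` (data.frame `track1`, `track2`, `cost`),
#'   `unmatched_ch1`, `unmatched_ch2`, `total_cost`.
#' @export
pair_two_color <- function(tracks_ch1, tracks_ch2, min_overlap = 5,
                           time_tol_s = 1e-6) {
  n1 <- length(tracks_ch1); n2 <- length(tracks_ch2)
  if (n1 == 0 || n2 == 0) stopf("need at least one track per channel")
  cost <- matrix(NA_real_, n1, n2)
  for (i in seq_len(n1)) {
    a <- tracks_ch1[[i]]
    if (nrow(a) < 1) stopf("track %d in channel 1 has no frames", i)
    for (j in seq_len(n2)) {
      b <- tracks_ch2[[j]]
      ia <- which(!is.na(match(round(a$time_s / time_tol_s),
                               round(b$time_s / time_tol_s))))
      ib <- match(round(a$time_s[ia] / time_tol_s),
                  round(b$time_s / time_tol_s))
      if (length(ia) < min_overlap) next
      dd <- sqrt((a$x[ia] - b$x[ib])^2 + (a$y[ia] - b$y[ib])^2 +
                   (a$z[ia] - b$z[ib])^2)
      cost[i, j] <- mean(dd)
    }
  }
  if (all(is.na(cost)))
    stopf("pairing impossible: no pair of tracks shares %d frames", min_overlap)

  big <- 2 * sum(cost, na.rm = TRUE) + max(cost, na.rm = TRUE) + 1
  n <- max(n1, n2)
  sq <- matrix(big, n, n)
  sq[seq_len(n1), seq_len(n2)] <- ifelse(is.na(cost), big, cost)

  perm <- if (n <= 6) assignment_brute_force(sq) else assignment_hungarian(sq)

  pairs <- data.frame(track1 = seq_len(n), track2 = perm,
                      cost = sq[cbind(seq_len(n), perm)])
  pairs <- pairs[pairs$track1 <= n1 & pairs$track2 <= n2 &
                   pairs$cost < big, , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       unmatched_ch1 = setdiff(seq_len(n1), pairs$track1),
       unmatched_ch2 = setdiff(seq_len(n2), pairs$track2),
       total_cost = sum(pairs$cost))
}

# all permutations of 1..n (n small)
permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, matrix(c(seq_len(n)[-k])[sub], nrow(sub)))))
}

assignment_brute_force <- function(cost) {
  n <- nrow(cost)
  perms <- permutations(n)
  tot <- apply(perms, 1, function(p) sum(cost[cbind(seq_len(n), p)]))
  as.integer(perms[which.min(tot), ])
}

# Hungarian algorithm (shortest augmenting path with potentials), O(n^3).
# Returns perm[i] = column assigned to row i of a square cost matrix.
assignment_hungarian <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1)         # row potentials, u[n+1] unused guard
  v <- numeric(n + 1)         # column potentials, index 1 = virtual column 0
  p <- integer(n + 1)         # p[j+1] = row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          if (p[j + 1] > 0) u[p[j + 1]] <- u[p[j + 1]] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  perm <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) perm[p[j + 1]] <- j
  perm
}

as_positions <- function(x) {
  if (inherits(x, "paired_trajectory"))
    stopf("pass one channel, e.g. as.matrix(traj[, c('ch1_x','ch1_y','ch1_z')])")
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

#' Time-averaged mean squared displacement
#'
#' `MSD(L) = mean_t |x(t+L) - x(t)|^2` over all frame pairs at each lag.
#'
#' @param positions `n x d` matrix of positions (nm), uniformly sampled.
#' @param lags integer frame lags; lags beyond the trajectory are dropped with
#'   a warning.
#' @param dt_s frame interval, seconds (for the `lag_s` column).
#' @return data.frame with `lag_frames`, `lag_s`, `msd_nm2`.
#' @export
msd <- function(positions, lags = NULL, dt_s = 1) {
  x <- as_positions(positions)
  n <- nrow(x)
  if (n < 2) stopf("msd needs at least 2 frames")
  if (is.null(lags)) lags <- seq_len(min(n - 1, 100))
  lags <- as.integer(lags)
  bad <- lags >= n | lags < 0
  if (any(bad)) {
    warning(sprintf("dropping %d lag(s) not inside the trajectory", sum(bad)))
    lags <- lags[!bad]
  }
  m <- vapply(lags, function(L) {
    if (L == 0) return(0)
    d <- x[(L + 1):n, , drop = FALSE] - x[1:(n - L), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
  data.frame(lag_frames = lags, lag_s = lags * dt_s, msd_nm2 = m)
}

#' Normalized velocity (frame displacement) autocorrelation
#'
#' `C(L) = mean_t <v(t) . v(t+L)> / mean_t |v(t)|^2` with
#' `v(t) = x(t+1) - x(t)`; `C(0) = 1`. Anti-correlation at lag 1 signals
#' confined or noise-dominated motion.
#'
#' @inheritParams msd
#' @export
velocity_autocorrelation <- function(positions, lags = NULL, dt_s = 1) {
  x <- as_positions(positions)
  n <- nrow(x)
  if (n < 3) stopf("velocity_autocorrelation needs at least 3 frames")
  v <- x[-1, , drop = FALSE] - x[-n, , drop = FALSE]
  nv <- nrow(v)
  if (is.null(lags)) lags <- 0:min(nv - 1, 50)
  lags <- as.integer(lags)
  bad <- lags >= nv | lags < 0
  if (any(bad)) {
    warning(sprintf("dropping %d lag(s) not inside the trajectory", sum(bad)))
    lags <- lags[!bad]
  }
  c0 <- mean(rowSums(v^2))
  vac <- vapply(lags, function(L) {
    if (L == 0) return(1)
    mean(rowSums(v[1:(nv - L), , drop = FALSE] * v[(L + 1):nv, , drop = FALSE])) / c0
  }, numeric(1))
  data.frame(lag_frames = lags, lag_s = lags * dt_s, vac = vac)
}

#' MS2/PP7 transcription reporter
#'
#' @param gene_length_bp gene length, bp.
#' @param hairpin_position_bp distance from the transcription start site to
#'   the hairpin array insertion (0 = 5'-UTR tag, `gene_length_bp` = 3'-UTR
#'   tag; the default).
#' @param elongation_rate_bp_per_s RNA polymerase elongation rate, bp/s.
#' @param dwell_s how long a finished nascent signal remains visible, s.
#' @return an object of class `reporter_spec`.
#' @export
reporter_spec <- function(gene_length_bp,
                          hairpin_position_bp = gene_length_bp,
                          elongation_rate_bp_per_s = 30,
                          dwell_s = 60) {
  if (hairpin_position_bp < 0 || hairpin_position_bp > gene_length_bp)
    stopf("hairpin position must lie in [0, gene_length]")
  if (elongation_rate_bp_per_s <= 0) stopf("elongation rate must be > 0")
  structure(list(gene_length_bp = gene_length_bp,
                 hairpin_position_bp = hairpin_position_bp,
                 elongation_rate_bp_per_s = elongation_rate_bp_per_s,
                 dwell_s = dwell_s),
            class = "reporter_spec")
}

#' Detection delay of an MS2/PP7 reporter
#'
#' A nascent transcript only becomes visible once the polymerase has
#' transcribed the hairpin array, so initiation is detected
#' `hairpin_position_bp / elongation_rate_bp_per_s` seconds late. For a 10 kb
#' 3'-tagged gene this is 1000 s (~17 min) at 10 bp/s and ~167 s (~3 min) at
#' 60 bp/s.
#'
#' @param reporter a [reporter_spec()].
#' @return delay in seconds.
#' @export
ms2_delay <- function(reporter) {
  if (reporter$elongation_rate_bp_per_s <= 0)
    stopf("elongation rate must be > 0")
  reporter$hairpin_position_bp / reporter$elongation_rate_bp_per_s
}

#' Three-state enhancer-promoter kinetic model
#'
#' Continuous-time Markov chain over the states `unpaired`,
#' `paired_OFF`, `paired_ON`, with transcription initiation as a Poisson
#' process of rate `k_init` while in `paired_ON`. The default rates give a
#' total paired occupancy of about 5%, consistent with the structural-loop
#' scenario. `distance_scale_nm` gives the RMS enhancer-promoter distance per
#' state, used when synthesizing distance series from a state path.
#'
#' @param k_pair unpaired -> paired_OFF rate, 1/s.
#' @param k_unpair paired_OFF -> unpaired rate, 1/s.
#' @param k_on paired_OFF -> paired_ON rate, 1/s.
#' @param k_off paired_ON -> paired_OFF rate, 1/s.
#' @param k_on_unpair paired_ON -> unpaired rate, 1/s.
#' @param k_init transcription initiation rate in paired_ON, 1/s.
#' @param distance_scale_nm named length-3 vector of RMS distances (nm).
#' @return an object of class `kinetic_model_3state` with the generator `Q`.
#' @export
kinetic_model_3state <- function(k_pair = 0.0075, k_unpair = 0.2,
                                 k_on = 0.1, k_off = 0.1,
                                 k_on_unpair = 0.05, k_init = 0.2,
                                 distance_scale_nm = c(unpaired = 350,
                                                       paired_OFF = 60,
                                                       paired_ON = 60)) {
  rates <- c(k_pair, k_unpair, k_on, k_off, k_on_unpair, k_init)
  if (any(rates < 0)) stopf("rates must be >= 0")
  Q <- matrix(0, 3, 3,
              dimnames = list(c("unpaired", "paired_OFF", "paired_ON"),
                              c("unpaired", "paired_OFF", "paired_ON")))
  Q["unpaired", "paired_OFF"] <- k_pair
  Q["paired_OFF", "unpaired"] <- k_unpair
  Q["paired_OFF", "paired_ON"] <- k_on
  Q["paired_ON", "paired_OFF"] <- k_off
  Q["paired_ON", "unpaired"] <- k_on_unpair
  diag(Q) <- -rowSums(Q)
  structure(list(Q = Q, k_init = k_init,
                 distance_scale_nm = distance_scale_nm),
            class = "kinetic_model_3state")
}

#' Stationary distribution of the three-state generator
#' @param model a [kinetic_model_3state()].
#' @return named probability vector solving `pi Q = 0`, `sum(pi) = 1`.
#' @export
stationary_distribution <- function(model) {
  A <- rbind(t(model$Q), rep(1, 3))
  pi <- qr.solve(A, c(0, 0, 0, 1))
  setNames(pmax(pi, 0) / sum(pmax(pi, 0)), rownames(model$Q))
}

#' Simulate the three-state process
#'
#' Discrete-time Markov simulation with transition matrix `I + Q dt`;
#' initiation events are emitted with probability `k_init dt` per step while
#' in `paired_ON`. Fully reproducible from `seed`.
#'
#' @param model a [kinetic_model_3state()].
#' @param duration_s total simulated time, s.
#' @param dt_s time step, s; `dt * max(rate) < 0.1` is enforced for accuracy.
#' @param seed optional integer seed.
#' @param initial_state starting state index (1 = unpaired).
#' @return list with `times`, `states` (integer 1..3), `state_names`,
#'   `initiation_times`, `dt_s`, `model`.
#' @export
simulate_three_state <- function(model, duration_s, dt_s, seed = NULL,
                                 initial_state = 1L) {
  max_rate <- max(abs(diag(model$Q)), model$k_init)
  if (dt_s * max_rate >= 0.1)
    stopf("unstable dt: dt * max rate = %.3f >= 0.1", dt_s * max_rate)
  n <- floor(duration_s / dt_s)
  P <- diag(3) + model$Q * dt_s
  cum <- t(apply(P, 1, cumsum))
  p_init <- model$k_init * dt_s
  with_seed(seed, {
    states <- integer(n)
    s <- as.integer(initial_state)
    u <- stats::runif(n)
    u2 <- stats::runif(n)
    inits <- numeric(0)
    for (i in seq_len(n)) {
      s <- if (u[i] <= cum[s, 1]) 1L else if (u[i] <= cum[s, 2]) 2L else 3L
      states[i] <- s
      if (s == 3L && u2[i] < p_init) inits <- c(inits, i * dt_s)
    }
    list(times = seq_len(n) * dt_s, states = states,
         state_names = rownames(model$Q),
         initiation_times = inits, dt_s = dt_s, model = model)
  })
}

#' Synthesize an enhancer-promoter distance series from a state path
#'
#' Draws an independent 3D-norm (Maxwell) distance per frame with per-state
#' RMS given by the model's `distance_scale_nm`. A crude stand-in for full
#' polymer dynamics that preserves the state-distance coupling used by the
#' correlation analysis.
#'
#' @param sim3 output of [simulate_three_state()].
#' @param seed optional integer seed.
#' @return a [distance_series()] with provenance `"true"`.
#' @export
three_state_distances <- function(sim3, seed = NULL) {
  scale <- sim3$model$distance_scale_nm[sim3$states]
  with_seed(seed, {
    d <- rapparent_distance(length(sim3$states), 0, 1) * scale / sqrt(3)
    distance_series(sim3$times, d, provenance = "true")
  })
}

#' Binary detected nascent-RNA signal
#'
#' The signal is ON at time t when some initiation event fired at
#' `t - delay_s - dwell_s < t_init <= t - delay_s`: detection waits for the
#' polymerase to transcribe the hairpins ([ms2_delay()]) and each transcript's
#' signal persists for `dwell_s`.
#'
#' @param initiation_times event times, s.
#' @param times_s frame times (uniform grid), s.
#' @param delay_s detection delay, s.
#' @param dwell_s signal dwell time, s.
#' @return integer 0/1 vector along `times_s`.
#' @export
detected_signal <- function(initiation_times, times_s, delay_s, dwell_s) {
  sig <- integer(length(times_s))
  for (t0 in initiation_times) {
    on <- times_s >= t0 + delay_s & times_s < t0 + delay_s + dwell_s
    sig[on] <- 1L
  }
  sig
}

#' Cross-correlation of enhancer-promoter proximity with nascent signal
#'
#' Pearson correlation of mean-subtracted proximity (negative distance, so
#' "closer" correlates positively with "transcribing") against the detected
#' signal at signed frame lags. The lag is applied to the proximity series:
#' a peak at negative lag means proximity *precedes* the signal, as expected
#' when the reporter detects initiation only after a delay. Both series must
#' share a uniform time grid.
#'
#' @param distances a [distance_series()] or numeric vector (nm).
#' @param signal numeric/integer signal series, same length.
#' @param dt_s frame interval, s.
#' @param max_lag_s largest |lag| examined, s.
#' @return data.frame with `lag_frames`, `lag_s`, `r`.
#' @export
proximity_transcription_correlation <- function(distances, signal, dt_s,
                                                max_lag_s) {
  x <- -as_distances(distances)
  y <- as.numeric(signal)
  if (length(x) != length(y)) stopf("series lengths differ")
  if (sd(x) < 1e-12 || sd(y) < 1e-12)
    stopf("undefined correlation: constant series")
  x <- x - mean(x); y <- y - mean(y)
  n <- length(x)
  L <- min(floor(max_lag_s / dt_s), n - 2)
  lags <- (-L):L
  r <- vapply(lags, function(l) {
    if (l >= 0) {
      xs <- x[(1 + l):n]; ys <- y[1:(n - l)]
    } else {
      xs <- x[1:(n + l)]; ys <- y[(1 - l):n]
    }
    stats::cor(xs, ys)
  }, numeric(1))
  data.frame(lag_frames = lags, lag_s = lags * dt_s, r = r)
}

#' Lag of the correlation peak
#' @param xc output of [proximity_transcription_correlation()].
#' @return the `lag_s` at which `r` is maximal.
#' @export
correlation_peak_lag <- function(xc) xc$lag_s[which.max(xc$r)]
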