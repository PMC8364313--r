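#' CTCF site table
#'
#' @param site 0-based monomer indices.
#' @param dir blocking direction per site: `-1` holds loop-extruding factor
#'   (LEF) arms that try to step leftward off the site, `+1` holds rightward
#'   movement. A convergent CTCF pair around a loop domain uses `-1` at the
#'   upstream anchor and `+1` at the downstream anchor.
#' @param prob capture probability in `[0, 1]` applied at each blocked step
#'   attempt; 1 is an absorbing stall.
#' @return data.frame with columns site, dir, prob.
#' @export
ctcf_sites <- function(site, dir, prob = 1) {
  if (length(site) == 0)
    return(data.frame(site = integer(), dir = integer(), prob = numeric()))
  stopifnot(all(dir %in% c(-1L, 1L)), all(prob >= 0 & prob <= 1))
  data.frame(site = as.integer(site), dir = as.integer(dir),
             prob = rep_len(prob, length(site)))
}

#' Loop-extrusion state on the 1D lattice
#'
#' @param lefs integer matrix with columns `left`, `right`: 0-based monomer
#'   indices of each LEF's two arms, `left <= right`. Zero rows = no LEFs.
#' @param ctcf a [ctcf_sites()] table.
#' @param loading_rate LEF loading rate per unoccupied site per second.
#' @param velocity extrusion speed of each arm, monomers per second.
#' @param unbinding_rate LEF unbinding rate per second (exponential lifetime
#'   `1/unbinding_rate`; mean unobstructed loop size is
#'   `2 * velocity / unbinding_rate` monomers).
#' @param mapping a [chain_mapping()] used to validate indices.
#' @return an object of class `extrusion_state`.
#' @export
extrusion_state <- function(mapping,
                            lefs = matrix(integer(), ncol = 2),
                            ctcf = default_ctcf(mapping),
                            loading_rate = 2.05e-5,
                            velocity = 20,
                            unbinding_rate = 0.06) {
  lefs <- matrix(as.integer(lefs), ncol = 2)
  colnames(lefs) <- c("left", "right")
  n <- mapping$n_monomers
  if (nrow(lefs) > 0) {
    if (any(lefs[, 1] > lefs[, 2]))
      stopf("invalid extrusion state: LEF left arm must be <= right arm")
    if (any(lefs < 0) || any(lefs >= n))
      stopf("invalid extrusion state: LEF arms outside [0, n_monomers)")
    # exclusion between different LEFs (a freshly loaded LEF may have both
    # of its own arms on one site)
    per_lef <- ifelse(lefs[, 1] == lefs[, 2], 1L, 2L)
    sites <- unlist(mapply(function(l, r, w) if (w == 1L) l else c(l, r),
                           lefs[, 1], lefs[, 2], per_lef, SIMPLIFY = FALSE))
    if (anyDuplicated(sites))
      stopf("invalid extrusion state: two LEFs occupy the same monomer")
  }
  if (any(ctcf$site < 0) || any(ctcf$site >= n))
    stopf("invalid extrusion state: CTCF site outside chain")
  stopifnot(loading_rate >= 0, velocity >= 0, unbinding_rate >= 0)
  structure(list(lefs = lefs, ctcf = ctcf,
                 rates = list(loading = loading_rate, velocity = velocity,
                              unbinding = unbinding_rate)),
            class = "extrusion_state")
}

#' CTCF boundary elements at the mapping's anchors
#'
#' Each anchor is modeled as an impermeable boundary: a site on the anchor
#' monomer stalls arms extruding outward from inside the domain (these form
#' the loop, landing exactly on the anchor), and a site on the adjacent
#' outside monomer stalls arms arriving from the flanks (so flank-loaded LEFs
#' cannot slip past one anchor and bridge the other, which would shortcut the
#' domain).
#'
#' @param mapping a [chain_mapping()].
#' @param prob capture probability for all sites.
#' @export
default_ctcf <- function(mapping, prob = 1) {
  sites <- c(mapping$anchor_A, mapping$anchor_B,
             mapping$anchor_A - 1L, mapping$anchor_B + 1L)
  dirs <- c(-1L, 1L, 1L, -1L)
  keep <- sites >= 0 & sites < mapping$n_monomers
  ctcf_sites(site = sites[keep], dir = dirs[keep], prob = prob)
}

#' @export
print.extrusion_state <- function(x, ...) {
  cat(sprintf("<extrusion_state> %d LEF(s), %d CTCF site(s); load %.3g/site/s, v %.3g mon/s, unbind %.3g/s\n",
              nrow(x$lefs), nrow(x$ctcf), x$rates$loading, x$rates$velocity,
              x$rates$unbinding))
  invisible(x)
}

lef_occupied <- function(lefs, site) {
  nrow(lefs) > 0 && any(lefs[, 1] == site | lefs[, 2] == site)
}

#' One stochastic loop-extrusion step (reference implementation)
#'
#' Advances the 1D extrusion state by `dt` seconds: each LEF unbinds with
#' probability `unbinding_rate * dt`; each surviving arm steps outward with
#' probability `velocity * dt` unless the target site is off-chain or occupied
#' by another LEF arm, or the arm sits on a CTCF site oriented against its
#' direction of motion (held with the site's capture probability, so `prob = 1`
#' pins the arm on the anchor). New LEFs load as width-zero loops at uniformly
#' random unoccupied sites with rate `loading_rate` per free site.
#'
#' This pure-R version defines the update semantics one step at a time and is
#' what the tests exercise; [run_simulation()] uses an equivalent compiled
#' loop for long trajectories.
#'
#' @param state an [extrusion_state()].
#' @param mapping a [chain_mapping()].
#' @param dt_s time step in seconds; `velocity * dt` must be <= 1.
#' @return the updated `extrusion_state`.
#' @export
step_extrusion <- function(state, mapping, dt_s) {
  n <- mapping$n_monomers
  v <- state$rates$velocity
  p_move <- v * dt_s
  p_unbind <- state$rates$unbinding * dt_s
  if (p_move > 1) stopf("rate overflow: velocity * dt = %g > 1", p_move)
  if (p_unbind > 1) stopf("rate overflow: unbinding_rate * dt > 1")

  block_left <- block_right <- numeric(n)
  if (nrow(state$ctcf) > 0) {
    lf <- state$ctcf$dir < 0
    block_left[state$ctcf$site[lf] + 1] <- state$ctcf$prob[lf]
    block_right[state$ctcf$site[!lf] + 1] <- state$ctcf$prob[!lf]
  }

  lefs <- state$lefs
  keep <- rep(TRUE, nrow(lefs))
  for (i in seq_len(nrow(lefs))) {
    if (stats::runif(1) < p_unbind) { keep[i] <- FALSE; next }
    if (stats::runif(1) < p_move) {
      a <- lefs[i, 1]; tgt <- a - 1L
      if (tgt >= 0 && !lef_occupied(lefs, tgt) &&
          !(block_left[a + 1] > 0 && stats::runif(1) < block_left[a + 1]))
        lefs[i, 1] <- tgt
    }
    if (stats::runif(1) < p_move) {
      a <- lefs[i, 2]; tgt <- a + 1L
      if (tgt < n && !lef_occupied(lefs, tgt) &&
          !(block_right[a + 1] > 0 && stats::runif(1) < block_right[a + 1]))
        lefs[i, 2] <- tgt
    }
  }
  lefs <- lefs[keep, , drop = FALSE]

  lam <- state$rates$loading * dt_s * (n - 2 * nrow(lefs))
  if (lam > 0 && stats::runif(1) < lam) {
    free <- setdiff(0:(n - 1), c(lefs))
    if (length(free) > 0) {
      s <- free[sample.int(length(free), 1)]
      lefs <- rbind(lefs, c(s, s))
    }
  }
  state$lefs <- lefs
  state
}

#' Is some LEF bridging both CTCF anchors?
#' @param state an [extrusion_state()].
#' @param mapping a [chain_mapping()].
#' @return logical.
#' @export
is_bridged <- function(state, mapping) {
  lefs <- state$lefs
  nrow(lefs) > 0 &&
    any(lefs[, 1] == mapping$anchor_A & lefs[, 2] == mapping$anchor_B)
}
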