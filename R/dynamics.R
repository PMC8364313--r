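#' One overdamped Langevin step (reference implementation)
#'
#' Euler-Maruyama update of the bead-spring chain with thermal energy kT = 1:
#' `x <- x + mobility * F * dt + sqrt(2 * mobility * dt) * eta`, where `F`
#' collects harmonic backbone bonds (spring constant `3 / b^2`, the ideal-chain
#' value giving `<r^2> = b^2` per bond), one identical harmonic bond per LEF
#' between its two arm monomers, and optional soft-core excluded-volume
#' repulsion. `mobility` (nm^2/s) is also the free-monomer diffusion
#' coefficient.
#'
#' @param conf a [conformation()].
#' @param state an [extrusion_state()] supplying LEF bonds (may have none).
#' @param mapping a [chain_mapping()].
#' @param dt_s time step, seconds.
#' @param mobility_nm2_s temperature-scaled mobility, nm^2/s.
#' @param lef_stiffness LEF bridge spring constant as a multiple of the
#'   backbone bond constant (see [sim_config()]).
#' @param noise if `FALSE`, the thermal noise term is dropped (deterministic
#'   gradient descent on the harmonic energy; useful for integrator checks).
#' @param excluded_volume enable soft-core repulsion between non-bonded
#'   monomers closer than `ev_radius_nm`.
#' @param ev_radius_nm,ev_strength soft-core radius (nm) and force scale
#'   (kT/nm at full overlap).
#' @return the updated `conformation` (time advanced by `dt_s`).
#' @export
step_dynamics <- function(conf, state, mapping, dt_s,
                          mobility_nm2_s = 1000, lef_stiffness = 3,
                          noise = TRUE, excluded_volume = FALSE,
                          ev_radius_nm = 32, ev_strength = 10) {
  pos <- conf$positions
  n <- nrow(pos)
  if (n != mapping$n_monomers)
    stopf("conformation and mapping disagree on chain length")
  k <- 3 / mapping$bond_length_nm^2
  f <- matrix(0, n, 3)

  d <- pos[-1, , drop = FALSE] - pos[-n, , drop = FALSE]
  f[-n, ] <- f[-n, ] + k * d
  f[-1, ] <- f[-1, ] - k * d

  lefs <- state$lefs
  k_lef <- lef_stiffness * k
  for (i in seq_len(nrow(lefs))) {
    a <- lefs[i, 1] + 1L; b <- lefs[i, 2] + 1L
    if (b - a < 2) next
    dv <- pos[b, ] - pos[a, ]
    f[a, ] <- f[a, ] + k_lef * dv
    f[b, ] <- f[b, ] - k_lef * dv
  }

  if (excluded_volume) {
    for (i in seq_len(n - 2)) {
      dv <- pos[(i + 2):n, , drop = FALSE] -
        matrix(pos[i, ], n - i - 1, 3, byrow = TRUE)
      r <- sqrt(rowSums(dv^2))
      hit <- which(r < ev_radius_nm & r > 1e-6)
      for (h in hit) {
        j <- i + 1L + h
        mag <- ev_strength * (1 - r[h] / ev_radius_nm) / r[h]
        f[i, ] <- f[i, ] - mag * dv[h, ]
        f[j, ] <- f[j, ] + mag * dv[h, ]
      }
    }
  }

  pos <- pos + mobility_nm2_s * dt_s * f
  if (noise)
    pos <- pos + sqrt(2 * mobility_nm2_s * dt_s) * matrix(stats::rnorm(3 * n), n, 3)
  if (!all(is.finite(pos)))
    stopf(paste0("numerical instability: non-finite coordinates after update ",
                 "(max |F| = %.3g kT/nm, dt = %g s); reduce dt or mobility"),
          max(abs(f)), dt_s)
  conf$positions <- pos
  conf$time_s <- conf$time_s + dt_s
  conf
}

#' Total harmonic (backbone + LEF bond) energy in kT
#' @inheritParams step_dynamics
#' @export
harmonic_energy <- function(conf, state, mapping, lef_stiffness = 3) {
  pos <- conf$positions
  k <- 3 / mapping$bond_length_nm^2
  d <- pos[-1, , drop = FALSE] - pos[-nrow(pos), , drop = FALSE]
  e <- 0.5 * k * sum(d^2)
  lefs <- state$lefs
  for (i in seq_len(nrow(lefs))) {
    a <- lefs[i, 1] + 1L; b <- lefs[i, 2] + 1L
    if (b - a < 2) next
    e <- e + 0.5 * lef_stiffness * k * sum((pos[b, ] - pos[a, ])^2)
  }
  e
}
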