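#' Genomic-to-physical chain mapping
#'
#' Describes how a chromatin fiber is coarse-grained into a bead-spring chain:
#' how many monomers, how many base pairs each monomer absorbs, the physical
#' bond length, and where the two CTCF anchor monomers sit. The packaged
#' default places the anchors 210 monomers (525 kb at 2.5 kb/monomer) apart on
#' a 300-monomer chain, keeping 45 monomers of flanking chain on either side
#' so the anchors do not feel chain-end effects.
#'
#' @param n_monomers number of monomers in the chain.
#' @param bp_per_monomer base pairs represented by one monomer.
#' @param bond_length_nm equilibrium bond length b in nm.
#' @param anchor_A,anchor_B 0-based monomer indices of the two CTCF anchors,
#'   `anchor_A < anchor_B`.
#' @return an object of class `chain_mapping`.
#' @examples
#' m <- chain_mapping()
#' (m$anchor_B - m$anchor_A) * m$bp_per_monomer  # 525000
#' @export
chain_mapping <- function(n_monomers = 300, bp_per_monomer = 2500,
                          bond_length_nm = 40, anchor_A = 45, anchor_B = 255) {
  if (!is_count(n_monomers) || n_monomers < 2)
    stopf("invalid mapping: n_monomers must be an integer >= 2")
  if (!is_count(bp_per_monomer) || bp_per_monomer < 1)
    stopf("invalid mapping: bp_per_monomer must be a positive integer")
  if (!is.numeric(bond_length_nm) || length(bond_length_nm) != 1 ||
      !is.finite(bond_length_nm) || bond_length_nm <= 0)
    stopf("invalid mapping: bond_length_nm must be > 0")
  if (!is_count(anchor_A) || !is_count(anchor_B) ||
      !(anchor_A < anchor_B) || anchor_B >= n_monomers)
    stopf("invalid mapping: need 0 <= anchor_A < anchor_B < n_monomers")
  structure(list(n_monomers = as.integer(n_monomers),
                 bp_per_monomer = as.integer(bp_per_monomer),
                 bond_length_nm = bond_length_nm,
                 anchor_A = as.integer(anchor_A),
                 anchor_B = as.integer(anchor_B)),
            class = "chain_mapping")
}

#' @export
print.chain_mapping <- function(x, ...) {
  cat(sprintf(paste0("<chain_mapping> %d monomers x %d bp (%.1f nm bonds); ",
                     "anchors %d/%d (%.0f kb apart)\n"),
              x$n_monomers, x$bp_per_monomer, x$bond_length_nm,
              x$anchor_A, x$anchor_B,
              (x$anchor_B - x$anchor_A) * x$bp_per_monomer / 1000))
  invisible(x)
}

#' A single polymer conformation
#'
#' @param positions `n_monomers x 3` matrix of coordinates in nm.
#' @param time_s simulation time of the snapshot, seconds.
#' @return an object of class `conformation`.
#' @export
conformation <- function(positions, time_s = 0) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3 || !all(is.finite(positions)))
    stopf("conformation positions must be a finite n x 3 matrix")
  colnames(positions) <- c("x", "y", "z")
  structure(list(positions = positions, time_s = time_s),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("<conformation> %d monomers at t = %g s\n",
              nrow(x$positions), x$time_s))
  invisible(x)
}

#' Initialize a chain as an ideal random walk
#'
#' Draws a random-walk conformation with fixed-length bonds (length
#' `bond_length_nm`, isotropic random directions). This is an exact sample
#' from the ideal-chain equilibrium ensemble of the harmonic-backbone model up
#' to the (small) difference between fixed-length and Gaussian bonds, so
#' dynamics started here need no conformational burn-in for a free chain.
#'
#' @param mapping a [chain_mapping()].
#' @param seed optional integer seed (R RNG); same seed gives identical
#'   coordinates.
#' @return a [conformation()] at time 0, first monomer at the origin.
#' @export
init_chain <- function(mapping, seed = NULL) {
  if (!inherits(mapping, "chain_mapping"))
    stopf("invalid mapping: expected a chain_mapping object")
  n <- mapping$n_monomers
  b <- mapping$bond_length_nm
  with_seed(seed, {
    u <- stats::runif(n - 1, -1, 1)        # cos(polar angle)
    phi <- stats::runif(n - 1, 0, 2 * pi)
    s <- sqrt(1 - u^2)
    steps <- b * cbind(s * cos(phi), s * sin(phi), u)
    pos <- rbind(c(0, 0, 0), apply(steps, 2, cumsum))
    conformation(pos, time_s = 0)
  })
}

# squared distances between monomer pairs s bonds apart, averaged over the
# chain; used by the ideal-chain equilibrium tests
internal_mean_square_distance <- function(positions, s) {
  n <- nrow(positions)
  if (s >= n) stopf("subchain length s must be < n_monomers")
  d <- positions[(s + 1):n, , drop = FALSE] - positions[1:(n - s), , drop = FALSE]
  mean(rowSums(d^2))
}
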