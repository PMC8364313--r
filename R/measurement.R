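#' Fluorescent tag specification
#'
#' Where a label sits relative to its locus of interest. The label region
#' starts at `target_bp + tether_offset_bp` and spans `probe_span_bp` base
#' pairs (0 = point label on a single monomer). Genomic coordinates are
#' 0-based, intervals half-open.
#'
#' @param target_bp genomic position of the locus of interest.
#' @param tether_offset_bp signed genomic distance from locus to label start
#'   (the tether length d1/d2 of a two-color design).
#' @param probe_span_bp length of the labeled region, bp.
#' @param channel channel identifier, e.g. `"ch1"`.
#' @return an object of class `tag_spec`.
#' @export
tag_spec <- function(target_bp, tether_offset_bp = 0, probe_span_bp = 0,
                     channel = "ch1") {
  stopifnot(is.numeric(target_bp), length(target_bp) == 1,
            is.numeric(tether_offset_bp), probe_span_bp >= 0)
  structure(list(target_bp = target_bp,
                 tether_offset_bp = tether_offset_bp,
                 probe_span_bp = probe_span_bp,
                 channel = as.character(channel)),
            class = "tag_spec")
}

#' Monomer index containing a genomic position
#' @param bp genomic coordinate (0-based).
#' @param mapping a [chain_mapping()].
#' @return 0-based monomer index, `floor(bp / bp_per_monomer)`.
#' @examples
#' monomer_for_locus(2499, chain_mapping())  # 0
#' monomer_for_locus(2500, chain_mapping())  # 1
#' @export
monomer_for_locus <- function(bp, mapping) {
  max_bp <- mapping$n_monomers * mapping$bp_per_monomer
  if (any(bp < 0) || any(bp >= max_bp))
    stopf("coordinate error: bp must lie in [0, %d)", max_bp)
  as.integer(floor(bp / mapping$bp_per_monomer))
}

# 0-based monomers covered by a tag's labeled region
probe_monomers <- function(tag, mapping) {
  start <- tag$target_bp + tag$tether_offset_bp
  if (tag$probe_span_bp == 0) return(monomer_for_locus(start, mapping))
  last <- start + tag$probe_span_bp - 1
  max_bp <- mapping$n_monomers * mapping$bp_per_monomer
  if (start < 0 || last >= max_bp)
    stopf("coordinate error: probe [%g, %g) extends off the chain",
          start, start + tag$probe_span_bp)
  monomer_for_locus(start, mapping):monomer_for_locus(last, mapping)
}

#' True (noise-free) 3D position reported by a tag
#'
#' Point labels return the coordinate of the single labeled monomer; extended
#' probes return the uniform-intensity centroid of all labeled monomers.
#'
#' @param conf a [conformation()].
#' @param tag a [tag_spec()].
#' @param mapping a [chain_mapping()].
#' @return length-3 numeric (nm).
#' @export
true_tag_position <- function(conf, tag, mapping) {
  mon <- probe_monomers(tag, mapping)
  colMeans(conf$positions[mon + 1L, , drop = FALSE])
}

#' Measurement noise model for two-color localization
#'
#' @param sigma_nm per-axis localization SD; a scalar, a length-3 vector
#'   `(sx, sy, sz)` applied to both channels, or a named list per channel.
#' @param chromatic_shift_nm named list of per-channel 3-vectors (nm) added to
#'   apparent positions; channels absent from the list shift by zero only if
#'   named here, so declare every channel you will measure.
#' @param exposure_s camera exposure; positions are uniform time-averages of
#'   the true positions falling inside the exposure window (motion blur).
#' @param shift_field optional named list of 3x3 matrices `A` per channel
#'   making the shift position-dependent: `shift(p) = shift0 + A %*% p`.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(sigma_nm = c(30, 30, 30),
                        chromatic_shift_nm = list(ch1 = c(0, 0, 0),
                                                  ch2 = c(0, 0, 0)),
                        exposure_s = 0,
                        shift_field = NULL) {
  if (!is.list(sigma_nm)) {
    sigma_nm <- rep_len(sigma_nm, 3)
    sigma_nm <- lapply(setNames(nm = names(chromatic_shift_nm)),
                       function(ch) sigma_nm)
  } else {
    sigma_nm <- lapply(sigma_nm, rep_len, 3)
  }
  if (any(unlist(sigma_nm) < 0)) stopf("sigma_nm must be >= 0")
  if (exposure_s < 0) stopf("exposure_s must be >= 0")
  structure(list(sigma_nm = sigma_nm,
                 chromatic_shift_nm = chromatic_shift_nm,
                 exposure_s = exposure_s,
                 shift_field = shift_field),
            class = "noise_model")
}

channel_sigma <- function(noise, channel) {
  s <- noise$sigma_nm[[channel]]
  if (is.null(s)) stopf("unknown channel '%s' in noise model", channel)
  s
}

channel_shift <- function(noise, channel, pos) {
  s0 <- noise$chromatic_shift_nm[[channel]]
  if (is.null(s0)) stopf("unknown channel '%s' in noise model", channel)
  if (!is.null(noise$shift_field[[channel]])) {
    A <- noise$shift_field[[channel]]
    if (is.matrix(pos))
      return(matrix(s0, nrow(pos), 3, byrow = TRUE) + pos %*% t(A))
    return(s0 + as.numeric(A %*% pos))
  }
  if (is.matrix(pos)) matrix(s0, nrow(pos), 3, byrow = TRUE) else s0
}

#' Corrupt true positions with localization error and chromatic shift
#'
#' Adds independent per-axis Gaussian error with the channel's SDs, then the
#' channel's chromatic shift (evaluated at the true position when a shift
#' field is configured).
#'
#' @param pos length-3 vector or `n x 3` matrix of true positions (nm).
#' @param noise a [noise_model()].
#' @param channel channel identifier.
#' @return apparent position(s), same shape as `pos`.
#' @export
apply_noise <- function(pos, noise, channel = "ch1") {
  s <- channel_sigma(noise, channel)
  shift <- channel_shift(noise, channel, pos)
  if (is.matrix(pos)) {
    err <- matrix(stats::rnorm(length(pos)), nrow(pos), 3)
    err <- sweep(err, 2, s, `*`)
  } else {
    err <- stats::rnorm(3) * s
  }
  pos + err + shift
}

#' Undo the channel's chromatic shift
#'
#' Subtracts the calibrated shift (evaluated at the supplied apparent position
#' when a shift field is configured). For a constant shift,
#' `correct_chromatic_shift(apply_noise(p, nm, ch), nm, ch)` restores the
#' noise-free geometry exactly; with a position-dependent field the residual
#' equals the field mismatch between the true and apparent positions.
#'
#' @inheritParams apply_noise
#' @export
correct_chromatic_shift <- function(pos, noise, channel = "ch1") {
  pos - channel_shift(noise, channel, pos)
}

#' Motion blur: uniform time-average over an exposure window
#' @param positions `n x 3` matrix of sub-frame positions (n >= 1).
#' @return length-3 averaged position.
#' @export
motion_blur <- function(positions) {
  positions <- rbind(positions)
  if (nrow(positions) == 0) stopf("motion_blur: empty exposure window")
  colMeans(positions)
}

#' Localization precision from photon count
#'
#' The centroid of a fitted spot improves with the square root of the number
#' of detected photons: `sigma_psf / sqrt(N)`.
#'
#' @param psf_sigma_nm PSF standard deviation, nm.
#' @param n_photons detected photons (>= 1).
#' @return localization SD, nm.
#' @export
localization_precision <- function(psf_sigma_nm, n_photons) {
  if (any(n_photons < 1)) stopf("n_photons must be >= 1")
  psf_sigma_nm / sqrt(n_photons)
}

#' Second-moment statistics of a rendered fluorescent spot
#'
#' Models the emission of an extended probe as equal-intensity 3D Gaussians of
#' width `psf_sigma_nm` centered on each labeled monomer, and returns exact
#' moment statistics of the resulting intensity distribution: the centroid,
#' per-axis widths `sqrt(psf^2 + var_axis(monomers))` (population variance),
#' and the asymmetry `sqrt(largest/smallest principal variance)` of the
#' intensity covariance. Long probes on a disordered chain yield broadened,
#' asymmetric spots.
#'
#' @param conf a [conformation()].
#' @param tag a [tag_spec()] (the probe).
#' @param mapping a [chain_mapping()].
#' @param psf_sigma_nm PSF SD; scalar (isotropic) or per-axis length-3.
#' @return an object of class `spot_stats`: centroid_nm, widths_nm,
#'   asymmetry, total_intensity.
#' @export
render_spot <- function(conf, tag, mapping, psf_sigma_nm = 130) {
  if (any(psf_sigma_nm <= 0)) stopf("psf_sigma_nm must be > 0")
  psf <- rep_len(psf_sigma_nm, 3)
  mon <- probe_monomers(tag, mapping)
  if (length(mon) == 0) stopf("empty probe")
  p <- conf$positions[mon + 1L, , drop = FALSE]
  centroid <- colMeans(p)
  dev <- sweep(p, 2, centroid)
  cov_pop <- crossprod(dev) / nrow(p)
  covm <- cov_pop + diag(psf^2)
  ev <- eigen(covm, symmetric = TRUE, only.values = TRUE)$values
  structure(list(centroid_nm = centroid,
                 widths_nm = sqrt(diag(covm)),
                 asymmetry = sqrt(max(ev) / min(ev)),
                 total_intensity = length(mon)),
            class = "spot_stats")
}

#' @export
print.spot_stats <- function(x, ...) {
  cat(sprintf("<spot_stats> widths (%.1f, %.1f, %.1f) nm, asymmetry %.2f, intensity %g\n",
              x$widths_nm[1], x$widths_nm[2], x$widths_nm[3],
              x$asymmetry, x$total_intensity))
  invisible(x)
}

#' Observe a two-tag trajectory through the measurement model
#'
#' For every recorded sample: true tag positions (probe centroids), optional
#' motion blur over the exposure window, per-channel Gaussian localization
#' error plus chromatic shift, then apparent and true 3D inter-tag distances.
#' The simulation object is never modified.
#'
#' @param sim a `loop_sim` whose recording covers both probes' monomers.
#' @param tag1,tag2 [tag_spec()]s on the same chain (different channels).
#' @param noise a [noise_model()].
#' @param seed optional integer seed for the measurement noise.
#' @return a `paired_trajectory` data.frame with columns `time_s`,
#'   `ch1_x..ch1_z`, `ch2_x..ch2_z`, `dist_nm`, `true_dist_nm`.
#' @export
measure_trajectory <- function(sim, tag1, tag2, noise = noise_model(),
                               seed = NULL) {
  mapping <- sim$config$mapping
  pos_of <- function(tag) {
    mon <- probe_monomers(tag, mapping)
    idx <- match(mon, sim$monomers)
    if (anyNA(idx))
      stopf("probe monomers not recorded in this simulation; rerun with them")
    if (length(idx) == 1) return(sim$positions[, idx, ])
    # probe centroid per sample
    apply(sim$positions[, idx, , drop = FALSE], c(1, 3), mean)
  }
  t1 <- pos_of(tag1)
  t2 <- pos_of(tag2)

  if (noise$exposure_s > 0 && !is.null(sim$replicate))
    stopf("motion blur across pooled replicates is not defined; use a single run")
  if (noise$exposure_s > 0) {
    blur <- function(p) {
      t(vapply(seq_along(sim$times), function(i) {
        win <- sim$times >= sim$times[i] &
          sim$times < sim$times[i] + noise$exposure_s
        motion_blur(p[win, , drop = FALSE])
      }, numeric(3)))
    }
    t1b <- blur(t1); t2b <- blur(t2)
  } else {
    t1b <- t1; t2b <- t2
  }

  with_seed(seed, {
    a1 <- apply_noise(t1b, noise, tag1$channel)
    a2 <- apply_noise(t2b, noise, tag2$channel)
    out <- data.frame(time_s = sim$times,
                      ch1_x = a1[, 1], ch1_y = a1[, 2], ch1_z = a1[, 3],
                      ch2_x = a2[, 1], ch2_y = a2[, 2], ch2_z = a2[, 3],
                      dist_nm = sqrt(rowSums((a1 - a2)^2)),
                      true_dist_nm = sqrt(rowSums((t1 - t2)^2)))
    class(out) <- c("paired_trajectory", "data.frame")
    out
  })
}
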