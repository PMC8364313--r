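test_that("genomic coordinates map to monomers with 0-based half-open bins", {
  m <- chain_mapping()
  expect_identical(monomer_for_locus(0, m), 0L)
  expect_identical(monomer_for_locus(2499, m), 0L)
  expect_identical(monomer_for_locus(2500, m), 1L)
  # a 10 kb tether is a 4-monomer offset on 2.5 kb monomers
  expect_identical(monomer_for_locus(112500 + 10000, m) -
                     monomer_for_locus(112500, m), 4L)
  expect_error(monomer_for_locus(-1, m), "coordinate")
  expect_error(monomer_for_locus(300 * 2500, m), "coordinate")
})

test_that("true tag positions are monomer coordinates or probe centroids", {
  m <- chain_mapping(n_monomers = 10, anchor_A = 2, anchor_B = 8)
  set.seed(8)
  cf <- init_chain(m)
  # tether 0, span 0: exactly the anchor monomer position
  tg <- tag_spec(2 * 2500)
  expect_equal(true_tag_position(cf, tg, m), unname(cf$positions[3, ]),
               ignore_attr = TRUE)
  # span over two monomers: midpoint
  tg2 <- tag_spec(0, probe_span_bp = 5000)
  expect_equal(true_tag_position(cf, tg2, m),
               colMeans(cf$positions[1:2, ]), ignore_attr = TRUE)
  # probe running off the chain is a coordinate error
  expect_error(true_tag_position(cf, tag_spec(20000, probe_span_bp = 10000), m),
               "coordinate")
})

test_that("noise, chromatic shift and blur reduce to identity at zero", {
  nm0 <- noise_model(sigma_nm = 0)
  p <- c(10, -5, 3)
  expect_equal(apply_noise(p, nm0, "ch1"), p)
  expect_equal(correct_chromatic_shift(p, nm0, "ch1"), p)
  expect_equal(motion_blur(rbind(p)), p)
  expect_error(apply_noise(p, nm0, "ch7"), "unknown channel")
})

test_that("localization noise has the configured per-axis variance and shifts add", {
  nm <- noise_model(sigma_nm = 30,
                    chromatic_shift_nm = list(ch1 = c(0, 0, 0),
                                              ch2 = c(50, 0, 0)))
  set.seed(10)
  err <- apply_noise(matrix(0, 1e5, 3), nm, "ch1")
  expect_equal(apply(err, 2, var), rep(900, 3), tolerance = 0.05)

  # pure shift, no noise
  nms <- noise_model(sigma_nm = 0,
                     chromatic_shift_nm = list(ch1 = c(0, 0, 0),
                                               ch2 = c(50, 0, 0)))
  p <- c(1, 2, 3)
  expect_equal(apply_noise(p, nms, "ch2"), p + c(50, 0, 0))
  # apply then correct restores the original exactly (constant shift)
  expect_equal(correct_chromatic_shift(apply_noise(p, nms, "ch2"), nms, "ch2"), p)

  # mismatched linear field: residual equals the field evaluated at the
  # (shifted) position minus at the true one
  A <- diag(c(0.01, 0, 0))
  nmf <- noise_model(sigma_nm = 0,
                     chromatic_shift_nm = list(ch1 = c(0, 0, 0)),
                     shift_field = list(ch1 = A))
  appl <- apply_noise(p, nmf, "ch1")          # field at the true position
  corr <- correct_chromatic_shift(appl, nmf, "ch1")  # field at apparent pos
  expect_equal(corr - p, as.numeric(A %*% p) - as.numeric(A %*% appl))
})

test_that("motion blur averages and reduces apparent variance", {
  p <- rbind(c(0, 0, 0), c(10, 4, -2))
  expect_equal(motion_blur(p), c(5, 2, -1))
  expect_error(motion_blur(p[0, , drop = FALSE]), "empty")
  # averaging a diffusing locus shrinks the position variance
  set.seed(11)
  raw <- matrix(rnorm(3000), ncol = 3)
  blurred <- t(vapply(seq(1, 998, by = 5), function(i)
    motion_blur(raw[i:(i + 4), ]), numeric(3)))
  expect_true(all(apply(blurred, 2, var) < apply(raw, 2, var)))
})

test_that("localization precision follows the photon square-root law", {
  expect_equal(localization_precision(130, 1), 130)
  expect_equal(localization_precision(130, 100), 13)
  expect_equal(localization_precision(130, 400), localization_precision(130, 100) / 2)
  expect_error(localization_precision(130, 0), "photons")
})

test_that("rendered spots have exact moment widths and broaden with probe span", {
  m <- chain_mapping(n_monomers = 50, anchor_A = 0, anchor_B = 49)
  set.seed(12)
  cf <- init_chain(m)
  # point source: widths equal the PSF, asymmetry 1
  s1 <- render_spot(cf, tag_spec(0), m, psf_sigma_nm = 130)
  expect_equal(unname(s1$widths_nm), rep(130, 3))
  expect_equal(s1$asymmetry, 1)

  # two points 2*psf apart along x: x-width sqrt(2)*psf, exact second moment
  cf2 <- conformation(rbind(c(0, 0, 0), c(260, 0, 0)))
  m2 <- chain_mapping(n_monomers = 2, anchor_A = 0, anchor_B = 1)
  s2 <- render_spot(cf2, tag_spec(0, probe_span_bp = 5000), m2, 130)
  expect_equal(unname(s2$widths_nm), c(sqrt(2) * 130, 130, 130))
  expect_gt(s2$asymmetry, 1)

  # broadening: median width grows from 10 kb to 100 kb probes
  sim <- free_chain_sim()
  mp <- sim$config$mapping
  widths <- function(span) {
    tg <- tag_spec(150 * 2500, tether_offset_bp = -span / 2, probe_span_bp = span)
    vapply(1:150, function(i)
      mean(render_spot(get_frame(sim, i), tg, mp, 130)$widths_nm), numeric(1))
  }
  expect_lt(median(widths(10000)), median(widths(100000)))
})

test_that("measured trajectories reproduce truth at zero noise and inflate with it", {
  sim <- default_loop_sim()
  m <- sim$config$mapping
  tags <- anchor_tags(m, 0)

  tr0 <- measure_trajectory(sim, tags[[1]], tags[[2]],
                            noise_model(sigma_nm = 0), seed = 2)
  expect_equal(tr0$dist_nm, tr0$true_dist_nm, tolerance = 1e-12)
  expect_equal(tr0$true_dist_nm, anchor_distances(sim)$dist_nm,
               tolerance = 1e-12)

  # isotropic noise inflates the mean apparent distance
  tr <- measure_trajectory(sim, tags[[1]], tags[[2]],
                           noise_model(sigma_nm = 30), seed = 2)
  expect_gt(mean(tr$dist_nm), mean(tr$true_dist_nm))

  # measurement is pure: the simulation object is untouched
  expect_identical(sim$positions, default_loop_sim()$positions)
})

test_that("10 kb tethers keep tag distances >100 nm even when anchors touch", {
  sim <- default_loop_sim()
  m <- sim$config$mapping
  tags <- anchor_tags(m, 10000)
  tr <- measure_trajectory(sim, tags[[1]], tags[[2]],
                           noise_model(sigma_nm = 0), seed = 3)
  looped <- anchor_distances(sim)$dist_nm < 50
  expect_gt(sum(looped), 300)
  # The static ideal-chain floor over the 8 intervening tether monomers is
  # mean ~ 2 sqrt((8 b^2 / 3)) sqrt(2/pi) ~ 108 nm; extrusion dynamics add to
  # it (loop closure outruns flank relaxation, so conditioned-on-contact
  # frames carry stretched tethers), so the observed conditional mean sits
  # between that floor and roughly twice it.
  cond_mean <- mean(tr$dist_nm[looped])
  expect_gt(cond_mean, 100)
  expect_lt(cond_mean, 230)
})

test_that("apparent distances at fixed truth follow the noncentral-chi law", {
  # measurement pipeline vs the closed-form oracle: KS < 0.01 at n = 1e5
  set.seed(13)
  d_true <- 120; s_loc <- 50
  p1 <- apply_noise(matrix(0, 1e5, 3), noise_model(sigma_nm = s_loc), "ch1")
  p2 <- apply_noise(matrix(rep(c(d_true, 0, 0), each = 1e5), ncol = 3),
                    noise_model(sigma_nm = s_loc), "ch1")
  r <- sqrt(rowSums((p2 - p1)^2))
  ks <- max(abs(ecdf(r)(sort(r)) -
                  papparent_distance(sort(r), d_true, s_loc * sqrt(2))))
  expect_lt(ks, 0.01)
})
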