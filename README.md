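# loopscope

Design pitfalls of two-color super-resolution live-cell chromatin imaging
(SRLCI), simulated end to end.

SRLCI experiments tag two genomic loci — say the CTCF anchors of a loop
domain, or an enhancer and its promoter — with spectrally distinct
fluorophores and track their 3D distance over time. Between the biology and
the measurement sit several distortions that can make a genuine molecular
contact (< 50 nm) read out as hundreds of nanometers: the fluorescent label
is tethered some genomic distance d₁/d₂ from the locus of interest, the
labeled region has finite extent, each localization carries per-axis Gaussian
error of tens of nanometers, the channels are chromatically shifted, and
MS2/PP7 nascent-RNA reporters only become visible after the polymerase has
transcribed the hairpin array. `loopscope` is a forward model of that whole
chain, for experimentalists planning such a measurement and for analysts who
want calibrated null expectations.

The package has three layers:

* **Polymer simulator** — a CTCF loop domain as a bead-spring chain
  (300 monomers × 2.5 kb, bond b = 40 nm, anchors 525 kb apart) under
  overdamped Langevin dynamics (kT = 1, spring constant 3/b²), with cohesin
  loop extrusion on the 1D lattice: LEFs load, extrude bidirectionally at
  speed v, stall at CTCF boundary elements and unbind
  (`run_simulation()`, `run_ensemble()`, `calibrate_loop_occupancy()`). The
  packaged defaults are calibrated so the anchors are within the 50 nm
  contact radius ~5% of the time.
* **Measurement model** — tag tether offsets and finite probe spans
  (`tag_spec()`), per-axis Gaussian localization error, chromatic shift and
  motion blur (`noise_model()`, `apply_noise()`,
  `correct_chromatic_shift()`), the √N photon law
  (`localization_precision()`), second-moment spot rendering for extended
  probes (`render_spot()`), and `measure_trajectory()` to turn true
  conformations into apparent two-color trajectories.
* **Analysis** — contact fractions and distance histograms
  (`contact_fraction()`, `distance_histogram()`), the closed-form
  noncentral-chi law of apparent distances (`dapparent_distance()` and
  friends — the analytic oracle for every Monte Carlo path), bimodality
  scoring with a BIC-compared mixture of noncentral-chi shapes plus a dip
  statistic (`bimodality_score()`), optimal two-color track pairing
  (`pair_two_color()`), MSD and velocity autocorrelation, the MS2/PP7
  detection delay (`ms2_delay()`), and a three-state enhancer–promoter
  kinetic model with proximity–transcription cross-correlation
  (`simulate_three_state()`, `proximity_transcription_correlation()`).

Key relation used throughout: with true separation d and combined per-axis
localization SD σ, the apparent distance r follows the noncentral-chi(3) law

    f(r) = r / (d σ √(2π)) · [exp(−(r−d)²/2σ²) − exp(−(r+d)²/2σ²)],

the Maxwell distribution at d = 0. Its mean always exceeds d: localization
error inflates distances, never shrinks them.

## Worked example

Simulate the default 525 kb loop domain (an ensemble of replicate chains,
pooled the way an imaging experiment pools loci across cells), then compare
what a perfect label placement and a realistic one would see:

```r
library(loopscope)

cfg <- sim_config(n_samples = 2000, seed = 2)
sim <- run_ensemble(cfg, n_replicates = 10,
                    monomers = c(41, 45, 255, 259))

# ground truth: the anchors touch (<50 nm) about 5% of the time
contact_fraction(anchor_distances(sim))
#> [1] 0.05375

m <- cfg$mapping
on_target <- list(tag_spec(m$anchor_A * 2500, channel = "ch1"),
                  tag_spec(m$anchor_B * 2500, channel = "ch2"))
tethered  <- list(tag_spec(m$anchor_A * 2500, tether_offset_bp = -10000,
                           channel = "ch1"),
                  tag_spec(m$anchor_B * 2500, tether_offset_bp = 10000,
                           channel = "ch2"))

# labels directly on the anchors, no localization error: clearly bimodal
tr0 <- measure_trajectory(sim, on_target[[1]], on_target[[2]],
                          noise_model(sigma_nm = 0), seed = 502)
bimodality_score(tr0)
#> <bimodality_result> 2 component(s), delta BIC 5974.7, dip 0.0061, bimodal: TRUE
#>   component mean distances 35 nm (w=0.06) and 392 nm (w=0.94)

# labels 10 kb away from each anchor: the loop mode is gone
tr10 <- measure_trajectory(sim, tethered[[1]], tethered[[2]],
                           noise_model(sigma_nm = 0), seed = 10502)
bimodality_score(tr10)
#> <bimodality_result> 2 component(s), delta BIC 3327.4, dip 0.0055, bimodal: FALSE
#>   component mean distances 182 nm (w=0.32) and 468 nm (w=0.68)

# and with 35 nm per-axis error, frames where the anchors truly touch
# still measure as hundreds of nanometers between the tags
tr <- measure_trajectory(sim, tethered[[1]], tethered[[2]],
                         noise_model(sigma_nm = 35), seed = 4)
quantile(tr$dist_nm[anchor_distances(sim)$dist_nm < 50], c(0.5, 0.95))
#>      50%      95%
#> 174.7422 392.0867

# a 10 kb gene, 3'-tagged: the reporter fires 3-17 minutes late
ms2_delay(reporter_spec(10000, elongation_rate_bp_per_s = 10)) / 60
#> [1] 16.66667
ms2_delay(reporter_spec(10000, elongation_rate_bp_per_s = 60)) / 60
#> [1] 2.777778
```

The numbers mean: the structural loop is present ~5% of the time, and with
perfect labels the distance distribution resolves it — a 6%-weight component
with mean distance 35 nm, well separated from the 392 nm bulk, and the
two-mode test fires. Moving each label 10 kb away (8 intervening monomers,
an ideal-chain tether of RMS √8·40 ≈ 113 nm, further stretched by loop
dynamics) blends the loop into the bulk: a two-component fit still improves
the likelihood, but the density has no second mode and the flag is FALSE.
Adding 35 nm per-axis localization error on top, frames where the anchors
truly touch read as a median ~175 nm and a 95th percentile ~390 nm between
the tags — squarely in "proximity, not contact" territory. And a 3'-UTR MS2
tag delays every transcription event by 3–17 min depending on the elongation
rate. `run_label_design_pipeline()` runs the full tether / noise / probe-span
sweep and returns the corresponding tables.

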