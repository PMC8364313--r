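---
title: "Methods: simulating what super-resolution live-cell imaging does to a chromatin loop"
author: "loopscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating what super-resolution live-cell imaging does to a chromatin loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopscope)
```

## Why this package exists

Two-color super-resolution live-cell imaging (SRLCI) is the only way to watch
an enhancer-promoter or CTCF-CTCF interaction unfold in time, but every link
in the measurement chain distorts what is seen: the fluorescent label sits
some genomic distance (the *tether*, d1/d2) away from the locus of interest;
the labeled region has finite extent; each localization carries tens of
nanometers of per-axis Gaussian error; the two channels are chromatically
shifted; and nascent-RNA reporters only light up after the polymerase has
transcribed the hairpin array. `loopscope` provides a controlled forward
model of the entire chain — a loop-extrusion polymer simulation of a CTCF
loop domain, a measurement model, and the downstream statistics — so that a
planned experimental design can be stress-tested *in silico*: would you still
see the loop you are looking for?

## The polymer model

The chromatin fiber is a bead-spring chain of `n_monomers` beads, each
representing `bp_per_monomer` base pairs. The default mapping is 300 monomers
at 2.5 kb/monomer with the two CTCF anchors at monomers 45 and 255 — 210
monomers, i.e. 525 kb, apart — so each anchor keeps 45 monomers (112.5 kb) of
flanking chain and does not feel chain-end effects.

Dynamics are overdamped Langevin (Euler–Maruyama), with thermal energy
normalized to kT = 1:

$$
\mathbf{x}_i \leftarrow \mathbf{x}_i + \mu\,\mathbf{F}_i\,\Delta t
  + \sqrt{2\mu\,\Delta t}\;\boldsymbol{\eta}_i,
\qquad \boldsymbol{\eta}_i \sim \mathcal{N}(0, I_3),
$$

where the mobility $\mu$ (nm²/s) doubles as the free-monomer diffusion
coefficient. Backbone bonds are harmonic with the ideal-chain spring constant
$k = 3/b^2$ (bond length $b = 40$ nm), which gives $\langle r^2\rangle = b^2$
per bond and the Gaussian-chain internal distances
$\langle R^2(s)\rangle = s\,b^2$ that the tests verify to within 10%.
Excluded volume is **off** by default: the quantities of interest here are
pairwise distance statistics, for which the ideal chain is the standard and
analytically checkable reference; a soft-core repulsion
($|F| = A(1 - r/r_c)$ for $r < r_c$) is available behind a flag for users who
need topological realism.

Loop extrusion runs on the 1D monomer lattice, coupled to the 3D chain: each
loop-extruding factor (LEF, a cohesin stand-in) occupies two arm positions
joined by one extra harmonic bond identical to a backbone bond. Per time step
each arm moves one monomer outward with probability $v\,\Delta t$ unless the
target site is off-lattice or occupied by another LEF arm; an arm sitting on
a CTCF site oriented against its direction of motion is held with the site's
capture probability (1 by default — an absorbing stall, so arms land exactly
on the anchor monomers). LEFs unbind at rate $k_\mathrm{off}$ (exponential
lifetime) and new LEFs load as width-zero loops at uniformly random
unoccupied sites at rate $k_\mathrm{load}$ per free site.

Each anchor is modeled as an impermeable *boundary element* rather than a
single directional motif: an inside-facing site on the anchor monomer stalls
the arms that build the loop, and an outside-facing site on the adjacent
flank monomer stalls arms arriving from outside the domain. With a lone
directional site, a LEF loaded in a flank slips past the near anchor
(directionality lets it through) and stalls at the far one, bonding the
anchor to the flank; such "shortcut" loops compress the anchor pair to a
fraction of its contour and bury the low-distance histogram mode under a
spurious intermediate-distance hump. Real domain boundaries are clusters of
CTCF sites and are conventionally treated as extrusion-impermeable in minimal
models; the two-site boundary implements exactly that.

### Default parameters and why

| parameter | default | rationale |
|---|---|---|
| bond length $b$ | 40 nm | coarse-grained fiber scale; below the 50 nm contact radius so a bridged loop registers as a contact |
| contact radius $r_c$ | 50 nm | the conventional "contact" definition for chromatin interactions |
| mobility $\mu$ | 1000 nm²/s | gives locus dynamics fast enough to decorrelate within a desk-scale run |
| timestep $\Delta t$ | 0.01 s | per-step RMS displacement $\sqrt{6\mu\Delta t} \approx 7.7$ nm, under the enforced $b/2$ stability bound (and $\le 0.2\,b$) |
| extrusion speed $v$ | 20 monomers/s | deliberately accelerated LEF kinetics (see below). Faster speeds were rejected: an arm drags the chain with a lag of $\sim v/(2\mu k)$ monomers, and at $v \gtrsim 30$ this active driving visibly stretches the fiber near trafficked regions |
| unbinding $k_\mathrm{off}$ | 0.06 /s | processivity $2v/k_\mathrm{off} \approx 670$ monomers $\gg$ the 210-monomer anchor gap, so a domain-loaded LEF usually reaches both anchors (~10 s transit against a ~17 s mean residence), while loop episodes stay short enough that a default ensemble contains 100+ of them — the contact-fraction estimate is episode-limited |
| LEF bridge stiffness | 3 × backbone | holds a bridged anchor pair at ~23 nm RMS, inside the 50 nm contact radius ~96% of the time, so the "looped configuration" and the distance-based contact definition coincide; a 1x bridge (~40 nm RMS) leaves a quarter of genuinely looped frames outside the contact radius and smears the low-distance histogram mode |
| loading $k_\mathrm{load}$ | 2.05e-5 /site/s | **calibrated**, see below |
| sampling | every 50 steps (0.5 s) | resolves loop formation/decay episodes |
| burn-in | 5e4 steps (500 s) | ~20 LEF lifetimes; see below |

Two deliberate departures from physical literalism:

* **Accelerated LEF kinetics.** In vivo cohesin extrudes at roughly
  0.5–1 kb/s with residence times of minutes. Simulated at face value, a
  50,000-sample run would contain only a handful of loop formation/decay
  episodes and the contact fraction would be statistically useless. We keep
  the *ratios* that matter (processivity well above the anchor separation,
  transit short against the stalled episode, episodes short relative to the
  observation window) and speed up the clock: loop episodes turn over ~150
  times per acceptance-scale ensemble, which makes the ~5% contact fraction
  estimable to a few tenths of a percentage point.
* **Short burn-in.** The initial conformation is drawn from the exact
  ideal-chain equilibrium ensemble (fixed-length random-walk bonds), so the
  free-chain degrees of freedom start *at* equilibrium and only the
  extrusion state needs to relax; 500 s covers ~20 LEF lifetimes. A burn-in
  of several chain Rouse times would be needed only if the chain were started
  from an atypical conformation.
* **Replicate ensembles, not one long run.** The slowest Rouse mode of the
  300-mer relaxes in ~5000 s, so no desk-scale single trajectory can
  time-average the bulk (unlooped) distance distribution — each window
  freezes in a particular large-scale conformation and the histogram's bulk
  wobbles from seed to seed. `run_ensemble()` therefore pools replicate
  chains, each drawn fresh from the equilibrium ensemble, exactly as an
  imaging experiment pools loci across many cells: the fast loop-extrusion
  episodes average *within* each window, the slow conformational degrees of
  freedom average *across* replicates. All packaged distance statistics
  (calibration, histograms, bimodality sweeps) use pooled ensembles.

### Calibration to the 5% looped fraction

The reference scenario is a 525 kb loop domain whose anchors are within
50 nm about 5% of the time. "Looped" is operationalized two ways and both are
reported by `run_simulation()`: (a) *bridged* — some LEF is stalled at both
CTCF anchors (`$bridged`); (b) *in contact* — the 3D anchor distance is below
50 nm. The two differ: a bridged loop is held by a 40 nm-scale bond and sits
below 50 nm only ~75–80% of the time, while partially extruded loops
contribute transient contacts. Calibration targets definition (b), the
distance-based one, because that is what an imaging experiment measures.
`calibrate_loop_occupancy()` bisects the loading rate (the contact fraction
is monotone in it) and the packaged default `2.05e-5`/site/s is the frozen
result of that calibration (the acceptance script recomputes the achieved
fraction from scratch at 100,000 pooled samples).
With loading switched off entirely, the ideal-chain baseline contact
probability of two loci 210 monomers apart is
$(4/3)\pi r_c^3\,(3/(2\pi n b^2))^{3/2} \approx 9\times10^{-4}$ — the looped
state is what the extruder adds.

### Engine and reproducibility

Long trajectories run in a fused C++ loop (extrusion and Langevin update per
step) with an internal xoshiro256++ generator seeded from the configuration
seed, so a run is bit-reproducible from `(config, seed)` and independent of
R's RNG state. The pure-R `step_extrusion()`/`step_dynamics()` functions
define the same update rules one step at a time; the tests exercise those
directly (stalling, exclusion, energy dissipation, equilibrium bond
statistics) and check the engine against analytic equilibrium laws, so the
two implementations vouch for each other statistically rather than bitwise.
`run_simulation(monomers = ...)` records only requested loci, keeping a
50,000-sample run at a few megabytes.

## The measurement model

* **Tags** (`tag_spec`): the label starts `tether_offset_bp` away from the
  target locus and spans `probe_span_bp` (0 = point label). Genomic
  coordinates are 0-based half-open; a 10 kb tether on 2.5 kb monomers is
  exactly 4 monomers.
* **Localization error** (`apply_noise`): independent per-axis Gaussian error
  per channel. Default 30 nm per axis — "tens of nanometers", the realistic
  live-cell regime; the panel-specific values of published figures are user
  parameters, not constants.
* **Chromatic shift**: constant per-channel 3-vector, optionally with a
  linear position-dependent field; `correct_chromatic_shift()` inverts it
  exactly when the calibration model matches, and leaves exactly the field
  mismatch when it does not.
* **Motion blur**: uniform average of true positions across the exposure
  window.
* **Photon budget**: `localization_precision()` implements the
  $\sigma_\mathrm{PSF}/\sqrt{N}$ law.
* **Finite probes** (`render_spot`): emission is modeled as equal-intensity
  3D Gaussians (width = PSF) at each labeled monomer. Spot statistics are
  *exact second moments* of that mixture — per-axis widths
  $\sqrt{\sigma_\mathrm{PSF}^2 + \mathrm{var}_\mathrm{axis}}$ and
  principal-axis asymmetry — rather than a rasterize-and-refit pipeline; no
  camera model is implied, and fitting rendered images back to localizations
  is out of scope. Default PSF: $\sigma_{xy} = 130$ nm, $\sigma_z = 350$ nm
  (standard widefield values); widths are full-3D moments.

The analytic backbone of the measurement layer is the law of apparent
distances: if the true separation is $d$ and the *combined* per-axis error of
the two loci is $\sigma$ ($\sqrt{\sigma_1^2+\sigma_2^2}$), the apparent
distance is the norm of a displaced 3D Gaussian — a noncentral chi with 3
degrees of freedom,

$$
f(r) = \frac{r}{d\,\sigma\sqrt{2\pi}}
 \left[e^{-(r-d)^2/2\sigma^2} - e^{-(r+d)^2/2\sigma^2}\right],
$$

reducing to the Maxwell distribution at $d = 0$. `dapparent_distance()` /
`papparent_distance()` implement the closed forms and every Monte Carlo path
in the package is tested against them (KS < 0.01 at $n = 10^5$). Two direct
consequences drive the design warnings: the mean apparent distance always
exceeds the true distance, and at $d = 0$ with 50 nm per-locus error the
apparent distance exceeds 200 nm with probability
$\mathrm{erfc}(z/\sqrt2) + \sqrt{2/\pi}\,z\,e^{-z^2/2} \approx 0.046$
($z = 200/(50\sqrt2)$) — "perfect colocalization" routinely measures as
hundreds of nanometers.

## The analysis layer

**Bimodality.** A structural loop present ~5% of the time shows up as a small
low-distance mode against a broad unlooped background. `bimodality_score()`
fits one- and two-component mixtures of noncentral-chi shapes (distances are
non-negative norms; Gaussian components would be the wrong family) by maximum
likelihood with deterministic quantile-based starts, and compares them by
BIC. The distribution is declared bimodal only when (i) the two-component
model is preferred by $\Delta\mathrm{BIC} \ge 10$ (a conservative,
"decisive"-evidence threshold, stable at $n \sim 10^3$) **and** (ii) the
fitted mixture density has two *distinct* modes: two local maxima whose
connecting valley falls below 80% of the lower peak. Condition (ii) is the
literal meaning of "bimodal" and guards against large-$n$ BIC rewarding
generic lack of fit of a single shape when the true distribution is a
unimodal blend — in that failure mode the "second maximum" is a ripple whose
valley sits within a few percent of its peak, far from the 80% cutoff, while
a genuine loop mode over a broad bulk produces valley-to-peak ratios of
0.2–0.5; the rule is insensitive to the exact cutoff over that whole range. A Hartigan-style dip statistic is reported alongside,
computed from its definition: for each candidate mode, the best unimodal CDF
is the greatest convex minorant of the empirical CDF to the left stitched to
the least concave majorant to the right, and the dip is half the smallest
maximal deviation (samples are thinned to 300 order statistics before the
O(n²) scan). The published figure this mirrors never quantifies
"bimodality"; the thresholded $\Delta$BIC is this package's convention and is
flagged as such in reports.

**Trajectory pairing.** Two-color tracks are paired by minimizing the summed
frame-by-frame distance, normalized by the number of shared frames (at least
5) so short overlaps are not artificially cheap. Up to 6 tracks per channel
the optimum is found by exhaustive enumeration; beyond that by a
shortest-augmenting-path (Hungarian) solver, written in-package because no
assignment solver is among the package's dependencies, and tested against
brute force.

**Time-domain tools.** `msd()` (time-averaged, expected slope ~0.5 on
log-log axes for a Rouse monomer at intermediate lags) and
`velocity_autocorrelation()` (normalized displacement autocorrelation; −0.5
at lag 1 for localization-noise-dominated tracks — a useful diagnostic).

**Reporter delay and the three-state model.** `ms2_delay()` is the exact
arithmetic `hairpin_position / elongation_rate`: a 10 kb 3′-tagged gene at
10–60 bp/s reports 1000 s (~17 min) down to ~167 s (~3 min) after initiation.
The enhancer-promoter interaction itself is modeled as a three-state Markov
chain — *unpaired*, *paired & OFF*, *paired & ON* — with initiation a Poisson
process (rate `k_init`) while in *paired & ON*. Default rates give ~5% total
paired occupancy, consistent with the structural-loop scenario.
`proximity_transcription_correlation()` correlates mean-subtracted proximity
(negative distance, so "closer" correlates positively with "transcribing")
with the detected signal at signed lags, the lag applied to the proximity
series: a hit-and-run interaction read out through a 3′ reporter with delay
$D$ peaks at lag $\approx -D$ — proximity precedes signal. The detected
signal is binary with a fixed dwell (default 60 s) per transcript;
correlation peaks are smeared by about half the dwell time, so delay-recovery
checks use a dwell of one frame. Pearson correlation at signed lags is this
module's convention; rate *inference* from data (HMM fitting of interaction
states) is deliberately out of scope.

## What the generator does and does not emulate

The synthetic data reproduce: a two-anchor loop domain in contact ~5% of the
time; tether offsets of 0–10 kb; per-axis Gaussian localization error of tens
of nm; probes spanning 10–200 kb; chromatic shift; motion blur; and
reporter-delayed transcription readout. They do **not** contain: excluded
volume or chain topology (unless enabled), nucleosome-level structure,
sister-chromatid doublets, tracking/detection failures, camera noise,
photobleaching, or cell-to-cell variability. Passing tests therefore show
that the *measurement chain itself* destroys or distorts the signal as
described — they do not certify performance on real movies, where those
additional effects stack on top.

## Numerical choices and degenerate inputs

* Timestep validity is enforced at configuration time (RMS step $< b/2$);
  the integrator raises a diagnostic error on non-finite coordinates.
* With noise off the Euler step is pure gradient descent, so harmonic energy
  is non-increasing — tested, as an integrator-sanity invariant.
* `velocity * dt > 1` or `unbinding_rate * dt > 1` are rate-overflow errors.
* Mixture fits use L-BFGS-B with box constraints ($\mu \ge 0$,
  $\sigma \ge 10^{-3}$) and several deterministic starts; a constant distance
  series is declared unimodal with score 0; fewer than 50 points is an error.
* `distance_histogram()` uses left-closed right-open bins anchored at 0 and
  extends the range as needed so densities always integrate to 1.
* Ties in the dip construction are broken by an order-preserving jitter of
  relative size 1e-9.
* The calibration bisects in log rate and reports the bracketing values when
  the target is unreachable.

## Problem sizes used by the tests and acceptance script

The reference scale is an ensemble of replicate default chains (300 monomers,
5000 samples per replicate at 0.5 s spacing): 10 replicates (50,000 pooled
conformations) in the test suite and 20 (100,000) in the acceptance script —
the scale at which the 5% contact fraction and the conditioned tag-distance
percentiles are computed. Smaller chains and sample counts are used for
unit-level physics checks (equilibrium bond statistics, Rouse scaling, MSD
slopes). These sizes were chosen so the Monte-Carlo error of each reported
quantity is several times smaller than the tolerance applied to it.

## Known limitations

* The extrusion model is minimal: two-sided, fixed speed, no pausing, no
  bypassing, CTCF as a hard directional stall. It is sufficient to produce
  the bimodal/unimodal distance phenomenology; it is not a cohesin model.
* LEF kinetics are accelerated (see above); absolute times in simulation
  output should be read as scaled, not literal, seconds. Extrusion is an
  active process even in this minimal form: moving arms drag the chain, and
  loop closure (seconds) outruns the relaxation of the flanking chain (tens
  of seconds for the ~110 kb flanks), so frames conditioned on anchor
  contact carry tethers still stretched toward where the anchors came from.
  With 10 kb tethers the conditional tag-tag mean therefore sits well above
  the static ideal-chain floor of ~110 nm (typically 1.3–1.7x, seen in the
  tests as an envelope rather than a point value). The direction of the bias
  only strengthens the design warning the simulation is built to quantify:
  tethered labels over-report loop distances.
* Probe rendering assumes uniform labeling efficiency per monomer (flagged
  extension point) and computes moments, not fitted localizations.
* The three-state distance synthesis draws i.i.d. per-frame distances given
  the state — it preserves state-distance coupling but not polymer memory;
  use the polymer simulator when temporal distance correlations matter.
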