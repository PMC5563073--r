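---
title: "Quantifying RNA granule docking, local translation and branch remodeling in axon time-lapse imaging"
author: "axodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{axodyn methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axodyn)
```

## Scope and scientific background

Developing axons branch extensively while navigating to their targets, and
mRNAs transported into the axon terminal as ribonucleoprotein particles
("RNA granules") can be translated locally where new protein is needed.
`axodyn` implements the quantitative image-analysis procedures used to link
three observations in time-lapse imaging of retinal ganglion cell (RGC)
axon terminals:

1. **Granule trafficking and docking** — run-and-pause transport of granules
   along the terminal shaft, their pausing ("docking") at fixed sites, and
   the temporal association between docking events and the emergence of
   filopodia and branches, with two randomized controls.
2. **Local translation read out by FRAP** — recovery of a fluorescent
   translation reporter after photobleaching, normalized recovery curves and
   their single-exponential fits, and the fluorescence variation index
   (FVI), a hotspot statistic that compares intensity heterogeneity in
   branches against the axon shaft.
3. **Spatial coincidence of RNA dwell and nascent protein** — per-pixel
   dwell-time maps (temporal medians) and cumulative recovery maps (temporal
   maxima), compared by masked Pearson correlation against Costes-style
   block-scramble nulls.

Because the imaging data behind these procedures are not public, the package
pairs every estimator with a stochastic generator of synthetic time-lapse
data whose ground truth is known. The published population statistics are
the generator's presets, and each estimator is validated by parameter
recovery: simulate under the preset, measure, and require agreement within
Monte-Carlo tolerance. This is what `tests/testthat/` and
`scripts/acceptance.R` do end to end.

## Data model

All coordinates use the arc length `s` (µm) along the terminal shaft, 0 at
the proximal edge of the analyzed segment and increasing distally, so
anterograde transport means increasing `s`. Default acquisition metadata
follow the fast live-imaging protocol: 118 nm pixels and a 3 s frame
interval (the docking criterion requires at least 3 frames; sampling must be
at most one third of the docking threshold).

The S4 containers are deliberately thin: `AxonGeometry` (shaft polyline and
acquisition metadata), `GranuleKinetics`, `BranchKinetics` and `FrapModel`
(presets with validity checks), `AxonRecording` (track table + protrusion
table + ground truth), `FrapSeries` (pre-/post-bleach stacks with roi,
shaft, branch and background masks), and `ArborTrace` (SWC-style node table
with a branch decomposition). Track and event tables are plain data frames
with stable column names so that real tracking exports can be analyzed with
the same functions.

## Granule dynamics estimators

**Motility classes.** Over a 60 s window a granule is *stationary* if its
maximum excursion from the starting position is below 1 µm, *bi-directional*
if it reverses direction at least once with runs of at least 1 µm on both
sides of the turn (turning-point detection with a 1 µm hysteresis), and
otherwise *anterograde* or *retrograde* by the sign of its net displacement.
The excursion reading of "moved less than 1 µm" keeps the classes exhaustive
and mutually exclusive: an oscillating granule with large swings is
bi-directional, not stationary.

**Speeds.** Runs are maximal stretches of frame steps whose speed exceeds
2 µm/min with consistent direction and whose displacement reaches 1 µm; each
run contributes displacement/duration, averaged per granule and then across
granules, separately by direction. Pauses and docks are thereby excluded,
so the estimator recovers the preset run speeds without dilution.

**Docking.** A dock is a maximal interval in which the granule's position
range (max s − min s) stays within one granule diameter (1 µm by default)
for at least 10 s (60 s for mitochondria). The range criterion is the
direct reading of "stationary or oscillatory movements within a distance of
the diameter": a centroid-referenced criterion would admit a span of two
diameters and absorb several approach frames on each side, which distorts
dock onsets — and onsets matter, because the randomized-follow control
scores protrusion emergence within 10 s *of dock onset*. Detection is
greedy left-to-right over maximal windows and is tested for exact agreement
with an exhaustive window-enumeration oracle.

**Association statistics.** Three quantities connect docking to branching:

* `protrusionDockAssociation()` — the fraction of protrusions with a dock
  overlapping the 10 s window before emergence within one granule diameter
  of the base (published value 84%);
* `randomSiteDockFraction()` — the fraction of uniformly random
  (position, time) sites covered by a dock (16%), the spatial control;
* `randomFollowControl()` — nearest granule to a random site, followed
  forward to its first dock of ≥ 10 s, scored positive if a protrusion is
  born within 10 s of dock onset at the dock position (22%), the
  prospective control.

Two ambiguities had to be resolved: "within the 10 s of docking" is read as
within 10 s *after dock onset* (the alternative readings — during the dock,
or after dock end — are expressible through `windowS` but are not the
default), and a dock already in progress at the query time counts as the
first dock found (the follower sees a granule that *is* docking; skipping
ongoing docks would make permanently docked stationary granules invisible
to the control, which cannot be what a manual scorer does).

## The synthetic generator

### Motion model

The generator is defined by what the estimators must recover, since the
source describes window statistics rather than a kinetic model. Motion is a
discrete-time Markov chain on the frame grid: runs at the preset speed with
geometric dwell (mean 12 s), separated by single-frame pauses, with the
minimum run length chosen so that consecutive pauses are separated by more
than one granule diameter. Under these rules no natural dwell window can
satisfy the 10 s docking criterion, so *docking events are exactly the docks
the generator inserts* — the property that makes the three association
probabilities independently controllable. Bi-directional granules alternate
run direction every run, guaranteeing a reversal in any 60 s window.
Stationary granules hold position with 0.03 µm jitter. Granules leaving the
segment wrap to the opposite end under a fresh track id (bi-directional
granules reflect instead), keeping density stationary in time.

### Docks, protrusions and calibration

Docks are inserted on directed mobile granules as Poisson arrivals and
frozen in place for 12–18 s; a subset ("coupled") spawns a protrusion at the
dock position 1–2.5 s after dock onset, so the dock both overlaps the 10 s
pre-birth window and persists through emergence, as observed in vivo.
Uncoupled protrusions, at rate `(1 − coupled fraction) ×` the total
protrusion rate (50 filopodia + 8 branches per 10 min on the terminal
50 µm), appear at uniform positions. Stationary granules sit in clusters of
three at shared sites — immobile granules accumulate at a few hotspots per
terminal — and are docked throughout.

The two insertion rates are solved from the presets inside
`axodyn:::dockInsertionPlan()`:

* the coupled rate reproduces `pDockGivenProtrusion × protrusion rate`,
  discounted for *coincidental* positives (an uncoupled protrusion can meet
  a background dock in its 10 s window; the expected spacetime coverage of
  that window is computed from the dock counts, durations and the
  association radius, and the coupled fraction is lowered so the *measured*
  association equals the preset);
* the uncoupled rate balances the randomized-follow procedure: queries that
  resolve to permanently docked stationary granules are always negative,
  mobile-granule queries find a coupled first dock with a probability set by
  the coupled/uncoupled rate ratio, and a few composition factors (the share
  of resolved queries landing on directed granules, the detection-onset fuzz
  of coupled docks, the false-positive rate of uncoupled docks) enter as
  constants matched by Monte Carlo at the default presets.

Poisson insertion with a refractory dock occupancy is a counter with dead
time, so the candidate rate is inflated by the type-II correction
`rate / (1 − rate × busy)`; the refractory gap of 3 frames also guarantees
that consecutive docks sit more than a diameter apart and cannot merge in
detection.

The background random-site coverage is then an emergent consistency check
rather than a free dial: stationary clusters contribute a constant spatial
coverage (sites × 2 radius / length) and inserted docks a spacetime term
(count × duration × 2 radius / (length × time)). The stationary cluster
size (3) and dock duration range (12–18 s) were chosen once so that total
coverage sits at the preset 16% under the default presets; the
rate-consistency test in `test-simulate-axon.R` verifies all three
statistics within 3 Monte-Carlo SE over 50 replicate axons.

### What the generator does and does not emulate

It reproduces: granule density (Poisson, 2.6/10 µm), the four motility
fractions, run speeds, dock-protrusion coupling with the published
probabilities, protrusion addition/removal rates with triangular length
profiles, and (through `renderStack()`) diffraction-limited spot images on
an axon-shaped background. It does **not** emulate: photon-counting noise
statistics of real cameras (Gaussian noise is used), granule excursions into
branches (tracks stay on the shaft; branch-resident dwell can be encoded
through the optional `branch_id`/`d_um` track columns), anisotropic drift,
z-sectioning, or biological heterogeneity between axons beyond Poisson
sampling. Passing parameter-recovery tests therefore demonstrates estimator
correctness under the stated model, not robustness to every real-world
artifact.

## FRAP analysis

Normalized recovery is `R(t) = (F(t) − F0) / Fp` on background-corrected
roi means, with `F0` from the first post-bleach frame and `Fp` from the
pre-bleach frames; `R(0) = 0` by construction and `R` is invariant to affine
intensity rescaling. The synthetic series pin the recovery to the published
anchors — 18.6% at 5 min for the translated reporter, 4.8% at 10 min for the
control — through the plateau identity `A = fraction / (1 − e^(−t/τ))`
(τ = 100 s and 200 s respectively; the cycloheximide preset suppresses the
plateau to 0.03). The per-frame acquisition-bleaching parameter defaults to
0 because the anchors are as-measured recoveries; it exists to stress-test
the pipeline. Fitting uses Levenberg–Marquardt least squares for
`A (1 − e^(−t/τ))` with multi-start initialization over a τ grid and bounds
`A ∈ (0, 1]`, and ordinary least squares for the quadratic FVI trend; nested
fits are compared with the extra sum-of-squares F test.

The FVI of a frame is the population SD of branch-mask pixels divided by
the population SD of shaft-mask pixels, pooling all branches of the axon:
≈ 1 for spatially uniform recovery, > 1 when recovery concentrates in focal
hotspots. `fviSeries()` computes it per post-bleach frame; histogram-matching
bleach correction is available but off by default, because remapping a
*recovering* series onto the first post-bleach frame's histogram rescales
the recovery signal itself — the histogram method is meant for channels
whose intensity distribution is stationary, such as the RNA channel feeding
the dwell map. Drift is corrected by integer-pixel phase correlation;
descriptor-based registration is not reimplemented because rigid
translation is an adequate drift model at these timescales and field sizes.

## Arbor complexity

`ArborTrace` reads SWC text with the shaft marked by its SWC type code.
Branch decomposition follows the traced-path convention of neurite-tracing
tools: a path keeps its identity through bifurcations (the lowest-id
non-shaft child continues it), and other children become daughter branches,
one order higher; branches off the shaft are primary. This is the reading
under which an arbor with four primary and two secondary branches has six
branches, not eight. The axon complexity index is the mean branch order,
`ACI = Σ order / n branches`, isolated in one method so an alternative
formula is a one-line change; it is 1 for purely primary arbors, consistent
with the simple/complex cut at 1.4 (simple < 1.4 ≤ complex). Branch length
sums each branch's own polyline (including its attachment edge), not its
descendants.

## Dwell maps, cumulative FRAP and scramble nulls

The dwell map is the per-pixel temporal median of the (corrected) RNA
series within the axon mask; the cumulative FRAP map is the per-pixel
temporal maximum of the recovery series. Both are tested against their
brute-force per-pixel oracles. Masked Pearson correlation is computed over
mask pixels (or voxels; a time-resolved variant returns R per frame).

Significance uses a Costes-style block scramble: the second image is
partitioned into square blocks, blocks fully inside the mask are permuted
uniformly (partial blocks frozen — the simplest rule that preserves mask
support), and R is recomputed per scramble; only one channel is scrambled
because Pearson correlation is symmetric in its arguments. The default
block edge of 8 px matches the rendered PSF full width at half maximum
(1 µm at 118 nm pixels) and is exposed as a parameter because the null
width depends on it. `obsVsNull()` summarizes per-axon observed-minus-null
differences with a paired t test and empirical percentiles.

For validation, image pairs with a prescribed expected correlation are
built by the variance-ratio construction: adding zero-mean noise with
variance `r × Var(A)` inside the mask gives `E[R] = 1 / sqrt(1 + r)`, so
`r = 0.731` targets the published dwell-map/recovery correlation of 0.76.

## Numerical conventions and problem sizes

Boundary rules (all documented at the functions, all configurable):
protrusions of exactly 5 µm are branches; lifetimes of exactly 30 min are
short-lived; branch lengths of exactly 15 µm are short; ACI of exactly 1.4
is complex; an axon moving exactly 5 µm/hr is not stalled (the stalling
definition is strict). Every stochastic entry point takes an explicit seed,
runs under a private RNG stream and restores the caller's RNG state, so
identical calls are bit-identical and independent of call order.

The test suite and acceptance script size their simulations for a few
minutes on one CPU: 500–1000 granule tracks for kinetics recovery, 25–50
axons of 10 min recordings for the docking statistics, 50 seeded FRAP
series per preset, and 50 dwell-map replicates; these sizes put the
Monte-Carlo SE of every recovered statistic well inside the 3 SE acceptance
bands.

## Known limitations

* The dock-insertion calibration constants are matched at the default
  presets; far from those presets (for example, an order-of-magnitude change
  in density or protrusion rate) the three association statistics will still
  move in the right direction but are no longer guaranteed to land within
  Monte-Carlo error of the presets.
* Granule tracks live on a 1D arc-length axis rendered into 2D images; no
  true 2D diffusion or branch excursions are simulated.
* The follow control's nearest-granule metric is |Δs| along the shaft, as in
  the tracked-coordinate analysis; it does not model observer bias in manual
  tracking.
* FRAP simulation treats bleaching as instantaneous and spatially uniform
  within the roi; diffusion-versus-binding recovery models are out of scope
  (only the empirical normalization and the two published fits).
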