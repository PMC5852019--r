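---
title: "Quantifying membrane-protein mobility and reorganization in bacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane-protein mobility and reorganization in bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bactoscope)
```

## Scope

`bactoscope` implements the image-quantification procedures used to study
how inner-membrane proteins of *Escherichia coli* (the Tol-Pal system and
its partners) change mobility and spatial organization when outer-membrane
proteins are engaged — for example by a colicin. Four measurement families
are covered, plus the synthetic-microscopy generator that provides ground
truth for all of them:

1. **FRAP** — double-normalized recovery curves and a single-exponential
   kinetic fit yielding a mobile fraction.
2. **Single-particle tracking** — sub-pixel localization by elliptical
   Gaussian fitting, frame-by-frame nearest-neighbour linking,
   single-bleach-step selection, and diffusion coefficients from the first
   four points of the time-averaged MSD via `MSD(t) = 4Dt`.
3. **Cluster statistics** — the max/mean *relative intensity* heterogeneity
   index, the ≥3-shared-pixel co-clustering percentage with a Monte-Carlo
   random-placement null, the yellow-pixel colocalization ratio, and
   bead-based two-channel similarity alignment.
4. **Axial profiling** — pole detection as the maximally separated pixel
   pair of a thresholded region, 11 offset line profiles averaged and
   resampled to 0–100 % of cell length, with septal/polar summary indices.

No public raw data accompany these procedures, so the package treats its
simulator as a first-class module: every estimator is validated against
scenes whose ground truth is known exactly.

## Coordinate and unit conventions

Images are numeric matrices indexed `[row, column]`, 1-based, with pixel
centers at integer coordinates. Point data are `(x = column, y = row)`.
Physical lengths are pixel distances times `pixel_size_um`. The two imaging
constants that recur throughout — 0.096 µm/px and a 33 ms frame
interval — are the defaults of `cell_geometry()` and `motion_model()`.

## The synthetic scene model

A scene (`scene_spec()`) combines:

* **Geometry** — a spherocylinder (rectangle with semicircular caps) of
  length `length_um` pole-to-pole and cap radius `radius_um`, rasterized by
  testing each pixel center against the outline. The default 3 × 1 µm cell
  is a typical *E. coli* size.
* **Emitter distribution** — `uniform`, `clustered` (uniform cluster
  centers + isotropic Gaussian offsets, resampled until inside the cell),
  `septal` (axial Gaussian band at mid-cell), or `polar` (half-Gaussians at
  the two poles). These emulate the uniform, toxin-clustered, divisome- and
  pole-associated patterns seen in live cells.
* **Motion** — Brownian displacements with per-axis variance `2 D Δt`.
  The cell outline reflects specularly; the reflection targets a radius
  ~0.71 px inside the outline so that every continuous position rounds
  onto a pixel of the rasterized mask (the containment invariant used by
  the tests). Optional confinement is a hard reflecting disc centered on
  the emitter's starting position, applied after the boundary so the
  tether radius is never exceeded — the simplest mechanism that produces
  the MSD plateau characteristic of a colicin-tethered protein.
* **Photophysics/camera** — each live emitter contributes
  `photons_per_frame` expected counts through an isotropic Gaussian PSF
  (σ = 1.3 px by default), on a constant background; the expected image is
  Poisson-sampled and Gaussian read noise is added. Bleaching is a
  per-frame Bernoulli event with a permanent dark state (no blinking),
  which is exactly the single-step phenotype the tracking filter selects
  for. `shot_noise = FALSE` gives deterministic expected-value renders for
  oracle tests.

Every stochastic function takes an explicit seed (scenes carry one in the
camera model); the same spec and seed reproduce output bit-for-bit.

What the generator deliberately does **not** model: motion blur within a
frame (positions are sampled instantaneously), blinking/fluorophore
re-activation, aberrated or depth-dependent PSFs, curved cells, and 3D
sectioning. Passing tests therefore demonstrate correctness of the
*estimators* under the stated model, not robustness to every artifact of
real microscopes.

## FRAP

`double_normalize()` implements the standard double normalization: per
frame, the mean background (a rectangle outside all cells) is subtracted
from both the measurement-box mean and the whole-cell mean; their ratio
corrects the gradual acquisition photobleaching; dividing by the pre-bleach
ratio scales the curve so the pre-bleach point is exactly 1. The whole-cell
mean is used as the bleaching-correction denominator; if a reference-region
variant is preferred, pass that region as the cell mask.

Two ROI sizes coexist deliberately: bleaching uses a 50 × 30 px rectangle
while intensity readout uses a 50 × 50 px box centered on it, mirroring
common acquisition protocols that bleach a tighter stripe than they
measure.

`fit_recovery()` fits `I(t) = I0 + A(1 − exp(−kt))` to the post-bleach
points (bleach at `t = 0`, first sample at 5 s, then every 5 s to 60 s,
plus 120 s and 180 s — `frap_default_times()`). The mobile fraction is
`A / (1 − I0)`. Two numerical guards matter in practice:

* a flat noisy curve can be mimicked by an unidentifiably fast rise with a
  negative `I0`; the exponential is therefore only reported when it beats
  the constant model in an F-test (otherwise the curve is declared flat,
  mobile fraction 0);
* non-convergence returns a flagged result with residual diagnostics, not
  an exception.

Single-exponential kinetics is an approximation to diffusive refilling; it
slightly underestimates intermediate mobile fractions because the early
sqrt-t-like rise pulls `I0` up. In the package's validation conditions
(5 × 1 µm cell at 50 nm/px, 250 emitters, mobile D = 0.1 µm²/s, full-depth
bleach of the left half-cell, 5 cells averaged per condition) recovered
mobile fractions are within ±0.08 of truth across
f ∈ {0, 0.25, 0.5, 0.75, 1}, within the package's ±0.1 validation band.

## Tracking and diffusion

`detect_and_fit()` finds local maxima of a lightly smoothed frame above
`median + 5·MAD` (robust units, so the threshold adapts to background and
noise), merges candidates closer than one fit window to the brighter one,
and refines each by least-squares elliptical Gaussian fitting in a 9 × 9
window. `link_frame_by_frame()` is greedy nearest-neighbour linking,
closest pairs first, no gap closing — the simplest rule faithful to
frame-by-frame construction; it is validated against an exhaustive
assignment oracle for up to three particles. `single_bleach_step_filter()`
accepts a trace only when the best one-step piecewise-constant fit is
significant against a constant, a second change point brings no significant
F-test improvement (α = 0.01), the step is downward, and (optionally) the
post-step level is within 3σ of the supplied background.

`compute_msd()` is the time-averaged MSD over all ordered pairs;
`estimate_D()` fits lags 1–4 by ordinary least squares with a free
intercept by default — localization noise offsets the MSD by a constant,
and the free intercept absorbs it; `through_origin = TRUE` gives the pure
`MSD = 4Dt` form. Negative slopes are reported as-is with a flag.

Validation geometry matters. Per-track medians of the lag-1–4 OLS slope
are biased low on short tracks (the slope distribution is right-skewed),
and reflecting boundaries depress apparent D for tracks near the wall, so
the package's standard recovery conditions use 60-frame movies, a ≥30-frame
track filter, and cells large enough that the lag-4 RMS displacement is
well below the cap radius: 5 × 2 µm at D = 0.01, 12 × 6 µm at D = 0.1, and
22 × 10 µm at D = 1 µm²/s (the last two are estimator-validation
geometries, not physiological cells). Under these conditions the median
recovered D is within 15 % of truth for all three decades, and 0.1 µm radius
confinement in a realistic 3 × 1 µm cell depresses the estimate more than
three-fold — the synthetic analogue of the mobile-vs-tethered contrast the
measurements were designed to detect. Emitter densities are kept low
(3–6 per cell) because two molecules within one fit window merge into the
brighter candidate and fragment tracks; this is a property of the detector,
visible in the logged drop counts, not silent data loss.

## Cluster statistics

`relative_intensity()` is `max / mean` of the background-corrected in-cell
intensity: exactly 1 for a homogeneous cell, rising with clustering.

Cluster delineation is not prescribed by the measurements it serves, so
`segment_clusters()` makes its rule explicit: pixels above
`median + 3·MAD` of the background, 8-connected components, components
smaller than 4 px dropped. All three numbers are arguments, never silent
defaults. Connected-component labeling is an in-package iterative
min-propagation labeler because the package needs 8-connectivity
(`EBImage::bwlabel` is 4-connected).

`co_cluster_fraction()` scores each channel-A cluster by the pixels it
shares with the channel-B label map; ≥3 shared pixels counts as
co-clustered. `random_null_overlap()` asks how often *randomly placed*
clusters of the same size and count would meet that criterion: centers
uniform over the mask, discs rasterized, 1000 seeded replicates, reporting
the percentage sharing fewer than 3 pixels. "Similar density" is
parameterized (counts, radius, mask) because the quantity is extremely
density-sensitive: in a 3 × 1 µm mask at 96 nm/px (~300 px), ten
radius-2-px discs cover ~40 % of the cell and the mean percentage sharing
<3 px is only ~45 %; the >95 % regime quoted for free fluorophores holds
at substantially lower effective density (larger masks at finer sampling
and/or fewer, smaller spots). The package reports whatever the stated
configuration yields.

For coupled-vs-uncoupled validation, coupled scenes (`channel_coupling = 1`)
are pushed through the full render → segment → overlap path (they score
≥90 % co-clustering), while uncoupled scenes are compared with the null on
their ground-truth cluster centers using the null's own disc statistic —
an apples-to-apples placement comparison with no segmentation confound.

`colocalization_ratio()` classifies pixels as yellow (above both channel
thresholds), red or green (above one); the ratio is
`yellow / (yellow + red + green)`. Thresholds default to per-channel Otsu
levels with manual override.

`estimate_channel_alignment()` solves the 2D similarity transform
(translation, proper rotation, one scale) in closed form from matched bead
coordinates (SVD of the cross-covariance, reflection excluded), with
bilinear resampling of channel B into the channel-A frame. It agrees with
`vegan::procrustes` to machine precision and recovers noiseless synthetic
transforms to 1e−6. Axial (z) shifts are out of scope: alignment is 2D.

## Axial profiles

`binarize_and_clean()` thresholds at a user-chosen intensity and applies a
3 × 3 majority (binary median) filter with edge replication — replication
rather than zero padding so a constant image stays constant. Poles are the
maximally separated pixel pair of a connected region (`find_poles()`),
searched exactly (convex-hull-accelerated for large regions), with a
deterministic lexicographic tie-break. On symmetric rasterized cells two
diagonal diameters can tie; the tie-break picks one reproducibly.

`extract_axial_profile()` samples the image by bilinear interpolation
along 11 lines parallel to the pole axis. The line offsets are uniformly
spaced and symmetric about the axis; spacing defaults to
`width / 10` (width estimated from the region mask) so the lines span the
cell. The 11 profiles are averaged and resampled to 101 positions covering
0–100 % of the pole separation. The "0–100" normalization is read as
*positional* (enabling cross-cell comparison); an optional
`normalize_intensity` flag additionally min–max scales the intensity to
0–100, since the phrase admits either reading. `cell_length()` is the pole
separation times the pixel size.

`distribution_stats()` condenses a profile into a septal index (mean over
the central 20 % of positions ÷ overall mean) and a polar index (mean over
the two outer 10 % windows ÷ overall mean); both are exactly 1 for a flat
profile. The window widths are arguments.

## Validation summary

The test suite builds every fixture in code and checks, among others:

* free-motion steps and ensemble MSD against `4Dkt`; photon statistics
  (variance = mean + read-noise²) on flat fields; bit-exact determinism;
* `compute_msd` against an explicit double loop, `find_poles` against the
  all-pairs maximum, linking against exhaustive assignment;
* end-to-end D recovery and confined-vs-free discrimination
  (Mann–Whitney, α = 0.01);
* FRAP mobile-fraction recovery across mixing ratios;
* co-clustering discrimination and the random-placement null, including
  the density sensitivity discussed above;
* exact recovery of synthetic similarity transforms.

Problem sizes (tens of movies of 60 frames, thousands of Monte-Carlo
replicates) were chosen as the smallest that keep Monte-Carlo error
comfortably inside each validation band.

## Known limitations

* The single-exponential FRAP model is a summary, not a reaction–diffusion
  fit; its mobile fraction is mildly biased for intermediate mixtures.
* Greedy linking swaps identities when unrelated molecules approach within
  one frame displacement; densities should be kept low, as in the
  validation scenes.
* The MSD estimator reports apparent D; in small cells it is depressed by
  the boundary, which is physical confinement, not an implementation
  error.
* Straight pole-to-pole profiling is inappropriate for strongly curved or
  branched cells; a medial-axis variant is a possible extension.
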