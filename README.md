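# bactoscope

Quantification toolkit for live-cell fluorescence imaging of bacterial
membrane proteins, written for the kind of study that asks whether
engaging outer-membrane proteins (for example with a colicin) restricts
the mobility of inner-membrane partners such as the Tol-Pal complex and
reorganizes them into clusters.

It implements, as tested reusable functions:

* **FRAP double normalization and kinetics** — per-frame background
  subtraction, whole-cell acquisition-bleaching correction and pre-bleach
  scaling (`double_normalize()`), curve averaging across cells, and a
  single-exponential fit `I(t) = I0 + A(1 − e^(−kt))` whose mobile
  fraction is `A / (1 − I0)` (`fit_recovery()`).
* **Single-particle tracking** — sub-pixel localization by 2D elliptical
  Gaussian fitting (`detect_and_fit()`), greedy frame-by-frame
  nearest-neighbour linking (`link_frame_by_frame()`), single-bleach-step
  trace selection (`single_bleach_step_filter()`), time-averaged MSD
  (`compute_msd()`), and diffusion coefficients from a linear fit to the
  first four MSD points following `MSD(t) = 4Dt` (`estimate_D()`,
  `diffusion_coefficients()`).
* **Cluster and two-channel statistics** — the max/mean *relative
  intensity* heterogeneity index (exactly 1 for a homogeneous cell), the
  ≥3-shared-pixel co-clustering percentage with a seeded Monte-Carlo
  random-placement null, the yellow-pixel colocalization ratio, and
  closed-form bead-based channel alignment (shift + rotation + scale).
* **Axial profiling** — threshold + binary-median cleanup, poles as the
  maximally separated pixel pair of a region, 11 offset line profiles
  averaged and resampled to 0–100 % of cell length, and septal/polar
  distribution indices.
* **A synthetic microscopy generator** — spherocylindrical cells with
  uniform / clustered / septal / polar emitter layouts, Brownian or
  confined motion with reflecting boundaries, Gaussian PSF, Poisson shot
  noise, read noise and single-step photobleaching — so every estimator
  above is validated against exact ground truth.

See the vignette
(`vignettes/quantifying-membrane-protein-reorganization.Rmd`) for the
models, defaults and design choices.

## Worked example

```r
library(bactoscope)

## simulate a single-molecule movie and recover the diffusion coefficient
geom  <- cell_geometry(length_um = 12, radius_um = 3)   # validation geometry
scene <- scene_spec(geom,
                    emitter_distribution("uniform", n_emitters = 5),
                    motion_model(d_um2_s = 0.1, frame_interval_s = 0.033),
                    camera_model(photons_per_frame = 3000,
                                 background_level = 10, seed = 7),
                    n_frames = 60)
movie  <- render_movie(scene)
locs   <- detect_movie(movie$frames)
tracks <- link_frame_by_frame(locs, max_disp_px = 5)
dcoef  <- diffusion_coefficients(tracks, pixel_size_um = 0.096,
                                 frame_interval_s = 0.033)
median(dcoef$d_um2_s[dcoef$n_frames >= 30])

## a half-mobile FRAP experiment
frap_scene <- scene_spec(cell_geometry(5, 0.5, pixel_size_um = 0.05),
                         emitter_distribution("uniform", 250),
                         motion_model(d_um2_s = 0.1),
                         camera_model(photons_per_frame = 2000,
                                      background_level = 10, seed = 11),
                         image_shape = c(64, 140))
sim <- simulate_frap_series(frap_scene, roi_spec("bleach", 20, 18, 50, 30),
                            mobile_fraction = 0.5)
fit_recovery(double_normalize(sim$series))

## heterogeneity index of a perfectly homogeneous cell
mask <- render_cell_mask(cell_geometry(3, 0.5), c(64, 64))
img  <- matrix(0, 64, 64); img[mask] <- 100
relative_intensity(img, mask)$value
```

This prints:

```
279 localizations -> 18 trajectories; median D = 0.087 um^2/s
<recovery_fit> mobile fraction 0.425, rate 0.03125 /s (t1/2 22.2 s), I0 0.142, rms 4.48e-02
relative intensity of a homogeneous cell: 1
```

The recovered median D (0.087 µm²/s for a true 0.1) reflects the mild
short-track and boundary bias discussed in the vignette; the FRAP mobile
fraction 0.425 estimates the true 0.5 from a single simulated cell; the
relative intensity of a uniform cell is exactly 1.

A thin command-line front end is available for shell pipelines
(`cli_dispatch()`, wrapped by `inst/cli/bactoscope`): subcommands
`simulate`, `track`, `frap`, `cluster`, `profile`, each writing CSV/TIFF
outputs.

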