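---
title: "synaptomap: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{synaptomap: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

synaptomap quantifies how membrane proteins move on neuronal dendrites and
how they organize at synapses, from three kinds of raw data: sparse
single-molecule tracking movies (uPAINT), dense blink localization tables
(dSTORM), and fluorescence recovery after photobleaching (FRAP) traces.
This vignette explains the models behind every stage, the tunable
parameters and their defaults, the numerical choices made where the
methodology leaves latitude, and what the synthetic-data generator does and
does not emulate.

Units are micrometres and seconds throughout, with one deliberate
exception: FRAP rates are expressed in min⁻¹ at the reporting boundary,
matching how such rates are conventionally quoted. Images are indexed
0-based and row-major in the stored arrays; the continuous position of the
centre of pixel (i, j) is ((j + 0.5)·px, (i + 0.5)·px) with x rightward and
y downward, which pins down every sub-pixel statement in the package.

## Spot detection and localization

Diffraction-limited emitters are detected per frame with an undecimated
à-trous wavelet transform using the B3-spline kernel [1,4,6,4,1]/16. Pixel
noise concentrates in the first detail plane; spots of roughly 2–4 px
extent concentrate in the second. The detector thresholds the level-2
plane at `k` times a robust estimate of the image noise, takes connected
components, and emits one candidate per component at its intensity-weighted
centroid.

Two numerical choices matter here:

- **Noise estimate.** The noise sd is 1.4826·MAD of the *first* detail
  plane, divided by 0.8908 (the fraction of white-noise sd that plane
  passes for this kernel). Estimating from the noise-dominated first plane
  and thresholding the signal-dominated second plane is what makes the
  detector quiet on blank frames: the second plane attenuates white noise
  about five-fold, so a threshold calibrated to the image noise sits many
  plane-2 noise sd above the background. With default `k = 2`, 100 blank
  Poisson frames yield zero candidates in the test suite.
- **Count maps.** For super-resolved localization histograms (domain
  detection) the MAD collapses to zero because most pixels are empty; there
  the noise estimate is floored by the plain sd of the first detail plane.
  This keeps sparse uniform maps cluster-free while leaving dense domains
  (hundreds of localizations over tens of nm) far above threshold.

Candidates are refined by least-squares fitting of a pixel-integrated
isotropic 2D Gaussian (total photons, x, y, σ, offset) on a 7×7 px window
(`fit_window`). The integrated model — products of Gaussian CDF differences
per axis — matches exactly how the renderer deposits photons, so noiseless
fits recover positions to machine precision and the estimator carries no
binning bias. Fits that fail to converge, or whose σ leaves
[0.5, 3]×`psf_sigma`, are dropped; edge-clipped windows are fitted on the
available pixels and flagged. Watershed splitting of merged components is
not applied: at uPAINT labelling densities merges are rare, and the sigma
sanity range rejects most of the remainder.

The pointing accuracy σ_xy is the pooled per-axis sd of repeated
localizations of immobile emitters (groups of more than 10 points, the
long-trajectory criterion), and the spatial resolution uses the empirical
convention FWHM = 2.3·σ_xy. That FWHM (default 0.054 µm) feeds the
slow-mobility threshold below.

Lateral drift is removed with fiducial bead tracks: per-frame offsets are
the mean bead displacement from the first frame, smoothed with a 10-frame
running mean (shrinking at the edges), anchored to exactly (0, 0) at the
reference frame. A correlation mode (block-wise 2D-histogram
cross-correlation with parabolic peak interpolation) covers acquisitions
where stable autofluorescent structures stand in for beads; the fiducial
path is the primary, precision-tested one. Dual-colour registration fits a
closed-form least-squares similarity transform (translation + rotation +
scale) to ≥3 matched bead pairs; a full affine is available and refuses
collinear beads.

## Trajectory linking

Frame-to-frame linking is a global one-to-one assignment between
consecutive frames minimizing total squared displacement, with candidate
pairs capped at `d_max` and a fixed cost `d_max²` per unmatched detection
(birth/death). The default `d_max = sqrt(4·D_max·Δt)` with
D_max = 5 µm²/s is the step a molecule at the fastest plausible membrane
diffusion would take in one frame. The objective is solved exactly by an
O(n³) Hungarian algorithm (potentials + shortest augmenting path) on the
standard augmented square matrix; a seeded simulated-annealing solver with
geometric cooling optimizes the same objective and is cross-checked against
the exact solver in the tests — the assignment solver is the default
because it is deterministic and provably optimal.

Gap closing then joins trajectory ends to starts up to `max_gap` skipped
frames (default 2, for blinking), shortest gaps first, within a cap
`d_max·sqrt(gap)` that widens with the diffusion scale of the gap. Each
detection belongs to at most one trajectory; trajectories shorter than two
points are discarded and counted as singletons, so detections are conserved
exactly. No motion-model prediction (Kalman) and no merge/split events are
attempted.

## Mobility analysis

The MSD of a trajectory at lag nΔt averages the squared displacement over
all overlapping ordered pairs n frames apart — the lower-variance
convention. The instantaneous diffusion coefficient is slope/4 of an
unweighted least-squares line through the first `n_fit = 4` lag points with
a free intercept; the intercept absorbs the localization-noise offset
(4σ_xy²) so it does not bias the slope. Trajectories must therefore have at
least five points. Estimates are floored at `d_floor = 10⁻⁵ µm²/s` so that
negative noise slopes remain representable on log axes.

A trajectory is *slow* when D falls below

D_threshold = FWHM² / (4 · n_fit · Δt),

the diffusion coefficient at which a molecule explores an area the size of
the resolution limit during the fitting window. At the conventional inputs
(0.054 µm, 4 points, 20 ms) this evaluates to 9.11×10⁻³ µm²/s, commonly
rounded to ~0.01; published statements of ~0.0093 arise from rounding the
inputs before evaluating the formula. Semi-log histograms of D use fixed
0.2-decade bins.

Confinement is quantified by fitting the pooled MSD of slow trajectories
with the one-phase association curve MSD(t) = P·(1 − exp(−kt)). For a
molecule exploring a disk of radius R uniformly, the MSD plateau is
E|X−Y|² = R², so the reported confinement diameter is 2√P — the disk
convention adopted here because the confining compartment (a synaptic
nanodomain) is approximately isotropic. Fits are started from the curve's
own scales (P at the MSD maximum, k from the initial slope over P), bounded
to non-negative parameters with P ≤ 20× the MSD maximum, and flagged
*unconfined* when the plateau is not approached inside the fitted range
(k·t_max < 0.2) — a straight-line MSD lands there by construction. In a
simulation of reflected Brownian motion inside a 60-nm disk the fitted
diameter is 120 nm within a few percent, confirming the convention's
calibration.

The explored membrane area rasterizes all localizations on a grid of
FWHM/2 (half the resolution, the finest scale at which occupancy is
meaningful) and counts occupied cells; a stationary molecule therefore
reports one cell's area.

## Synapse-referenced statistics

Synapses are segmented from the postsynaptic marker channel (a Homer1c-like
fusion) with the same wavelet detector (level 2, `k = 2`), removing regions
below `min_area = 0.02 µm²` — smaller than any postsynaptic density, large
enough to reject single-pixel noise. A localization is synaptic iff it
falls on a labelled mask pixel; out-of-bounds positions count as
extrasynaptic and are flagged.

The sorting metrics follow their operational definitions: the percentage of
synapses containing the target uses a ≥10-detection criterion
(`min_detections`); synaptic coverage rasterizes synaptic detections at
FWHM/2 (consistent with the explored-area raster) and reports occupied over
total synaptic area; the percentage of synaptic detections is a simple
count ratio. Synaptic enrichment is computed per unit area — synaptic
detection density over extrasynaptic density on the cell footprint minus
the synapse regions — rather than from raw counts, because only a density
ratio is invariant to how much shaft membrane the field of view happens to
contain. The footprint defaults to the whole image and accepts a
low-threshold marker mask (`cell_mask`) when the cell covers only part of
the field. A uniform localization field gives enrichment 1 for any region
geometry, which the tests assert.

Dispersion pools the distances from each synaptic detection to its
synapse's centroid; detection density maps count neighbours within
`density_radius = 0.4 µm` of each localization (the focal point excluded,
so an isolated point reports zero), computed with a cell-list so large
tables stay linear. Treatment time courses divide per-interval trajectory
counts by the pre-treatment baseline interval.

## Nanodomains

Super-resolved maps are count histograms at `map_pixel = 20 nm`, matching
the lateral resolution of dSTORM on cultured neurons; the pixel sum equals
the localization count. Domains are the wavelet clusters of the map (with
the sd-floored noise estimate above and `min_area = 0.002 µm²`), tagged
synaptic when their centroid lies on a synapse region.

Domain size is the Gaussian FWHM = 2√(2 ln 2)·σ. Isotropic fits use the
pixel-integrated Gaussian, so histogram binning does not inflate σ;
anisotropic fits (σ_x, σ_y plus rotation, initialized from the intensity
moments' principal axes) sample at pixel centres and remove the binning
variance px²/12 by Sheppard's correction, reporting the mean of the two
axis FWHMs as the single per-cluster length. The fit window extends well
beyond the bright core (twice the cluster's equivalent radius) because a
truncated window biases σ low. Goodness is judged by Pearson χ² per pixel
against the fitted intensities — ≈1 when residuals are counting noise,
inflated when the shape is wrong (a uniform disk is flagged at χ² ≈ 3) —
which, unlike R², does not degrade at low counts.

Trans-synaptic pairing matches domain centres across registered channels by
minimizing the total centre-to-centre distance with a fixed penalty per
unmatched domain, so pairs form only within `pair_distance = 0.2 µm` (a
synapse-scale cap; the apposition criterion itself is a package
convention). The optimal matching reuses the assignment solver rather than
greedy mutual nearest neighbours: the two coincide on unambiguous
geometries, and on ambiguous ones the optimal matching is the defensible,
oracle-checkable choice.

## FRAP

Recovery of a bleached spot of radius r follows the two-component
diffusion–reaction model

f(t) = φ·[1 − erf(1/(2·√(k_diff·t)))] + (1 − φ)·[1 − exp(−k_reac·t)],

where φ is the freely diffusing fraction, k_diff = D/r² (min⁻¹) its
characteristic diffusive rate, and k_reac the turnover rate of the bound
pool. The erf argument 1/(2√(k_diff·t)) is the only form with f(0) = 0 and
f(∞) = 1, and both limits plus monotonicity are property-tested over 10⁴
random parameter draws. k_diff is never fitted: D is taken from the fastest
tracked molecules (default 0.1 µm²/s) and r from the bleach geometry
(default 0.5 µm), leaving a two-parameter fit over (φ, k_reac) with bounds
φ ∈ [0, 1], k_reac ≥ 0. Because short traces exhibit a shallow trade-off
between φ and k_reac, the optimizer runs from five seeded starts (one
central, four random over φ and log-k_reac) and keeps the lowest residual.
When the bound pool vanishes (φ → 1), k_reac no longer moves the
residuals; the fit flags this by perturbing k_reac and checking the
residual response. The synaptic enrichment is reported at full precision as
1/φ — total (bound + free) over free molecules.

Raw traces are normalized by subtracting the first post-bleach value and
dividing by the bleach depth relative to the mean of ≥3 pre-bleach points;
an unbleached control trace, when supplied, is divided out first (after
normalization to its own baseline) to correct observational photobleaching.

## The synthetic-data generator

The simulator provides ground truth for every stage:

- **Tracking.** Molecules perform 2D Brownian motion (per-axis step
  variance 2DΔt) on a rectangular membrane patch with *reflecting*
  boundaries — an oblique-illumination field of view loses molecules to
  neither wrap-around nor absorption. A free molecule inside a synapse disk
  is trapped with probability 1 − exp(−k_on·Δt) per frame, diffuses while
  trapped with D_trap confined to the disk (radial reflection), and is
  released with probability 1 − exp(−k_off·Δt); trapping is memoryless and
  gated purely on geometric overlap, the simplest mechanism that produces
  the observed two-peak diffusion distribution. Defaults mirror the
  experimental regime: Δt = 20 ms, D_free 0.1–0.5 µm²/s, a slow synaptic
  pool near 0.005 µm²/s. Trapping kinetics are not constrained by
  measurement; the defaults k_on = 10 s⁻¹, k_off = 1 s⁻¹ give a mean
  trapped dwell of 1 s, the order of reported synaptic dwell times, and are
  simulator knobs, not estimates.
- **Rendering.** Emitters deposit pixel-integrated Gaussian PSFs
  (σ = 0.1 µm) with Poisson photon noise, constant background and Gaussian
  read noise; a static marker channel renders synapse disks as bright
  Gaussian puncta. Bleaching is single-step; there is no blinking
  photophysics in the movie renderer and no 3D.
- **dSTORM tables.** Molecule positions scatter normally around nanodomain
  subcentres plus a uniform shaft population; each molecule emits a
  geometric number of blinks jittered by the localization precision, so
  localization variance adds as σ_domain² + σ_loc² — the property the
  sizing tests exploit.
- **FRAP.** Traces are the model plus i.i.d. Gaussian noise.

Everything is reproducible bit-exactly: one global seed, and every
stochastic stage draws from a generator seeded by (seed, stage name), so
stages can be re-run in isolation. What the generator does *not* emulate —
dye photophysics beyond geometric blinking, anisotropic or depth-dependent
PSFs, vesicular/directed transport, marker bleed-through, detector
fixed-pattern noise — bounds what green tests prove: they validate the
estimators and conventions against data satisfying the models'
assumptions, not the instrument.

## Problem sizes and runtime

The test suite runs at desk scale by design: 10⁴ trajectories of 20 frames
for the diffusion-estimator calibration, 150 confined molecules over 150
frames for the confinement check, 800–4000 localizations per rendered
nanodomain, 10⁴ random parameter draws for the FRAP identities, and movies
of 30–200 frames at 48–64 px for the detection and pipeline tests. These
sizes hold every Monte-Carlo tolerance used (10% on medians, 5% on FWHM
recovery) with margin while keeping the whole suite around a minute.

## Known limitations

- 2D only: no astigmatic z-localization, no 3D masks.
- Single-emitter fitting: overlapping emitters at dSTORM densities are
  rejected by the σ range rather than multi-fitted.
- The annealing tracker is a fidelity reference, not the performance path;
  both solvers share one objective, which ignores motion prediction.
- Enrichment depends on the cell-footprint definition when the cell does
  not fill the field; supply `cell_mask` in that case.
- The confinement diameter convention (2√P) assumes isotropic disk-like
  compartments; elongated confinement would need the anisotropic domain
  machinery instead.
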