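---
title: "Models and methods behind tirfsmt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tirfsmt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tirfsmt)
```

## What the package models

`tirfsmt` simulates single-molecule TIRF movies of membrane proteins and
quantifies them the way a single-molecule microscopist would: spot
detection and photon-calibrated intensity measurement, trajectory linking
and diffusion analysis, intensity-based stoichiometry, ALEX-smFRET
dimerization analysis, and image-level metrics (decorrelation resolution,
actin-corral statistics). The simulator and the quantification chain share
one parameterization, so every analysis routine can be validated against
ground truth it did not see.

### Emitter motion and photophysics

Emitters are placed uniformly at the configured surface density and
perform free 2-D Brownian walks: each per-axis step is a standard normal
draw times the mean displacement $\bar d = \sqrt{2 D \Delta t}$, with a
per-species diffusion constant $D$ (µm²/s) and the frame interval
$\Delta t$. On-times are single-exponential with mean $\tau$; in PAINT
mode binding events start uniformly in time and the walks are frozen
($D = 0$). A size-$k$ oligomer emits $k$ independent monomer-equivalent
photon streams, i.e. twice the monomer mean for dimers, with all
stochasticity applied downstream in the camera model so that photon shot
noise is not double counted.

Axial positions emulate membrane topography: at node frames (every
`node_spacing` frames) a position is drawn from
$\mathcal N(z_0, \sigma_z)$ and intermediate frames are
spline-interpolated, which produces smooth axial trajectories rather than
frame-to-frame axial white noise. The evanescent excitation decays as
$\exp(-(z - z_0)/d_p)$ with penetration depth $d_p$, normalized so an
emitter at the reference position $z_0$ emits exactly the configured
photon count. The exponential can instead be evaluated in its raw
unnormalized form (`literal_formula = TRUE`) for users who prefer the
bare $e^{z/d_p}$ convention; the default normalized form is what
guarantees a user-defined single-emitter intensity at a specified axial
position. The node spacing is exposed as a frame count because the
literature statement of "node distance $2/\bar d$" is dimensionally
ambiguous; a sensible default is `max(2, round(2 / d_bar_um))`.

### Optics and camera

Spots are rendered as symmetric 2-D Gaussians with
$\sigma_\mathrm{PSF} = 1.3\, d_\mathrm{Abbe} / 2.355
= 0.276\, \lambda_\mathrm{em} / \mathrm{NA}$, where the empirical
prefactor 1.3 absorbs the effective numerical aperture and finite
resolution of a real objective. Rendering happens on a supersampled grid
(5 nm pitch by default), truncated at `truncation_radius` (5 σ, losing
< 0.01 % of the volume), then block-summed to camera pixels; background
is added per camera pixel. A Gaussian illumination profile scales each
emitter by its lateral position (normalized to mean 1 over the field);
the flat-field profile is identically 1, which is precisely why
flat-field illumination yields narrower intensity histograms — one of the
properties the test suite asserts.

The EMCCD model converts photons to photoelectrons with quantum
efficiency QE and draws electrons with mean $\mu_e$ and variance
$F^2 \mu_e$, implemented as $F^2 \cdot \mathrm{Poisson}(\mu_e / F^2)$
with excess-noise factor $F = \sqrt 2$. This mean-preserving inflation
reproduces the variance/mean ratio of 2 that EM gain registers exhibit
without simulating the gain cascade itself (a Gamma-based register model
would also work but adds a parameter the analyses never see). Counts are
electrons × ecf + offset + Gaussian read noise, rounded and clipped to
the 16-bit range. The excess draw is applied in the electron domain,
after QE conversion.

Trajectories diffuse unbounded and simply render nothing outside the
field, matching a crop of a larger membrane; there is no reflecting
boundary. Coordinates are continuous, in µm, origin at the top-left pixel
corner, pixel (0,0) spanning $[0, \mathrm{pixel})^2$.

With a Gaussian profile and `bleach_exponent` α > 1, the per-frame bleach
hazard is proportional to (local excitation)$^\alpha$, which reproduces
qualitatively the stronger apparent photobleaching under the
over-illuminated center of a single-beam profile. The default α = 1 is
the plain exponential model.

## The quantification chain

**Detection** applies a 3×3 median prefilter, a difference-of-Gaussian
band-pass with $\sigma_1$ = half the expected spot radius and
$\sigma_2 = 1.6 \sigma_1$, 3×3 local-maximum selection above the quality
threshold, and subpixel refinement by least-squares fitting of a
fixed-width 2-D Gaussian (free position, amplitude and offset). Fits that
wander more than 2 px or fail to converge are discarded; localizations
whose window clips the border are flagged `edge` and excluded by default.

**Intensity measurement** uses a Gaussian-weighted sum
$\hat N = \sum_i w_i (x_i - b) / \sum_i w_i^2$ with $w_i$ the
pixel-integrated unit-volume PSF, so a perfect spot of volume $N$ returns
$N$ photons exactly. The background $b$ comes from an annulus (3–5 σ) as
the mean of pixels no more than 4 MAD above their median. A plain median
is biased low by a few tenths of a photon on the skewed, lumpy EMCCD
photon distribution at realistic backgrounds, which the weighted sum
amplifies into a 2–4 % intensity bias; the upward-clipped mean keeps the
median's robustness to bright neighbours while being unbiased to within
0.03 photons (verified by Monte Carlo in the test suite). The
signal-to-noise ratio is $20 \log_{10}$(peak amplitude / σ~background~)
in dB, consistent with the ~21 dB figures typical of a few-hundred-photon
membrane-protein spot. `intensity_measurement_variance()` propagates the
full camera model (shot × excess noise, read noise, background
subtraction) through this estimator in closed form.

**Linking** is frame-to-frame greedy assignment on globally
distance-sorted candidate pairs capped at `max_link` (500 nm default),
with greedy gap closing across up to 2 missed frames within 500 nm. The
full Jaqaman cost-matrix graph is intentionally not reproduced; for the
sparse fields this package targets, the greedy assignment agrees with the
optimal one except in rare near-tie configurations, and it is
permutation-invariant with respect to input order (tested).

**Immobile filtering** is DBSCAN over all pooled localizations with
ε = 100 nm. "Observation probability 50 %" is read as: a cluster is
immobile when it has members in at least half the frames it spans. Two
implementation choices make this reading work on realistic data: the
core-point threshold defaults to 10 (an immobile emitter keeps nearly all
its localizations inside ε, while a diffuser at membrane-typical
D ≈ 0.1 µm²/s spends only a handful of frames there), and an immobile
cluster must additionally stay within ε of its centroid, because DBSCAN
happily chains a slow diffuser's footsteps into one long cluster that
would otherwise pass the frame-coverage test.

**Diffusion** uses the time-averaged MSD over all pairs per lag and an
ordinary least-squares line through the first 5 MSD points, $D$ = slope/4
for 2-D diffusion; the intercept is retained as the localization-error
offset and never forced through zero.

**Stoichiometry** fits a sum of $k$ unnormalized Gaussians to histogram
bin counts by nonlinear least squares (matching the histogram-fitting
practice of the field, not sample-level maximum likelihood), with
Freedman–Diaconis bin widths by default, k-means initialization and
parameter standard errors from the fit covariance. Peak means and widths
are left unconstrained by default (an optional µ₂ = 2 µ₁ constraint
exists); the dimer level is the high-peak area share
$A_2 \sigma_2 / (A_1 \sigma_1 + A_2 \sigma_2)$. Threshold classification
assigns values exactly at the threshold to the low class.

**ALEX-smFRET** corrections follow the standard accurate-FRET chain: raw
efficiency from the sensitized and donor channels; leakage $l$ estimated
as the mean sensitized/donor ratio of donor-only records; the direct
excitation term subtracted as `dir_coeff` × the directly excited acceptor
intensity (the proportional form standard in ALEX analysis — a constant
offset mode is available since the original tuning to "1 %" does not
state the functional form); the γ factor
$\varphi_A \eta_A / (\varphi_D \eta_D)$ mapping proximity ratios to
accurate efficiencies; and the efficiency–distance inversion
$r = R_0 ((1-E)/E)^{1/6}$ with the Cy3B/ATTO 643 Förster radius of
6.441 nm as default. Corrected sensitized intensities may be negative and
are kept — clipping them would bias the zero-FRET population that the
bimodal efficiency fit relies on to separate real FRET from chance
co-localization.

Dimer counting corrects for stochastic dual-color labeling: with labeling
ratio $r_l$, a mixed-label dimer is observable with probability
$2 r_l (1 - r_l)$ (a factor-2 correction at equimolar labeling), giving
$N_d = n_d^{12*} / c_l$ with $c_l = r_l(1 - r_l)$, monomer counts
corrected for label-homozygous dimers, and the closed form
$f_\mathrm{rel}^D = n_d^{12*} / (c_l (n_1^* + n_2^*))$, whose equality
with the explicit count composition is asserted to $10^{-12}$ on every
call. Sensitized-FRET detections are gated on the corrected sensitized
intensity exceeding 5× a robust noise scale estimated from the donor-only
records, which is what keeps the dimer estimate near zero for pure
monomers at densities where naive co-localization produces large
false-positive fractions.

**Decorrelation resolution** apodizes the image with a raised-cosine
taper (20 px), and exploits that the Pearson correlation in Fourier space
between $I(k)$ and its unit-modulus normalization masked at radius $r$
reduces to cumulative $|I(k)|$ sums, so all 50 radii cost one sort. The
analysis repeats after 10 log-spaced Gaussian high-pass filters; each
curve contributes its highest (lightly smoothed) interior local maximum,
no peak if it has none, and the cutoff $k_c$ is the maximum peak
position, with resolution $2 \cdot \mathrm{pixel} / k_c$. Constant images
raise a "featureless input" error.

**Corral statistics** label 4-connected foreground components (corral
interiors; skeletonized meshworks should be inverted first, with IsoData
as the default automatic threshold and Otsu as the alternative), exclude
border-touching components, filter at 0.25 µm² maximum area, and report
areas plus equivalent-circle diameters.

## What the simulator does and does not emulate

It reproduces the statistics the analyses are sensitive to: Brownian
displacement distributions, exponential survival, evanescent intensity
modulation with membrane-ripple axial noise, diffraction-limited Gaussian
spots on a fine grid, illumination-profile heterogeneity and EMCCD
shot/excess/read noise. It does not model the EM gain-register cascade,
pixel-dependent sCMOS noise maps, 3-D PSF shapes, SIM raw patterns,
structured backgrounds (cell autofluorescence, endosomal debris) or
dye-state kinetics (blinking, spectral shifts). Passing the
parameter-recovery suite therefore demonstrates correctness of the
estimators under the stated noise model, not robustness to every artifact
of real cell data.

The ALEX generator (`simulate_alex_experiment`) works at the
localization level: channel intensities carry shot noise with the EMCCD
excess factor and positions carry Gaussian localization noise, but
frames are not re-rendered and re-detected; the rendered-image route is
exercised end-to-end by the stoichiometry recovery instead. Its
generative model places a fraction `f_true` of receptors in dimers,
labels every receptor color 1 with probability `r_l`, and lets
label-homozygous dimers appear as a single spot in their channel — under
which the labeling-corrected estimator carries a small known positive
bias (≈ +1 point at f = 0.2, r_l = 0.5), well inside the tolerances used.

## Numerical choices and degenerate inputs

* Mixture fits reject histograms without spread and report a diagnostic
  carrying the initial values on non-convergence. Fits are invariant to
  the histogram bin origin within quoted standard errors (tested).
* The acceptor-population filter only removes a low-intensity component
  when its area share is below 5 % *and* it is separated from the main
  peak by more than twice the summed widths; otherwise everything is
  retained. Values are cut at the crossing point of the two components.
* Transform fits require 3 (affine) / 4 (projective) pairs and raise a
  rank error on collinear beads; the projective fit uses the normalized
  direct linear transform.
* Trajectory counts are `round(density × area)`; positions are drawn
  before the categorical oligomer sizes because the first uniforms after
  integer seeding are the least well decorrelated across nearby seeds,
  and a uniform position is insensitive to that while a categorical draw
  is not.
* Empty inputs (no localizations, empty masks, zero density) return
  empty tables rather than errors wherever an empty result is
  scientifically meaningful.

## Problem sizes used in the tests

The recovery suite simulates what a desk check can afford while keeping
each statistic's Monte-Carlo error well below its tolerance: 1000
trajectories for displacement statistics; 10⁵ pixel draws for the camera
noise ratio; four 160×160 px, 50-frame movies (≈ 100 emitters, ≈ 4600
localizations) for the 80/20 monomer/dimer recovery, compared against the
realized (not nominal) dimer fraction of each run; 1000 receptors × 40
ALEX frame pairs for the smFRET recovery; and 256² images for the
decorrelation checks. The full suite runs in about a minute on a laptop
core, and all random inputs are seeded.

## Known limitations

Greedy linking can differ from optimal assignment in dense fields; the
DBSCAN immobility reading is one of several defensible interpretations of
"observation probability"; the dimer-level estimate inherits an upward
contribution from chance emitter overlaps that grows with surface density
(quantified in the tests at the densities used); and absolute
reproduction of published corral-size statistics would require the
original SIM data and trained segmentation classifier, which is why the
corral module is validated on synthetic meshes with known geometry
instead.
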