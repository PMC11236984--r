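# tirfsmt

Simulation and quantification of single-molecule TIRF microscopy
experiments on membrane proteins.

Single-molecule total internal reflection fluorescence (TIRF) imaging is
the workhorse for watching receptors diffuse, dimerize and get
endocytosed in the plasma membrane of live cells. Quantitative
conclusions — "18 % of these receptors are dimers", "dimers diffuse 25 %
slower", "this FRET peak corresponds to an 8.3 nm separation" — rest on
photon-calibrated intensity measurements, corrected smFRET ratios and
diffusion statistics whose estimators are easy to get subtly wrong.
`tirfsmt` provides both sides needed to trust such numbers: a
physically parameterized simulator that generates movies with known
ground truth, and the full quantification chain that is validated
against it.

For microscopists and image-analysis developers, the package covers:

* **Simulation** — emitters at a given surface density performing 2-D
  random walks (per-axis steps $\sqrt{2D\Delta t}\cdot\mathcal N(0,1)$),
  exponential on-times, evanescent-field intensity modulation
  $e^{-(z-z_0)/d_p}$ with spline-smoothed axial ripple, Gaussian PSF with
  $\sigma_\mathrm{PSF}=0.276\,\lambda_\mathrm{em}/\mathrm{NA}$ rendered
  on a 5 nm supersampled grid, flat-field or Gaussian illumination, and
  an EMCCD camera model with excess-noise factor $F=\sqrt2$
  (electron variance $F^2\mu_e$), gain, offset and read noise.
* **Detection & tracking** — median + difference-of-Gaussian detection,
  subpixel Gaussian fitting, Gaussian-weighted intensity measurement in
  photons, greedy nearest-assignment linking with 2-frame/500 nm gap
  closing, DBSCAN immobile-particle filtering (100 nm / 50 %), bead-based
  affine/projective channel registration, and MSD diffusion fits
  ($D=\mathrm{slope}/4$ over the first 5 lags).
* **Stoichiometry** — Gaussian-mixture fits of intensity histograms,
  dimer levels from peak integrals
  $A_2\sigma_2/(A_1\sigma_1+A_2\sigma_2)$, and threshold classification
  (e.g. monomers < 625 < dimers photons).
* **ALEX-smFRET** — donor/acceptor co-localization (150 nm), leakage /
  direct-excitation / γ corrections,
  $E = E_\mathrm{PR}/(\gamma-(\gamma-1)E_\mathrm{PR})$, the
  efficiency–distance inversion $r = R_0((1-E)/E)^{1/6}$, and the
  labeling-ratio-corrected dimer fraction
  $f^D_\mathrm{rel} = n_d^{12*}/(c_l(n_1^*+n_2^*))$ with
  $c_l = r_l(1-r_l)$.
* **Image metrics** — parameter-free resolution estimation by
  decorrelation analysis and corral-size statistics of cortical
  actin meshwork masks.

The methods vignette (`vignettes/tirfsmt-methods.Rmd`) documents every
model, default and numerical choice.

## Worked example

Simulate a partially dimerized, immobile receptor population at
live-cell conditions (400 photons per monomer and frame, 0.12 /µm²,
16×16 µm field, EMCCD noise), detect and measure every spot, and fit the
intensity histogram:

```r
library(tirfsmt)

cfg <- simulation_config(
  imaging  = imaging_config(width_px = 160, height_px = 160,
                            pixel_size = 100, n_frames = 50,
                            frame_interval = 0.025),
  emitter  = emitter_model(mean_photons = 400, density = 0.12,
                           oligomer_fractions = c("1" = 0.8, "2" = 0.2),
                           D_by_size = c("1" = 0, "2" = 0)),
  psf      = psf_model(lambda_em = 680, na = 1.49),
  camera   = camera_model(qe = 0.9, ecf = 12, offset = 100,
                          read_sigma = 6),
  background = 10)

sim  <- run_simulation(cfg, seed = 11)
locs <- detect_stack(sim$stack, quality_threshold = 3)
fit  <- fit_intensity_mixture(locs$intensity, k = 2)
fit
#> 2-component Gaussian mixture (bin width 12.9):
#>   component 1: mean = 401.8 +/- 1.4, sigma = 45.43 +/- 1.4, amplitude = 137.9
#>   component 2: mean = 805.7 +/- 15, sigma = 55.22 +/- 15, amplitude = 13.86
dimer_level_from_integrals(fit)
#> [1] 0.1085
```

The two fitted peaks sit at the simulated monomer and dimer intensities
(400 and 800 photons) to within ~1 %, and the peak-integral dimer level
(10.9 %) matches this run's realized dimer fraction (9.7 % of the 31
emitters drawn — at 31 emitters the 20 % nominal fraction fluctuates).
The same chain on a two-color ALEX-smFRET simulation:

```r
alex <- simulate_alex_experiment(n_receptors = 1000, f_true = 0.2,
                                 r_l = 0.5, E_true = 0.18, seed = 7)
res  <- analyze_alex_experiment(alex)
c(dimer_fraction = res$dimer$f_rel_D, E_peak = res$E_peak,
  distance_nm = distance_from_efficiency(res$E_peak))
#> dimer_fraction         E_peak    distance_nm
#>      0.193          0.180          8.3
```

recovering the simulated dimer fraction (0.2), efficiency (0.18) and the
corresponding 8.3 nm donor–acceptor distance.

A command-line front end is included (`inst/cli/tirfsmt`, installed
under the package's `cli/` directory) with `simulate`, `detect`,
`track`, `register`, `stoich`, `fret`, `decorr` and `corrals`
subcommands; every run logs its parameters and seed and is reproducible
from the emitted config snapshot.

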