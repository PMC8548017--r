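# tdnirs

Time-domain near-infrared spectroscopy (TD-NIRS) measures how a short
laser pulse spreads in time after multiple scattering through tissue. The
shape of the resulting *distribution of times of flight of photons*
(DTOF) separates absorption from scattering, so a time-domain oximeter
can report absolute tissue properties — the absorption coefficient μa and
reduced scattering coefficient μs′ (cm⁻¹) — and from μa at several
wavelengths the concentrations of oxy- and deoxyhemoglobin, total
hemoglobin HbT = HbO₂ + Hb and tissue oxygen saturation
StO₂ = HbO₂ / HbT. `tdnirs` is an R toolkit for this analysis chain and
for the standardized performance protocols (BIP, MEDPHOT, nEUROPt) used
to qualify such instruments, driven entirely by a synthetic instrument
simulator so every stage can be validated against known ground truth.

It is aimed at researchers in diffuse optics who need a tested reference
implementation of the standard measurands, and at anyone building or
assessing a multi-wavelength TCSPC instrument.

## What is implemented

* **Forward model** — time-resolved diffuse reflectance of a homogeneous
  semi-infinite medium, diffusion dipole solution with extrapolated
  boundary condition:

  R(ρ,t) = ½ (4πDv)^(−3/2) t^(−5/2) exp(−μa v t − ρ²/(4Dvt))
  × \[z₀ e^(−z₀²/4Dvt) + (z₀+2z_b) e^(−(z₀+2z_b)²/4Dvt)\],

  with D = 1/(3μs′), z₀ = 1/μs′, z_b = 2AD, v = c/n. A synthetic
  instrument convolves this with a Gaussian IRF (150 ps FWHM, 1–2%
  afterpulse ~1 ns after the peak), scales to a photon budget and draws
  Poisson counts on a 1024 × 9.77 ps TCSPC grid (16 spectral channels,
  674–874 nm).
* **DTOF measurands** — background subtraction, thresholded statistical
  moments N, m1, V, early/late time-window counts, perturbation
  contrasts ΔA_TW = −ln(N_TW/N_TW,0), Δm1 = m1,0 − m1, ΔV = V₀ − V,
  differential nonlinearity ε_DNL, temporal-fluctuation statistics,
  IRF-drift correction and frame rebinning.
* **Optical-property recovery** — bounded nonlinear least squares of the
  IRF-convolved model against a measured DTOF over a percentage fit
  range (85%→1% of maximum, or 75%→3% for blood/in-vivo work).
* **Chromophore analysis** — Beer–Lambert unmixing of μa(λ) into HbO₂,
  Hb and water (bundled extinction table), the noise-reducing two-step
  water subtraction, and the modified Beer–Lambert law with
  time-of-flight pathlengths for concentration *changes*.
* **Depth sensitivity** — first-order Born model of a small absorbing
  inclusion (image-source Green's functions; surface-flux adjoint),
  depth/lateral contrast scans, sensitivity factors MPP = ΔA/Δμa,
  MTSF = Δm1/Δμa, VSF = ΔV/Δμa, cross-validated by a photon-packet
  Monte Carlo oracle (Rcpp).
* **Protocols** — MEDPHOT 32-phantom grid (A1–D8) with linearity and
  coupling reports and the separation-dependent exclusions; nEUROPt scan
  summaries (maximum contrast, depth of maximum, lateral FWHM); affine
  StO₂ comparison fits between oximeters; co-oximetry dilution
  reference.
* **Scenario generators** — the phantom grid, perturbation scans,
  blood–Intralipid deoxygenation cycles and arterial/venous cuff
  occlusions, each emitting its ground truth.

## Worked example

```r
library(tdnirs)

cfg       <- instrument_config()                 # 1024 x 9.77 ps, 16 channels
irf_curve <- synthesize_irf(irf_model(fwhm = 150, afterpulse_fraction = 0.015), cfg)

# simulate one measurement on a B2-like phantom at rho = 3 cm
medium   <- optical_properties(mua = 0.07, musp = 8, n_medium = 1.55)
model    <- diffuse_reflectance_td(bin_centers(cfg), rho = 3, medium)
expected <- expected_dtof(model, irf_curve, total_photons = 1e6)
d        <- sample_dtof(expected, seed = 42, bin_width = cfg$bin_width, rho = 3)

dtof_moments(d, threshold_fraction = 0.01)
#> N = 992657 photons, m1 = 2196.0 ps, V = 335504 ps^2
fit <- fit_optical_properties(d, irf_curve, rho = 3, n_medium = 1.55)
#> mua = 0.0704 cm^-1 (true 0.07), musp = 8.024 cm^-1 (true 8)
```

N is the integrated count above 1% of the peak; m1 includes the ~1 ns
instrument delay. The curve fit recovers both coefficients to well within
the 5% accuracy expected at a ~10 ps time resolution.

Depth sensitivity of the five measurands to a 98 mm³, Δμa = 0.017 cm⁻¹
inclusion moved below the source–detector midpoint:

```r
pert <- perturbation(center = c(1.5, 0, 1.5),
                     volume_mm3 = cylinder_volume_mm3(5, 5), delta_mua = 0.017)
scan <- scan_contrasts(medium, rho = 3, pert, positions = seq(-0.5, 3, 0.1),
                       threshold_fraction = 0.001)
neuropt_summary(scan, NULL, reference_depth = 1.5)
#>   measurand depth_of_max contrast_at_reference
#> 1  dA_early        0.471              5.24e-04
#> 2  dA_total        0.555              1.48e-03
#> 3   dA_late        1.040              4.79e-03
#> 4       dm1        1.238              6.79e-01
#> 5        dV        1.534              4.77e+02
```

The depth of maximum contrast moves deeper with moment order
(ΔA < Δm1 < ΔV) — the reason higher moments and late time windows are
preferred for brain monitoring through superficial layers.

## Vignette

`vignettes/tdnirs-methods.Rmd` describes the models, their assumptions,
the numerical choices (fit ranges, thresholds, trust-region settings,
Monte Carlo geometry) and the known limitations of the synthetic
scenarios.
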