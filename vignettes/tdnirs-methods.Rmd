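---
title: "Models and methods in tdnirs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in tdnirs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdnirs)
```

`tdnirs` implements the data analysis of multi-wavelength time-domain
near-infrared spectroscopy (TD-NIRS): from raw photon time-of-flight
histograms (DTOFs) to absolute optical properties, hemoglobin
concentrations and oxygen saturation, together with the standardized
instrument performance protocols (BIP, MEDPHOT, nEUROPt) and synthetic
scenario generators that make every stage testable against known ground
truth. This vignette records the models, the tunable parameters, the
numerical choices, and what the synthetic validation does and does not
demonstrate.

## Units

Time in ps, lengths in cm, μa and μs′ in cm⁻¹, concentrations in μM,
water as a volume fraction. The speed of light is 0.0299792458 cm/ps;
in-medium speed is `c/n`.

## Forward model

Time-resolved reflectance of a homogeneous semi-infinite medium uses the
diffusion dipole solution under the extrapolated boundary condition: an
isotropic point source at depth `z0 = 1/musp`, mirrored with negative
sign across the plane `z = -zb`, `zb = 2 A D`, `D = 1/(3 musp)`. The
mismatch factor `A` comes from the Groenhuis polynomial approximation of
the internal diffuse reflectance; for matched indices `A = 1`. Two
consequences of this closed form are used as exact test oracles:

* causality — the curve is identically zero for `t <= 0`;
* absorption factorization — `R(t; mua) = R(t; 0) * exp(-mua * v * t)`
  to machine precision, because absorption enters the diffusion Green's
  function only through that exponential.

Assumptions: homogeneous medium, source-detector separations large
enough for diffusion theory (the package is exercised at ρ = 2–4 cm with
μs′ = 5–20 cm⁻¹), no layered structure.

## Synthetic instrument

The instrument model follows a 16-channel polychromator + multi-anode
PMT + TCSPC chain: 1024 time bins of 9.77 ps (12.5 ns repetition
period), 16 spectral channels of 12.5 nm covering 674–874 nm, 0.3 s
frames. The default channel centers are the uniform grid
`680 + 12.5 k` (k = 0..15). Printed center lists for such polychromators
sometimes carry a one-channel irregularity (a 13 nm step near 780 nm);
the uniform grid is used here because it reproduces the operational
bookkeeping — exactly 11 channels inside the 705–830 nm band used for
chromophore estimation. The 12.5 nm bandwidth is metadata only; no
finite-bandwidth extinction correction is applied.

The IRF is a Gaussian main peak (default FWHM 150 ps) plus a broader
Gaussian afterpulse (default 1.5% of the main maximum, 1 ns later),
normalized to unit sum. Expected counts are the discrete convolution of
the model curve with the IRF; noise is independent Poisson per bin. An
optional mean-one per-bin pattern emulates TCSPC differential
nonlinearity for testing the ε_DNL metric. When a *series* of DTOFs is
generated (blood phantom, occlusions), the instrument amplitude is fixed
at the first time point, so the count rate falls when absorption rises —
the intensity information the MBLL method consumes. Single-shot
simulations normalize each DTOF to the requested photon budget instead.

## DTOF measurands

Background is estimated from up to 100 early bins that all lie more than
500 ps before the peak, and clipped subtraction keeps counts
nonnegative. Moments N, m1, V are computed over the contiguous run of
bins around the global maximum exceeding a threshold fraction of it
(default 1%; 0.1% and 2% presets for the solid/liquid perturbation
phantoms). Contiguity avoids picking up afterpulse islands. Bin times
are bin centers; V carries no Sheppard correction (≪ 1 ps² at 9.77 ps
bins).

One subtlety is worth recording: for *repeated-acquisition* statistics
(temporal fluctuations, drift), the integration limits must be fixed
once — on the summed or expected curve — and reused. Re-deriving the
threshold on every noisy DTOF makes the region boundaries jitter by a
few bins and roughly doubles the standard deviation of m1 relative to
the photon-noise floor `sqrt(V/N)`. With fixed limits the simulated
floor sits within ~10% of `sqrt(V/N)` (`dtof_moments(..., bins = )`).

Time-window counts use half-open intervals `[t1, t2)` measured from the
IRF maximum (0.5–1 ns early, 3–4 ns late by default). Contrasts follow
the standard sign conventions: `dA_TW = -ln(N_TW / N_TW0)`,
`dm1 = m1_0 - m1`, `dV = V_0 - V`, with the perturbation-at-infinity
measurement as reference — so a shallow inclusion gives negative dm1/dV
(it removes early photons) and a deep one positive values.

## Optical-property recovery

`fit_optical_properties()` minimizes Poisson-weighted residuals
(`1/max(counts, 1)` weights) between the measured counts and an
amplitude-scaled, IRF-convolved model over the percentage fit range
determined on the measured curve (first crossing of 85% of the maximum
on the rising edge to the last bin at 1% on the tail; 75%/3% for
blood-lipid and in-vivo work, where late-tail contamination matters
more). The amplitude is a nuisance parameter absorbing throughput; it is
profiled out analytically at each iterate, leaving a bounded
two-parameter Levenberg–Marquardt problem (μa in \[0, 1\], μs′ in
\[1, 40\] cm⁻¹, `minpack.lm`, parameter tolerance 1e-8).

Two robustness choices matter. The initial trust-region bound is kept
small (`factor = 1`): with the library default the first step can
overshoot into a shallow local basin at the low-μa/low-μs′ corner and
pin both parameters at their bounds. And if a solution does end on a
bound, the fit restarts once from the mid-range default (0.1, 10) and
keeps the lower-deviance result. With these settings the fit returns to
the same optimum from random initializations across the entire bound
box, and recovers noiseless self-generated data to optimizer tolerance.

## Chromophore analysis

Hemoglobin and water are unmixed from μa(λ) by ordinary least squares of
the Beer–Lambert system `mua(lambda) = sum_c eps_c(lambda) C_c`.
Extinction spectra ship as a plain-text table
(`inst/extdata/extinction_hemoglobin_water.csv`): an approximate
compilation written from the standard literature tabulations of
hemoglobin molar extinction and pure-water absorption, resampled to a
10 nm grid — adequate for simulation and self-consistent analysis, not a
metrological reference (the file header says so). Units are ln-based
cm⁻¹ μM⁻¹ (`molar_log10_to_uM_ln()` converts decadic molar values). No
nonnegativity constraint is imposed by default — commercial oximeters
report slightly negative concentrations in the same situations — but a
Lawson–Hanson NNLS option exists.

Water handling uses the two-step procedure: unmix HbO₂/Hb/water at every
time point, average the water fraction over the measurement (it is
assumed constant), subtract that mean water contribution from every
spectrum, and re-unmix only the two hemoglobins. Solving for fewer
chromophores demonstrably reduces the StO₂ noise in the test suite.
StO₂ is reported as NaN when HbT ≤ 0.1 μM.

The MBLL route converts attenuation changes to concentration changes
with the time-of-flight mean pathlength `L = v (m1 - m1_IRF)`; the IRF
mean time must be subtracted, otherwise the ~1 ns instrument delay
roughly doubles L and halves every recovered change. The baseline m1 is
used by default (a time-varying-m1 variant is available via the matrix
argument of `mbll_changes()`).

## Depth sensitivity: Born model and Monte Carlo oracle

A small absorbing inclusion is modeled to first Born order as a point
defect of strength `delta_mua * V` at the centroid of the submerged part
of its equivalent sphere (centers above the surface contribute only
their submerged cap, so scans that start above the surface begin at
exactly zero contrast). The perturbed curve is

`R_pert(t) = R0(t) - delta_mua * V * v * (G_rho ⊛ G_flux)(t)`,

where `G_rho` is the source-to-inclusion density propagator and
`G_flux` the inclusion-to-detector *surface-flux* (dipole reflectance)
kernel. The flux adjoint is a deliberate choice: with the
density-at-surface convention the predicted ΔA at 1.5 cm depth is ~15%
away from the package's Monte Carlo oracle, while the flux convention
agrees within statistical error — and it makes the unperturbed curve
identical to `diffuse_reflectance_td()`. The semigroup property of the
half-space kernels gives a global check used in the tests: summing
`MPP = dA/dmua` over a 3-D voxel grid reproduces the total mean
pathlength `v m1` within discretization error (~3% at 2.5 mm voxels).

The MC oracle (Rcpp) propagates photon packets in the half space with
isotropic scattering at μs′ (g = 0 similarity), continuous absorption
weighting, Fresnel internal reflection, a 12 ns time cap, and an annular
detector of ±2 mm around ρ. Because the Born model has a *point*
detector, each detected packet's partial pathlength through the
inclusion is evaluated with the inclusion rotated to the packet's exit
azimuth (a replay over the packet's private RNG substream) — exact by
the axial symmetry of the source, and it preserves the annulus's photon
economy. Energy bookkeeping (detected + escaped + absorbed + expired =
launched) closes to summation precision. The totally absorbing PVC
inclusion of the liquid phantom is emulated as Δμa = 1 cm⁻¹ — an
approximation; first-order linearity is *not* claimed there, only the
qualitative scan behavior.

## Protocols

MEDPHOT linearity fits measured-vs-nominal lines within each phantom
subset and reports the mean of `100 |measured - line| / line`
(fitted-line denominator, chosen for symmetry). Coupling is reported as
the raw OLS slope of one measured property against the nominal value of
the other — both axes in cm⁻¹, so the slope is dimensionless and reads
directly as "cm⁻¹ of crosstalk per cm⁻¹ of driver"; conventional
displays scale the μs′→μa direction by 10⁴. Exclusion rules are
data-driven parameters defaulting to the separation-dependent sets
(digits 6–8 dropped at ρ = 3 cm, only C8 at ρ = 2 cm). Grand summaries
use the arithmetic mean (a median option exists). nEUROPt summaries
refine the discrete maximum parabolically, interpolate the contrast at a
fixed reference depth linearly, and interpolate lateral FWHM from the
half-maximum crossings, reporting FWHM as absent when a profile never
crosses its half maximum inside the scan. Oximeter comparisons resample
both StO₂ traces to a common 10 s grid and fit a first-degree polynomial
over the 30–90% reference range.

## Synthetic scenarios and their limits

* **MEDPHOT grid** — 32 phantoms, μs′ ∈ {5,10,15,20} cm⁻¹ at 800 nm ×
  nominal μa ∈ {0,…,0.35} cm⁻¹, n = 1.55, per-channel μs′ following
  `(λ/800)^-1`. The resin matrix carries an intrinsic absorption offset
  (default 0.02 cm⁻¹) on top of the nominal values: "nominal 0" means no
  added absorber, and a strictly zero μa would make percent-from-line
  metrics ill-defined.
* **nEUROPt scans** — solid preset (μa 0.1, μs′ 8, n 1.55, 98 mm³,
  Δμa 0.017 cm⁻¹, 1 mm depth steps, lateral scan at 1.5 cm) and liquid
  preset (μa 0.026, μs′ 10.5, n 1.33, 50 mm³ strong absorber, 2.5 mm
  steps, lateral at 1.2 cm), both at ρ = 3 cm.
* **Blood-lipid phantom** — 2.5 l saline base, cumulative blood and
  Intralipid schedules (defaults 20/35/55/70 ml blood at 74 ml
  Intralipid), raised-cosine deoxygenation from 100% to 0% per 28 min
  cycle with instantaneous reoxygenation, HbT from the co-oximetry
  dilution of the bag, μs′(800) scaled to the Intralipid fraction
  through the calibration point 74 ml + 45 ml blood ≈ 5.5 cm⁻¹. The bag
  hemoglobin (2800 μM) is a free parameter chosen so that 45 ml in the
  standard mixture gives ~48 μM — a documented emulation constant, not a
  measured value. The transient HbT dip after oxygen bubbling is not
  enabled by default; the phantom's 1 mm silicone window is not modeled
  (the medium is homogeneous).
* **Cuff occlusions** — homogeneous forearm-like medium (n 1.4, water
  0.7, μs′ 9 cm⁻¹, baseline 40/20 μM), 1 min baseline, 2 min occlusion,
  3 min release. Venous truth: both hemoglobins rise fast then slowly;
  arterial truth: Hb rises more than HbO₂ falls (HbT rises), with a
  hyperemic overshoot after release. Because the medium is homogeneous,
  the depth-sensitivity difference between the MBLL and fit methods seen
  on real (layered) forearms is out of reach: the suite checks that the
  two methods agree in sign everywhere and within 30% in magnitude,
  nothing stronger.

Passing tests on these scenarios show the *pipeline* is correct under
its own forward model (no inverse crime is hidden: noise, IRF and
fit-range handling are all exercised); they do not certify accuracy on
real tissue, where layered structure, pile-up, and IRF drift add errors
the generators deliberately omit (drift correction is tested on injected
linear drifts only).

## Problem sizes

The shipped test suite runs the fluctuation analysis at 100 × 10⁶
photons, curve-fit checks at 10⁶ photons across several seeds, the MC
cross-validation at 10⁶ packets, the conservation sum on a 2.5 mm voxel
grid, and the blood-phantom/occlusion pipelines at 11 channels with
1–2 min sampling — sizes chosen so the whole suite completes in a couple
of minutes on one core while leaving every acceptance margin wide.

## File formats

DTOF sessions round-trip through a documented JSON container
(`write_dtof_container()` / `read_dtof_container()`): a format/version
header, an optional instrument-config block, and integer-exact count
records tagged with wavelength, separation, timing and an optional IRF
role. Tabular results are plain data.frames ready for `write.table()`.
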