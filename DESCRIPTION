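Package: tdnirs
Title: Time-Domain Near-Infrared Spectroscopy Simulation, Analysis and
    Performance Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for time-domain near-infrared spectroscopy (TD-NIRS)
    tissue oximetry. Implements a diffusion-theory forward model of
    time-resolved reflectance from a semi-infinite turbid medium with
    extrapolated boundary conditions, a synthetic multi-wavelength
    time-correlated single-photon counting instrument (instrument response
    function, Poisson noise, differential nonlinearity), statistical moments
    of photon time-of-flight distributions, curve-fit recovery of absorption
    and reduced scattering coefficients, spectral unmixing of hemoglobin and
    water with two-step water subtraction, the modified Beer-Lambert law,
    first-order Born depth-sensitivity analysis with a photon-packet Monte
    Carlo cross-check, and the MEDPHOT, nEUROPt and BIP instrument
    performance protocols, together with synthetic scenario generators
    (phantom grids, perturbation scans, blood-lipid deoxygenation cycles,
    cuff occlusions) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
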