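# Physics and instrument forward model: time-resolved diffuse reflectance of
# a homogeneous semi-infinite medium, instrument response function synthesis,
# convolution to expected counts, and Poisson sampling.

#' Instrument configuration
#'
#' Describes the time and wavelength axes of a multi-wavelength
#' time-correlated single-photon counting (TCSPC) detection module:
#' 1024 time bins of about 9.77 ps within a 12.5 ns laser repetition period
#' (80 MHz), and 16 spectral channels of 12.5 nm width spanning 674-874 nm.
#'
#' @param n_bins number of time bins per DTOF.
#' @param bin_width time bin width, ps.
#' @param rep_period_ns laser repetition period, ns.
#' @param channel_centers center wavelengths of the spectral channels, nm,
#'   strictly increasing.
#' @param channel_width spectral channel width, nm (metadata only; no
#'   finite-bandwidth correction is applied).
#' @param frame_time acquisition time per DTOF frame, s.
#' @return an object of class `instrument_config`.
#' @export
instrument_config <- function(n_bins = 1024L, bin_width = 9.77,
                              rep_period_ns = 12.5,
                              channel_centers = default_channel_centers(),
                              channel_width = 12.5, frame_time = 0.3) {
  stopifnot(n_bins >= 1, bin_width > 0, rep_period_ns > 0,
            channel_width > 0, frame_time > 0)
  if (n_bins * bin_width > rep_period_ns * 1000)
    stop("instrument_config: time window exceeds the repetition period")
  if (is.unsorted(channel_centers, strictly = TRUE))
    stop("instrument_config: channel centers must be strictly increasing")
  structure(list(n_bins = as.integer(n_bins), bin_width = bin_width,
                 rep_period_ns = rep_period_ns,
                 channel_centers = channel_centers,
                 channel_width = channel_width, frame_time = frame_time),
            class = "instrument_config")
}

#' Default spectral channel centers
#'
#' Sixteen channels on a uniform 12.5 nm grid from 680 to 867.5 nm,
#' covering the 674-874 nm polychromator range; eleven of them fall in
#' the 705-830 nm band used for chromophore estimation.
#'
#' @return numeric vector of 16 wavelengths, nm.
#' @export
default_channel_centers <- function() 680 + 12.5 * (0:15)

#' Time axis of an instrument configuration
#'
#' Bin times are taken at bin centers: `(i - 1/2) * bin_width` for
#' 1-based bin index `i`.
#'
#' @param config an [instrument_config()].
#' @return numeric vector of bin-center times, ps.
#' @export
bin_centers <- function(config) {
  (seq_len(config$n_bins) - 0.5) * config$bin_width
}

#' Optical properties of a turbid medium
#'
#' @param mua absorption coefficient, cm^-1 (>= 0).
#' @param musp reduced scattering coefficient, cm^-1 (> 0).
#' @param n_medium refractive index (>= 1).
#' @return an object of class `optical_properties`.
#' @export
optical_properties <- function(mua, musp, n_medium = 1.4) {
  if (!is.finite(mua) || mua < 0) stop("optical_properties: mua must be >= 0")
  if (!is.finite(musp) || musp <= 0)
    stop("optical_properties: musp must be > 0")
  if (!is.finite(n_medium) || n_medium < 1)
    stop("optical_properties: n_medium must be >= 1")
  structure(list(mua = mua, musp = musp, n_medium = n_medium),
            class = "optical_properties")
}

#' Boundary mismatch factor A
#'
#' Factor entering the extrapolated-boundary distance `z_b = 2 A D`,
#' computed from the internal diffuse reflectance of the refractive index
#' mismatch (Groenhuis polynomial approximation).
#'
#' @param n_rel relative refractive index n_in / n_out.
#' @return dimensionless A >= 1.
#' @export
boundary_mismatch_A <- function(n_rel) {
  stopifnot(n_rel > 0)
  if (n_rel == 1) return(1)
  rd <- -1.440 / n_rel^2 + 0.710 / n_rel + 0.668 + 0.0636 * n_rel
  (1 + rd) / (1 - rd)
}

#' Time-resolved diffuse reflectance of a semi-infinite medium
#'
#' Diffusion-theory dipole (image source) solution under extrapolated
#' boundary conditions: an isotropic source at depth `z0 = 1/musp` and its
#' negative image mirrored across the extrapolated plane at `-z_b`,
#' `z_b = 2 A D` with `D = 1/(3 musp)`. The returned curve is a relative
#' photon flux per unit time; absolute throughput is not modeled.
#'
#' @param times times after the source pulse, ps; entries <= 0 give 0.
#' @param rho source-detector separation, cm (> 0).
#' @param props an [optical_properties()] object.
#' @param n_external refractive index of the outside medium.
#' @return nonnegative numeric vector, same length as `times`.
#' @export
diffuse_reflectance_td <- function(times, rho, props, n_external = 1) {
  if (!inherits(props, "optical_properties"))
    props <- do.call(optical_properties, as.list(props))
  if (!is.finite(rho) || rho <= 0)
    stop("diffuse_reflectance_td: invalid geometry (rho must be > 0)")
  v <- speed_in_medium(props$n_medium)
  D <- 1 / (3 * props$musp)
  z0 <- 1 / props$musp
  zb <- 2 * boundary_mismatch_A(props$n_medium / n_external) * D
  out <- numeric(length(times))
  pos <- which(times > 0)
  if (length(pos)) {
    t <- times[pos]
    k <- 1 / (4 * D * v * t)
    out[pos] <- 0.5 * (4 * pi * D * v)^(-1.5) * t^(-2.5) *
      exp(-props$mua * v * t - rho^2 * k) *
      (z0 * exp(-z0^2 * k) + (z0 + 2 * zb) * exp(-(z0 + 2 * zb)^2 * k))
  }
  out
}

#' Instrument response function model
#'
#' Gaussian main peak (FWHM ~150 ps for the multi-anode PMT detector) plus
#' a small Gaussian afterpulse peak, typically 1-2% of the maximum about
#' 1 ns after the main peak.
#'
#' @param fwhm full width at half maximum of the main peak, ps.
#' @param afterpulse_delay delay of the afterpulse peak after the main
#'   peak, ps.
#' @param afterpulse_fraction afterpulse amplitude as a fraction of the
#'   main peak maximum, in \[0, 0.05\].
#' @param t0 time of the main peak, ps.
#' @return an object of class `irf_model`.
#' @export
irf_model <- function(fwhm = 150, afterpulse_delay = 1000,
                      afterpulse_fraction = 0.015, t0 = 1000) {
  stopifnot(fwhm > 0, afterpulse_delay > 0,
            afterpulse_fraction >= 0, afterpulse_fraction <= 0.05, t0 >= 0)
  structure(list(fwhm = fwhm, afterpulse_delay = afterpulse_delay,
                 afterpulse_fraction = afterpulse_fraction, t0 = t0),
            class = "irf_model")
}

#' Synthesize an instrument response function curve
#'
#' @param model an [irf_model()].
#' @param config an [instrument_config()].
#' @return unit-sum nonnegative curve on the instrument time grid.
#' @export
synthesize_irf <- function(model, config) {
  if (model$fwhm < 2 * config$bin_width)
    stop("synthesize_irf: fwhm not resolvable by the bin width")
  t <- bin_centers(config)
  s <- model$fwhm / (2 * sqrt(2 * log(2)))
  main <- exp(-(t - model$t0)^2 / (2 * s^2))
  after <- model$afterpulse_fraction *
    exp(-(t - model$t0 - model$afterpulse_delay)^2 / (2 * (2 * s)^2))
  curve <- main + after
  curve / sum(curve)
}

#' Expected DTOF: model curve observed through the instrument
#'
#' Discrete convolution of the theoretical reflectance curve with the IRF
#' on the shared instrument time grid, scaled so the in-window signal
#' (excluding background) sums to `total_photons`, plus a uniform
#' background level per bin.
#'
#' @param model_curve theoretical reflectance sampled on the instrument
#'   grid.
#' @param irf_curve IRF sampled on the same grid.
#' @param total_photons expected total signal photons in the window.
#' @param background_level expected background counts per bin.
#' @return numeric vector of expected counts per bin.
#' @export
expected_dtof <- function(model_curve, irf_curve, total_photons,
                          background_level = 0) {
  if (length(model_curve) != length(irf_curve))
    stop("expected_dtof: model and IRF curves must share the time grid")
  stopifnot(total_photons >= 0, background_level >= 0)
  n <- length(model_curve)
  sig <- conv_direct(irf_curve, model_curve)[seq_len(n)]
  s <- sum(sig)
  if (s <= 0) stop("expected_dtof: zero signal in window")
  sig * (total_photons / s) + background_level
}

#' Sample a noisy DTOF from expected counts
#'
#' Independent Poisson counts per bin, optionally modulated by a
#' differential-nonlinearity (DNL) pattern of mean 1 that emulates uneven
#' TCSPC bin widths. Identical seeds give identical draws.
#'
#' @param expected nonnegative expected counts per bin.
#' @param seed integer seed.
#' @param dnl_pattern optional multiplicative per-bin pattern, mean 1.
#' @param bin_width,channel_wavelength,rho,acquisition_time,background_level
#'   metadata stored on the returned [dtof()].
#' @return a [dtof()] with integer counts.
#' @export
sample_dtof <- function(expected, seed, dnl_pattern = NULL,
                        bin_width = 9.77, channel_wavelength = NA_real_,
                        rho = NA_real_, acquisition_time = NA_real_,
                        background_level = 0) {
  if (any(!is.finite(expected)) || any(expected < 0))
    stop("sample_dtof: expected counts must be finite and >= 0")
  lam <- expected
  if (!is.null(dnl_pattern)) {
    if (length(dnl_pattern) != length(expected))
      stop("sample_dtof: dnl_pattern length mismatch")
    if (abs(mean(dnl_pattern) - 1) > 1e-6)
      stop("sample_dtof: dnl_pattern must have mean 1")
    lam <- lam * dnl_pattern
  }
  counts <- withr::with_seed(seed, rpois(length(lam), lam))
  dtof(counts, bin_width = bin_width,
       channel_wavelength = channel_wavelength, rho = rho,
       acquisition_time = acquisition_time,
       background_level = background_level)
}

#' Distribution of times of flight of photons (DTOF)
#'
#' Container for one photon time-of-flight histogram and its metadata.
#'
#' @param counts counts per bin (integer when sampled; real after
#'   background subtraction or for noiseless model curves).
#' @param bin_width time bin width, ps.
#' @param channel_wavelength spectral channel center, nm.
#' @param rho source-detector separation, cm.
#' @param acquisition_time acquisition time, s.
#' @param background_level known/estimated background per bin.
#' @param role `"measurement"` or `"irf"`.
#' @return an object of class `dtof`.
#' @export
dtof <- function(counts, bin_width, channel_wavelength = NA_real_,
                 rho = NA_real_, acquisition_time = NA_real_,
                 background_level = 0, role = "measurement") {
  stopifnot(is.numeric(counts), length(counts) >= 1, bin_width > 0)
  if (any(!is.finite(counts))) stop("dtof: counts must be finite")
  structure(list(counts = as.numeric(counts), bin_width = bin_width,
                 channel_wavelength = channel_wavelength, rho = rho,
                 acquisition_time = acquisition_time,
                 background_level = background_level, role = role),
            class = "dtof")
}

#' Bin-center times of a DTOF
#'
#' @param d a [dtof()].
#' @return numeric vector of times, ps.
#' @export
dtof_times <- function(d) (seq_along(d$counts) - 0.5) * d$bin_width

#' @export
print.dtof <- function(x, ...) {
  cat(sprintf("<dtof> %d bins x %.2f ps, %s photons", length(x$counts),
              x$bin_width, format(round(sum(x$counts)))), "\n")
  if (!is.na(x$channel_wavelength))
    cat(sprintf("  channel %.1f nm, rho %.1f cm\n", x$channel_wavelength,
                x$rho))
  invisible(x)
}
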