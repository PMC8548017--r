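# Depth and lateral sensitivity to a small localized absorption
# perturbation: first-order Born model built from image-source diffusion
# Green's functions, scan contrasts, sensitivity factors, and a
# photon-packet Monte Carlo cross-check.

#' Localized absorption perturbation
#'
#' A small absorbing inclusion, treated in the Born model as an equivalent
#' sphere of the same volume centered at `center` (x, y, z) with z the
#' depth below the surface. Centers above the surface (z < 0) are allowed:
#' only the submerged part of the equivalent sphere contributes.
#'
#' @param center numeric (x, y, z), cm; z is depth (positive into the
#'   medium).
#' @param volume_mm3 perturbation volume, mm^3 (> 0); e.g. 98 mm^3 for a
#'   5 mm diameter x 5 mm cylinder, 50 mm^3 for 4 mm x 4 mm.
#' @param delta_mua absorption increase, cm^-1.
#' @return object of class `perturbation`.
#' @export
perturbation <- function(center, volume_mm3, delta_mua) {
  stopifnot(length(center) == 3, volume_mm3 > 0, is.finite(delta_mua))
  structure(list(center = as.numeric(center), volume_mm3 = volume_mm3,
                 delta_mua = delta_mua),
            class = "perturbation")
}

#' Volume of a cylinder, mm^3
#'
#' Convenience for the protocol's cylindrical inclusions.
#'
#' @param diameter_mm,length_mm cylinder dimensions, mm.
#' @return volume, mm^3.
#' @export
cylinder_volume_mm3 <- function(diameter_mm, length_mm) {
  pi * (diameter_mm / 2)^2 * length_mm
}

# diffusion propagator density (cm^-3) in the half space z > 0 with the
# extrapolated-boundary image across z = -zb; includes absorption decay
semiinf_propagator <- function(p1, p2, times, D, v, mua, zb) {
  d1 <- sqrt(sum((p2 - p1)^2))
  p1i <- c(p1[1], p1[2], -p1[3] - 2 * zb)
  d2 <- sqrt(sum((p2 - p1i)^2))
  out <- numeric(length(times))
  pos <- which(times > 0)
  if (length(pos)) {
    t <- times[pos]
    k <- 1 / (4 * D * v * t)
    out[pos] <- (4 * pi * D * v * t)^(-1.5) * exp(-mua * v * t) *
      (exp(-d1^2 * k) - exp(-d2^2 * k))
  }
  pmax(out, 0)
}

# surface flux (reflectance) kernel: signal at a surface detector a lateral
# distance r from a unit density impulse at depth zp (dipole form). The
# proper adjoint leg for a flux detector; with zp = 1/musp and r = rho this
# is exactly diffuse_reflectance_td().
semiinf_flux <- function(zp, r, times, D, v, mua, zb) {
  out <- numeric(length(times))
  pos <- which(times > 0)
  if (length(pos)) {
    t <- times[pos]
    k <- 1 / (4 * D * v * t)
    out[pos] <- 0.5 * (4 * pi * D * v)^(-1.5) * t^(-2.5) *
      exp(-mua * v * t - r^2 * k) *
      (zp * exp(-zp^2 * k) + (zp + 2 * zb) * exp(-(zp + 2 * zb)^2 * k))
  }
  pmax(out, 0)
}

# submerged portion of a sphere centered at depth zc (can be < 0) with
# radius a, cut by the surface plane z = 0: volume (cm^3) and centroid depth
submerged_sphere <- function(zc, a) {
  if (zc >= a) return(list(volume = 4 / 3 * pi * a^3, centroid = zc))
  if (zc <= -a) return(list(volume = 0, centroid = NA_real_))
  # integrate cross sections pi*(a^2 - (z - zc)^2) from z = 0 to zc + a
  z1 <- zc + a
  ivol <- function(z) pi * (a^2 * z - (z - zc)^3 / 3)
  imom <- function(z) pi * ((a^2 - zc^2) * z^2 / 2 + zc * z^3 * 2 / 3 -
                              z^4 / 4)
  vol <- ivol(z1) - ivol(0)
  mom <- imom(z1) - imom(0)
  list(volume = vol, centroid = mom / vol)
}

#' Perturbed time-resolved reflectance (first-order Born model)
#'
#' The unperturbed curve is [diffuse_reflectance_td()]. A localized
#' absorption increase subtracts the time convolution of the
#' source-to-perturbation density Green's function with the
#' perturbation-to-detector surface-flux (reflectance) kernel, scaled by
#' `delta_mua * V * v`; the result is floored at zero. The flux kernel is
#' the correct adjoint leg for a reflectance detector (it reproduces the
#' package's Monte Carlo oracle within statistical error, which the
#' density-at-surface convention does not). The perturbation is treated as
#' a point of strength `delta_mua * V` at the centroid of the submerged
#' part of its equivalent sphere.
#'
#' @param props [optical_properties()] of the background medium.
#' @param rho source-detector separation, cm.
#' @param pert a [perturbation()].
#' @param times uniform time grid, ps.
#' @param n_external outside refractive index.
#' @param source_pos,detector_pos optional explicit positions (cm)
#'   overriding the defaults `(0, 0, 1/musp)` and `(rho, 0, 0)`.
#' @return numeric vector `R_pert(t)` with attributes `r0` (unperturbed
#'   curve) and `degraded` (`TRUE` when the perturbation sits within 2 mm
#'   of source or detector, where the first-order model is unreliable).
#' @export
perturbed_tpsf <- function(props, rho, pert, times, n_external = 1,
                           source_pos = NULL, detector_pos = NULL) {
  stopifnot(inherits(pert, "perturbation"))
  if (length(times) > 1) {
    dt <- diff(times)
    if (any(abs(dt - dt[1]) > 1e-9 * dt[1]))
      stop("perturbed_tpsf: time grid must be uniform")
    dt <- dt[1]
  } else dt <- 1
  v <- speed_in_medium(props$n_medium)
  D <- 1 / (3 * props$musp)
  z0 <- 1 / props$musp
  zb <- 2 * boundary_mismatch_A(props$n_medium / n_external) * D
  src <- if (is.null(source_pos)) c(0, 0, z0) else as.numeric(source_pos)
  det <- if (is.null(detector_pos)) c(rho, 0, 0) else
    as.numeric(detector_pos)
  r0 <- semiinf_flux(src[3], sqrt(sum((det[1:2] - src[1:2])^2)), times,
                     D, v, props$mua, zb)

  a <- (3 * (pert$volume_mm3 / 1000) / (4 * pi))^(1 / 3)
  sub <- submerged_sphere(pert$center[3], a)
  degraded <- FALSE
  if (sub$volume <= 0 || pert$delta_mua == 0) {
    out <- r0
  } else {
    p <- c(pert$center[1], pert$center[2], sub$centroid)
    if (sqrt(sum((p - src)^2)) < 0.2 || sqrt(sum((p - det)^2)) < 0.2) {
      degraded <- TRUE
      warning("perturbed_tpsf: perturbation within 2 mm of an optode; ",
              "first-order model degraded")
    }
    g1 <- semiinf_propagator(src, p, times, D, v, props$mua, zb)
    g2 <- semiinf_flux(p[3], sqrt(sum((det[1:2] - p[1:2])^2)), times,
                       D, v, props$mua, zb)
    dR <- pert$delta_mua * sub$volume * v *
      conv_direct(g1, g2)[seq_along(times)] * dt
    out <- pmax(r0 - dR, 0)
  }
  attr(out, "r0") <- r0
  attr(out, "degraded") <- degraded
  out
}

#' Contrast scan of a moving perturbation
#'
#' Moves a perturbation along a depth scan (midplane between source and
#' detector, varying depth) or a lateral scan (fixed depth, varying lateral
#' offset from the midplane) and computes the five contrasts (dA_early,
#' dA, dA_late, dm1, dV) of each noiseless Born-model curve against the
#' unperturbed reference via [dtof_contrasts()].
#'
#' @param props background [optical_properties()].
#' @param rho source-detector separation, cm.
#' @param pert a [perturbation()]; its center is overridden by the scan.
#' @param positions scan positions, cm (depths, or lateral offsets).
#' @param mode `"depth"` or `"lateral"`.
#' @param lateral_depth depth of the perturbation during lateral scans, cm.
#' @param times uniform time grid, ps (default: 1024 bins of 9.77 ps).
#' @param n_external outside refractive index.
#' @param early,late contrast time windows, ps from t = 0 (the source
#'   pulse; model curves carry no IRF delay).
#' @param threshold_fraction,strict moment threshold, see [dtof_moments()].
#' @return data.frame of class `contrast_scan`: `position`, `dA_early`,
#'   `dA_total`, `dA_late`, `dm1`, `dV`; `delta_mua` kept as an attribute.
#' @export
scan_contrasts <- function(props, rho, pert, positions,
                           mode = c("depth", "lateral"),
                           lateral_depth = 1.5,
                           times = (seq_len(1024) - 0.5) * 9.77,
                           n_external = 1,
                           early = c(500, 1000), late = c(3000, 4000),
                           threshold_fraction = 0.001, strict = FALSE) {
  mode <- match.arg(mode)
  stopifnot(!is.unsorted(positions))
  dt <- times[2] - times[1]
  ref_curve <- NULL
  rows <- lapply(positions, function(x) {
    ctr <- if (mode == "depth") c(rho / 2, 0, x)
           else c(rho / 2, x, lateral_depth)
    p <- perturbation(ctr, pert$volume_mm3, pert$delta_mua)
    curve <- perturbed_tpsf(props, rho, p, times, n_external)
    if (is.null(ref_curve)) ref_curve <<- attr(curve, "r0")
    meas <- dtof(as.numeric(curve), bin_width = dt)
    ref <- dtof(ref_curve, bin_width = dt)
    cr <- dtof_contrasts(meas, ref, irf_max_time = 0, early = early,
                         late = late,
                         threshold_fraction = threshold_fraction,
                         strict = strict, position = x)
    data.frame(position = x, dA_early = cr$dA_early,
               dA_total = cr$dA_total, dA_late = cr$dA_late,
               dm1 = cr$dm1, dV = cr$dV)
  })
  out <- do.call(rbind, rows)
  attr(out, "delta_mua") <- pert$delta_mua
  attr(out, "mode") <- mode
  class(out) <- c("contrast_scan", "data.frame")
  out
}

#' Sensitivity factors from a contrast scan
#'
#' MPP = dA / dmua (mean partial pathlength, cm), MTSF = dm1 / dmua
#' (ps cm) and VSF = dV / dmua (ps^2 cm), elementwise over the scan.
#'
#' @param scan a [scan_contrasts()] result.
#' @param delta_mua the perturbation's absorption increase, cm^-1
#'   (default: taken from the scan attribute).
#' @return data.frame with `position`, `MPP`, `MTSF`, `VSF`.
#' @export
sensitivity_factors <- function(scan, delta_mua = attr(scan, "delta_mua")) {
  if (is.null(delta_mua) || delta_mua == 0)
    stop("sensitivity_factors: delta_mua must be nonzero")
  data.frame(position = scan$position,
             MPP = scan$dA_total / delta_mua,
             MTSF = scan$dm1 / delta_mua,
             VSF = scan$dV / delta_mua)
}

#' Monte Carlo contrast oracle
#'
#' Photon-packet Monte Carlo in the semi-infinite half space (isotropic
#' scattering at `musp`, continuous absorption weighting, Fresnel internal
#' reflection at the surface). Detected photons in an annulus around `rho`
#' record their partial pathlength inside the equivalent-sphere
#' perturbation; the perturbed attenuation contrast and its standard error
#' follow from reweighting by `exp(-delta_mua * l_pert)`.
#'
#' @param props background [optical_properties()].
#' @param rho source-detector separation, cm.
#' @param pert a [perturbation()].
#' @param n_photons launched photon packets (desk scale, <= 1e7).
#' @param seed integer seed (self-contained RNG; reproducible).
#' @param n_external outside refractive index.
#' @param det_halfwidth annulus half width, cm.
#' @param t_max_ps time cap, ps.
#' @param bin_width_ps,n_bins optional DTOF binning of detected photons.
#' @return list with `dA` (total attenuation contrast), `se` (standard
#'   error), `n_detected`, detected weight sums, energy-bookkeeping buckets
#'   (`detected`, `escaped_other`, `absorbed`, `expired`, `launched`) and
#'   binned histograms `hist`, `hist_pert`.
#' @export
mc_contrast <- function(props, rho, pert, n_photons, seed,
                        n_external = 1, det_halfwidth = 0.2,
                        t_max_ps = 12000, bin_width_ps = 9.77,
                        n_bins = 1024) {
  stopifnot(inherits(pert, "perturbation"), n_photons >= 1,
            n_photons <= 1e7)
  a <- (3 * (pert$volume_mm3 / 1000) / (4 * pi))^(1 / 3)
  res <- mc_semiinf(props$mua, props$musp, props$n_medium, n_external,
                    rho, det_halfwidth, pert$center, a, pert$delta_mua,
                    as.integer(n_photons), as.numeric(seed),
                    speed_in_medium(props$n_medium), t_max_ps,
                    bin_width_ps, as.integer(n_bins))
  if (!length(res$w)) stop("mc_contrast: zero detected photons")
  sw <- sum(res$w)
  swp <- sum(res$w_pert)
  ratio <- swp / sw
  # ratio-estimator delta method over launched packets (non-detected = 0)
  n <- n_photons
  mw <- sw / n
  mr <- swp / n
  vr <- (sum(res$w_pert^2) - n * mr^2) / (n - 1)
  vw <- (sum(res$w^2) - n * mw^2) / (n - 1)
  cv <- (sum(res$w_pert * res$w) - n * mr * mw) / (n - 1)
  var_ratio <- (vr - 2 * ratio * cv + ratio^2 * vw) / (n * mw^2)
  list(dA = -log(ratio), se = sqrt(max(var_ratio, 0)) / ratio,
       n_detected = length(res$w), detected = res$detected,
       escaped_other = res$escaped_other, absorbed = res$absorbed,
       expired = res$expired, launched = res$launched,
       hist = res$hist, hist_pert = res$hist_pert)
}
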