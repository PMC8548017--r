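# Synthetic scenario generators emulating the validation experiments:
# the MEDPHOT phantom grid, nEUROPt perturbation scans, blood-lipid
# deoxygenation cycles, and cuff-occlusion hemodynamics. Every generator
# emits its ground truth alongside the data and is reproducible from its
# seed.

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 11587 * as.numeric(i)) %% 2147483629)
}

# unnormalized IRF-convolved model curve on the instrument grid
instrument_curve <- function(props, rho, config, irf_curve,
                             n_external = 1) {
  t <- bin_centers(config)
  r <- diffuse_reflectance_td(t, rho, props, n_external)
  conv_direct(irf_curve, r)[seq_len(config$n_bins)]
}

# expected + optionally Poisson-sampled DTOF for one medium/channel/rho.
# With `amplitude` given, expected counts are amplitude * model curve
# (count rate varies with the medium, as for a real instrument with fixed
# throughput); otherwise the curve is normalized to `photons` total.
simulate_dtof <- function(props, rho, config, irf_curve, photons, seed,
                          noise = TRUE, background = 0,
                          wavelength = NA_real_, n_external = 1,
                          amplitude = NULL) {
  s <- instrument_curve(props, rho, config, irf_curve, n_external)
  ex <- if (is.null(amplitude)) s * (photons / sum(s)) + background
        else s * amplitude + background
  if (noise) {
    sample_dtof(ex, seed, bin_width = config$bin_width,
                channel_wavelength = wavelength, rho = rho,
                acquisition_time = config$frame_time,
                background_level = background)
  } else {
    dtof(ex, bin_width = config$bin_width, channel_wavelength = wavelength,
         rho = rho, acquisition_time = config$frame_time,
         background_level = background)
  }
}

#' Generate the 32-phantom MEDPHOT measurement set
#'
#' Grid A1-D8: nominal reduced scattering 5/10/15/20 cm^-1 (letters, at the
#' 800 nm reference wavelength) by nominal absorption 0 to 0.35 cm^-1 in
#' 0.05 steps (digits), refractive index 1.55 (epoxy resin). Per-channel
#' musp follows the power law `(lambda/800)^(-scatter_power)`; mua is
#' spectrally flat. One DTOF is simulated per phantom per channel.
#'
#' @param seed integer seed.
#' @param photons expected photons per DTOF.
#' @param rho source-detector separation, cm.
#' @param channels channel center wavelengths to simulate, nm.
#' @param config an [instrument_config()].
#' @param irf an [irf_model()].
#' @param noise Poisson noise (`FALSE` gives noiseless expected counts).
#' @param background expected background counts per bin.
#' @param scatter_power scattering power-law exponent b.
#' @param mua_offset intrinsic absorption of the resin matrix, cm^-1,
#'   added to every nominal value (nominal 0 means no added absorber, not
#'   a transparent medium; nominal values do not match true ones).
#' @return list with `truth` ([medphot_grid()] plus `true_mua` at the
#'   reference wavelength), `records` (list of
#'   `list(label, wavelength, dtof)`), `config`, `irf_curve`, `rho`,
#'   `n_medium`.
#' @export
gen_medphot_set <- function(seed = 1, photons = 1e6, rho = 2,
                            channels = 805, config = instrument_config(),
                            irf = irf_model(), noise = TRUE,
                            background = 0, scatter_power = 1,
                            mua_offset = 0.02) {
  grid <- medphot_grid()
  grid$true_mua <- grid$nominal_mua + mua_offset
  irf_curve <- synthesize_irf(irf, config)
  records <- list()
  k <- 0L
  for (i in seq_len(nrow(grid))) {
    for (wl in channels) {
      k <- k + 1L
      musp_wl <- grid$nominal_musp[i] * (wl / 800)^(-scatter_power)
      props <- optical_properties(grid$true_mua[i], musp_wl, 1.55)
      records[[k]] <- list(
        label = grid$label[i], wavelength = wl,
        dtof = simulate_dtof(props, rho, config, irf_curve, photons,
                             derive_seed(seed, k), noise, background, wl))
    }
  }
  list(truth = grid, records = records, config = config,
       irf_curve = irf_curve, rho = rho, n_medium = 1.55)
}

#' nEUROPt phantom presets
#'
#' Solid: mua 0.1, musp 8 cm^-1, n 1.55, 98 mm^3 perturbation with
#' delta_mua 0.017 cm^-1, 1 mm depth steps, lateral scan at 1.5 cm depth.
#' Liquid (1% Intralipid): mua 0.026, musp 10.5 cm^-1, n 1.33, 50 mm^3
#' strongly absorbing perturbation (emulated as delta_mua 1 cm^-1),
#' 2.5 mm depth steps, lateral scan at 1.2 cm depth. Both at rho = 3 cm,
#' lateral steps 2 mm; moment thresholds 0.1% (solid) / 2% (liquid).
#'
#' @param phantom `"solid"` or `"liquid"`.
#' @return list of preset parameters.
#' @export
neuropt_preset <- function(phantom = c("solid", "liquid")) {
  phantom <- match.arg(phantom)
  if (phantom == "solid") {
    list(phantom = "solid",
         props = optical_properties(0.1, 8, 1.55),
         pert = perturbation(c(0, 0, 0), cylinder_volume_mm3(5, 5), 0.017),
         depth_positions = seq(-0.5, 3, by = 0.1),
         lateral_positions = seq(-4, 4, by = 0.2),
         lateral_depth = 1.5, rho = 3, threshold_fraction = 0.001)
  } else {
    list(phantom = "liquid",
         props = optical_properties(0.026, 10.5, 1.33),
         pert = perturbation(c(0, 0, 0), cylinder_volume_mm3(4, 4), 1.0),
         depth_positions = seq(-0.5, 3, by = 0.25),
         lateral_positions = seq(-4, 4, by = 0.2),
         lateral_depth = 1.2, rho = 3, threshold_fraction = 0.02)
  }
}

#' Generate a nEUROPt perturbation scan
#'
#' Simulates the DTOF series of a perturbation moved through a depth scan
#' and a lateral scan over one of the [neuropt_preset()] phantoms, plus
#' the unperturbed reference (the perturbation-at-infinity measurement).
#' Noiseless Born-model curves by default; with `photons` set, curves are
#' scaled and Poisson sampled.
#'
#' @param seed integer seed (used only when `photons` is given).
#' @param phantom `"solid"` or `"liquid"`.
#' @param photons optional expected photons per DTOF.
#' @param config an [instrument_config()] providing the time grid.
#' @return list with the preset fields plus `depth_dtofs`,
#'   `lateral_dtofs`, `reference` (a [dtof()]) and `times`.
#' @export
gen_neuropt_scan <- function(seed = 1, phantom = c("solid", "liquid"),
                             photons = NULL,
                             config = instrument_config()) {
  pre <- neuropt_preset(phantom)
  times <- bin_centers(config)
  dt <- config$bin_width
  make_dtof <- function(curve, i) {
    if (is.null(photons)) {
      dtof(as.numeric(curve), bin_width = dt, rho = pre$rho)
    } else {
      ex <- curve / sum(curve) * photons
      sample_dtof(ex, derive_seed(seed, i), bin_width = dt, rho = pre$rho)
    }
  }
  ref_curve <- NULL
  i <- 0L
  gen_series <- function(positions, mode) {
    lapply(positions, function(x) {
      i <<- i + 1L
      ctr <- if (mode == "depth") c(pre$rho / 2, 0, x)
             else c(pre$rho / 2, x, pre$lateral_depth)
      p <- perturbation(ctr, pre$pert$volume_mm3, pre$pert$delta_mua)
      curve <- perturbed_tpsf(pre$props, pre$rho, p, times)
      if (is.null(ref_curve)) ref_curve <<- attr(curve, "r0")
      make_dtof(curve, i)
    })
  }
  depth_dtofs <- gen_series(pre$depth_positions, "depth")
  lateral_dtofs <- gen_series(pre$lateral_positions, "lateral")
  c(pre, list(depth_dtofs = depth_dtofs, lateral_dtofs = lateral_dtofs,
              reference = make_dtof(ref_curve, i + 1L), times = times))
}

#' Generate a blood-lipid phantom deoxygenation session
#'
#' Emulates a stirred saline phantom to which erythrocyte-bag blood and
#' Intralipid are added stepwise; each cycle deoxygenates from StO2 = 100%
#' to 0% with a smooth (raised-cosine) profile and is instantaneously
#' reoxygenated. HbT follows the co-oximetry dilution of the bag; musp at
#' 800 nm scales with the Intralipid concentration through the calibration
#' point 74 ml Intralipid + 45 ml blood in 2.5 l saline giving about
#' 5.5 cm^-1; per-channel musp follows `(lambda/800)^-1`. The absorption
#' spectrum at each time is assembled from the bundled extinction table
#' plus the water background, and one DTOF is simulated per channel per
#' time point.
#'
#' @param seed integer seed.
#' @param schedule data.frame with per-cycle cumulative `blood_ml` and
#'   `intralipid_ml` (defaults: the four blood amounts 20/35/55/70 ml at
#'   74 ml Intralipid).
#' @param bag_tHb total hemoglobin of the erythrocyte bag, uM (free
#'   parameter of the emulation).
#' @param base_volume_ml saline volume, ml.
#' @param cycle_minutes deoxygenation cycle duration, min.
#' @param dt_s sampling interval, s.
#' @param photons expected photons per DTOF.
#' @param rho source-detector separation, cm.
#' @param channels simulated channel centers, nm.
#' @param table an [extinction_table()].
#' @param config,irf instrument model.
#' @param noise Poisson noise on the DTOFs.
#' @return list with `truth` (per time point: `t_s`, `cycle`, `StO2`,
#'   `HbT`, `HbO2`, `Hb`, `water_fraction`, `musp800`), `mua_true`
#'   (time x channel matrix), `records` (list over time of lists over
#'   channels of [dtof()]s; `NULL` when `photons` is `NULL`),
#'   `wavelengths`, `config`, `irf_curve`, `rho`, `n_medium`.
#' @export
gen_blood_phantom <- function(seed = 1,
                              schedule = data.frame(
                                blood_ml = c(20, 35, 55, 70),
                                intralipid_ml = 74),
                              bag_tHb = 2800, base_volume_ml = 2500,
                              cycle_minutes = 28, dt_s = 60,
                              photons = 1e6, rho = 3,
                              channels = select_channels(
                                default_channel_centers()),
                              table = extinction_table(),
                              config = instrument_config(),
                              irf = irf_model(), noise = TRUE) {
  stopifnot(nrow(schedule) >= 1)
  n_medium <- 1.33
  musp_cal <- 5.5 / (74 / (2500 + 74 + 45))  # cm^-1 per unit IL fraction
  cyc_s <- cycle_minutes * 60
  tt <- seq(0, cyc_s, by = dt_s)
  truth <- do.call(rbind, lapply(seq_len(nrow(schedule)), function(k) {
    blood <- schedule$blood_ml[k]
    il <- schedule$intralipid_ml[k]
    total <- base_volume_ml + blood + il
    hbt <- co_oximetry_reference(bag_tHb, blood, base_volume_ml, il)
    sto2 <- 0.5 * (1 + cos(pi * tt / cyc_s))
    data.frame(t_s = (k - 1) * cyc_s + tt, cycle = k, StO2 = sto2,
               HbT = hbt, HbO2 = sto2 * hbt, Hb = (1 - sto2) * hbt,
               water_fraction = 1 - 0.2 * il / total,
               musp800 = musp_cal * il / total)
  }))
  ext <- extinction_at(table, channels)
  mua_true <- outer(truth$HbO2, ext$eps_hbo2) +
    outer(truth$Hb, ext$eps_hb) +
    outer(truth$water_fraction, ext$mua_water)
  records <- NULL
  irf_curve <- synthesize_irf(irf, config)
  if (!is.null(photons)) {
    k <- 0L
    amp <- rep(NA_real_, length(channels))  # throughput fixed at t = 0
    records <- lapply(seq_len(nrow(truth)), function(i) {
      lapply(seq_along(channels), function(j) {
        k <<- k + 1L
        props <- optical_properties(
          mua_true[i, j], truth$musp800[i] * (channels[j] / 800)^(-1),
          n_medium)
        if (is.na(amp[j])) {
          s <- instrument_curve(props, rho, config, irf_curve)
          amp[j] <<- photons / sum(s)
        }
        simulate_dtof(props, rho, config, irf_curve, photons,
                      derive_seed(seed, k), noise,
                      wavelength = channels[j], amplitude = amp[j])
      })
    })
  }
  list(truth = truth, mua_true = mua_true, records = records,
       wavelengths = channels, config = config, irf_curve = irf_curve,
       rho = rho, n_medium = n_medium)
}

# piecewise truth concentration curves for the occlusion scenarios, uM
occlusion_truth_curves <- function(t, kind, base_HbO2, base_Hb,
                                   t_occl = 60, dur = 120) {
  t_rel <- t - t_occl
  t_release <- t - (t_occl + dur)
  HbO2 <- rep(base_HbO2, length(t))
  Hb <- rep(base_Hb, length(t))
  occl <- t_rel >= 0 & t_release < 0
  post <- t_release >= 0
  if (kind == "venous") {
    fast <- pmin(pmax(t_rel, 0) / 30, 1)
    slow <- pmax(t_rel - 30, 0) / 90
    HbO2[occl] <- base_HbO2 + 6 * fast[occl] + 1.0 * slow[occl]
    Hb[occl] <- base_Hb + 5 * fast[occl] + 1.5 * slow[occl]
    dec <- exp(-t_release[post] / 30)
    HbO2[post] <- base_HbO2 + 7.0 * dec
    Hb[post] <- base_Hb + 6.5 * dec
  } else {  # arterial: Hb rises more than HbO2 falls, so HbT rises
    ramp <- pmin(pmax(t_rel, 0) / 120, 1)
    HbO2[occl] <- base_HbO2 - 7 * ramp[occl]
    Hb[occl] <- base_Hb + 12 * ramp[occl]
    e1 <- exp(-t_release[post] / 15)
    e2 <- (1 - e1) * exp(-t_release[post] / 60)
    HbO2[post] <- base_HbO2 - 7 * e1 + 9 * e2   # hyperemic overshoot
    Hb[post] <- base_Hb + 12 * e1 - 4 * e2      # washout undershoot
  }
  data.frame(HbO2 = HbO2, Hb = Hb)
}

#' Generate a cuff-occlusion in-vivo scenario
#'
#' Forearm-like homogeneous medium (n = 1.4) monitored through a baseline,
#' a 2 min occlusion, and a release phase. Venous truth: HbO2 and Hb both
#' rise, fast then slow. Arterial truth: Hb rises more than HbO2 falls
#' (HbT rises), with a post-release overshoot returning to baseline.
#'
#' @param seed integer seed.
#' @param kind `"arterial"` or `"venous"`.
#' @param dt_s sampling interval, s.
#' @param photons expected photons per DTOF (`NULL` for truth only).
#' @param rho source-detector separation, cm.
#' @param channels simulated channel centers, nm.
#' @param base_HbO2,base_Hb baseline concentrations, uM.
#' @param water_fraction tissue water volume fraction.
#' @param musp800 reduced scattering at 800 nm, cm^-1.
#' @param table,config,irf as in [gen_blood_phantom()].
#' @param noise Poisson noise.
#' @return list with `truth` (`t_s`, `phase`, `HbO2`, `Hb`, `HbT`),
#'   `mua_true`, `records`, `wavelengths`, `config`, `irf_curve`, `rho`,
#'   `n_medium`.
#' @export
gen_occlusion <- function(seed = 1, kind = c("arterial", "venous"),
                          dt_s = 5, photons = 1e6, rho = 3,
                          channels = select_channels(
                            default_channel_centers()),
                          base_HbO2 = 40, base_Hb = 20,
                          water_fraction = 0.7, musp800 = 9,
                          table = extinction_table(),
                          config = instrument_config(),
                          irf = irf_model(), noise = TRUE) {
  kind <- match.arg(kind)
  n_medium <- 1.4
  t_occl <- 60; dur <- 120; t_end <- 360
  t <- seq(0, t_end, by = dt_s)
  conc <- occlusion_truth_curves(t, kind, base_HbO2, base_Hb, t_occl, dur)
  phase <- ifelse(t < t_occl, "baseline",
                  ifelse(t < t_occl + dur, "occlusion", "release"))
  truth <- data.frame(t_s = t, phase = phase, HbO2 = conc$HbO2,
                      Hb = conc$Hb, HbT = conc$HbO2 + conc$Hb)
  ext <- extinction_at(table, channels)
  mua_true <- outer(truth$HbO2, ext$eps_hbo2) +
    outer(truth$Hb, ext$eps_hb) +
    matrix(water_fraction * ext$mua_water, nrow(truth),
           length(channels), byrow = TRUE)
  irf_curve <- synthesize_irf(irf, config)
  records <- NULL
  if (!is.null(photons)) {
    k <- 0L
    amp <- rep(NA_real_, length(channels))  # throughput fixed at baseline
    records <- lapply(seq_len(nrow(truth)), function(i) {
      lapply(seq_along(channels), function(j) {
        k <<- k + 1L
        props <- optical_properties(
          mua_true[i, j], musp800 * (channels[j] / 800)^(-1), n_medium)
        if (is.na(amp[j])) {
          s <- instrument_curve(props, rho, config, irf_curve)
          amp[j] <<- photons / sum(s)
        }
        simulate_dtof(props, rho, config, irf_curve, photons,
                      derive_seed(seed, k), noise,
                      wavelength = channels[j], amplitude = amp[j])
      })
    })
  }
  list(truth = truth, mua_true = mua_true, records = records,
       wavelengths = channels, config = config, irf_curve = irf_curve,
       rho = rho, n_medium = n_medium)
}
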