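# synthetic scenario generators: determinism, ground truth, and
# end-to-end round trips through the analysis pipelines

test_that("generators are deterministic for identical specifications", {
  a <- gen_medphot_set(seed = 4, photons = 1e4, channels = 805)
  b <- gen_medphot_set(seed = 4, photons = 1e4, channels = 805)
  expect_identical(lapply(a$records, function(r) r$dtof$counts),
                   lapply(b$records, function(r) r$dtof$counts))
  c1 <- gen_blood_phantom(seed = 9, dt_s = 600, photons = 1e4,
                          channels = c(730, 805))
  c2 <- gen_blood_phantom(seed = 9, dt_s = 600, photons = 1e4,
                          channels = c(730, 805))
  expect_identical(c1$records[[2]][[1]]$counts, c2$records[[2]][[1]]$counts)
  d1 <- gen_medphot_set(seed = 5, photons = 1e4, channels = 805)
  expect_false(identical(a$records[[1]]$dtof$counts,
                         d1$records[[1]]$dtof$counts))
})

test_that("the MEDPHOT set carries the nominal grid and passes a null analysis", {
  set <- gen_medphot_set(seed = 2, photons = 1e6, rho = 2, channels = 805,
                         noise = FALSE)
  expect_equal(length(set$records), 32)
  expect_setequal(vapply(set$records, `[[`, character(1), "label"),
                  medphot_grid()$label)
  # noiseless end-to-end: fit every phantom, then linearity and coupling
  grid <- set$truth
  fits <- lapply(set$records, function(r)
    fit_optical_properties(r$dtof, set$irf_curve, set$rho, 1.55))
  grid$mua_fit <- vapply(fits, function(f) f$props$mua, numeric(1))
  grid$musp_fit <- vapply(fits, function(f) f$props$musp, numeric(1))
  keep <- apply_exclusions(grid, rho = 2)
  lin_a <- medphot_linearity(keep$mua_fit, keep$nominal_mua, keep$letter)
  expect_lt(attr(lin_a, "grand"), 1)
  lin_s <- medphot_linearity(keep$musp_fit,
                             keep$nominal_musp * (805 / 800)^(-1),
                             keep$digit)
  expect_lt(attr(lin_s, "grand"), 1)
  # no crosstalk is injected, so the recovered coupling is at noise level
  cp <- medphot_coupling(keep$mua_fit, keep$nominal_musp, keep$digit)
  expect_lt(attr(cp, "grand"), 1e-3)
})

test_that("nEUROPt scans step as prescribed and reference the far position", {
  sc <- gen_neuropt_scan(phantom = "solid")
  expect_equal(unique(round(diff(sc$depth_positions), 10)), 0.1)
  expect_equal(unique(round(diff(sc$lateral_positions), 10)), 0.2)
  expect_equal(sc$lateral_depth, 1.5)
  scl <- gen_neuropt_scan(phantom = "liquid")
  expect_equal(unique(round(diff(scl$depth_positions), 10)), 0.25)
  expect_equal(scl$lateral_depth, 1.2)
  # first (above surface) and last (deep) positions match the reference
  first <- dtof_contrasts(sc$depth_dtofs[[1]], sc$reference,
                          threshold_fraction = sc$threshold_fraction,
                          strict = FALSE)
  last <- dtof_contrasts(sc$depth_dtofs[[length(sc$depth_dtofs)]],
                         sc$reference,
                         threshold_fraction = sc$threshold_fraction,
                         strict = FALSE)
  expect_lt(abs(first$dA_total), 1e-9)
  expect_lt(abs(last$dA_total), 1e-3)
  # analyzed through the protocol summary: depth ordering of the maxima
  pre <- neuropt_preset("solid")
  dscan <- scan_contrasts(pre$props, pre$rho, pre$pert,
                          pre$depth_positions,
                          threshold_fraction = pre$threshold_fraction)
  lscan <- scan_contrasts(pre$props, pre$rho, pre$pert,
                          pre$lateral_positions, mode = "lateral",
                          lateral_depth = pre$lateral_depth,
                          threshold_fraction = pre$threshold_fraction)
  sm <- neuropt_summary(dscan, lscan, reference_depth = 1.5)
  d <- setNames(sm$depth_of_max, sm$measurand)
  expect_lt(d["dA_total"], d["dm1"])
  expect_lt(d["dm1"], d["dV"])
})

test_that("blood-phantom truth spans the full saturation range on schedule", {
  bp <- gen_blood_phantom(seed = 1, photons = NULL, dt_s = 120)
  for (k in unique(bp$truth$cycle)) {
    s <- bp$truth$StO2[bp$truth$cycle == k]
    expect_equal(max(s), 1)
    expect_equal(min(s), 0)
    expect_true(all(diff(s) < 0))
  }
  expect_equal(nrow(bp$truth), length(bp$truth$t_s))
  expect_true(all(bp$truth$water_fraction > 0.9))
  # scattering calibration point: 74 ml IL + 45 ml blood ~ 5.5 cm^-1
  cal <- gen_blood_phantom(seed = 1, photons = NULL, dt_s = 600,
                           schedule = data.frame(blood_ml = 45,
                                                 intralipid_ml = 74))
  expect_equal(unique(cal$truth$musp800), 5.5, tolerance = 1e-9)
})

test_that("full blood-phantom pipeline recovers StO2 and HbT", {
  bp <- gen_blood_phantom(seed = 3,
                          schedule = data.frame(blood_ml = 55,
                                                intralipid_ml = 74),
                          dt_s = 120, photons = 1e6)
  rec <- recover_concentration_series(bp$records, bp$wavelengths,
                                      bp$irf_curve, bp$rho, bp$n_medium,
                                      extinction_table())
  truth_pct <- 100 * bp$truth$StO2
  rec_pct <- 100 * rec$StO2
  sel <- truth_pct >= 30 & truth_pct <= 90
  expect_lt(sqrt(mean((rec_pct - truth_pct)[sel]^2)), 5)
  expect_equal(mean(rec$HbT), unique(bp$truth$HbT), tolerance = 0.05)
  cmp <- oximeter_comparison(bp$truth$t_s, rec_pct, bp$truth$t_s,
                             truth_pct)
  expect_gte(cmp$slope, 0.9)
  expect_lte(cmp$slope, 1.1)
  expect_lte(abs(cmp$intercept), 5)
})

test_that("occlusion truths encode the textbook hemodynamics", {
  for (kind in c("arterial", "venous")) {
    oc <- gen_occlusion(seed = 1, kind = kind, photons = NULL, dt_s = 5)
    base <- oc$truth$phase == "baseline"
    occl <- oc$truth$phase == "occlusion"
    expect_equal(sd(oc$truth$HbO2[base]), 0)
    expect_equal(sd(oc$truth$Hb[base]), 0)
    expect_equal(sum(occl) * 5, 120, tolerance = 5)  # 2 min occlusion
    d_end <- function(x) x[max(which(occl))] - mean(x[base])
    if (kind == "arterial") {
      expect_gt(d_end(oc$truth$Hb), 0)
      expect_lt(d_end(oc$truth$HbO2), 0)
      expect_gt(d_end(oc$truth$HbT), 0)  # Hb rise beats the HbO2 fall
      # release overshoot above baseline, then return
      rel <- oc$truth$phase == "release"
      expect_gt(max(oc$truth$HbO2[rel]), mean(oc$truth$HbO2[base]))
      expect_equal(oc$truth$HbO2[length(oc$truth$HbO2)],
                   mean(oc$truth$HbO2[base]), tolerance = 0.5)
    } else {
      # both rise, fast then slow
      t_occ <- oc$truth$t_s[occl] - 60
      hb <- oc$truth$Hb[occl]
      rate_early <- (hb[t_occ == 30] - hb[t_occ == 0]) / 30
      rate_late <- (hb[t_occ == 115] - hb[t_occ == 45]) / 70
      expect_gt(d_end(oc$truth$Hb), 0)
      expect_gt(d_end(oc$truth$HbO2), 0)
      expect_gt(rate_early, 3 * rate_late)
    }
  }
})

test_that("both concentration methods recover the occlusion sign pattern", {
  tab <- extinction_table()
  oc <- gen_occlusion(seed = 5, kind = "arterial", dt_s = 20,
                      photons = 1e6)
  base_i <- which(oc$truth$phase == "baseline")
  rec <- recover_concentration_series(oc$records, oc$wavelengths,
                                      oc$irf_curve, oc$rho, oc$n_medium,
                                      tab)
  mb <- mbll_series(oc$records, oc$wavelengths, oc$irf_curve,
                    oc$n_medium, tab, baseline_index = base_i)
  occl <- oc$truth$phase == "occlusion"
  base <- oc$truth$phase == "baseline"
  dd <- function(x) mean(x[occl]) - mean(x[base])
  truth_dHb <- dd(oc$truth$Hb)
  truth_dHbO2 <- dd(oc$truth$HbO2)
  for (d in list(c(dd(rec$Hb), dd(rec$HbO2)),
                 c(dd(mb$dHb), dd(mb$dHbO2)))) {
    expect_equal(sign(d[1]), sign(truth_dHb))
    expect_equal(sign(d[2]), sign(truth_dHbO2))
  }
  # intensity-only MBLL tracks the time-domain fit within 30%
  expect_equal(dd(mb$dHb), dd(rec$Hb), tolerance = 0.3)
  expect_equal(dd(mb$dHbO2), dd(rec$HbO2), tolerance = 0.3)
})
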