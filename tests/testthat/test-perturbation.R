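# Born-model depth sensitivity and the Monte Carlo oracle

test_that("degenerate perturbations leave the curve untouched", {
  times <- (seq_len(512) - 0.5) * 19.54
  props <- solid_props()
  p0 <- perturbation(c(1.5, 0, 1.5), 98, 0)
  c0 <- perturbed_tpsf(props, 3, p0, times)
  expect_equal(as.numeric(c0), as.numeric(attr(c0, "r0")))
  # very deep perturbation: evanescent sensitivity
  pd <- perturbation(c(1.5, 0, 10), 98, 0.017)
  cd <- perturbed_tpsf(props, 3, pd, times)
  dcr <- dtof_contrasts(dtof(as.numeric(cd), 19.54),
                        dtof(attr(cd, "r0"), 19.54),
                        threshold_fraction = 0.001, strict = FALSE)
  expect_lt(max(abs(unlist(dcr[c("dA_early", "dA_total", "dA_late")]))),
            1e-6)
  # center a full radius above the surface: no submerged volume
  a <- (3 * 0.098 / (4 * pi))^(1 / 3)
  pu <- perturbation(c(1.5, 0, -1.1 * a), 98, 0.017)
  cu <- perturbed_tpsf(props, 3, pu, times)
  expect_equal(as.numeric(cu), as.numeric(attr(cu, "r0")))
})

test_that("midplane perturbations satisfy source-detector reciprocity", {
  times <- (seq_len(512) - 0.5) * 19.54
  props <- solid_props()
  z0 <- 1 / props$musp
  pert <- perturbation(c(1.5, 0.8, 1.2), 98, 0.017)
  fwd <- perturbed_tpsf(props, 3, pert, times,
                        source_pos = c(0, 0, z0),
                        detector_pos = c(3, 0, 0))
  swp <- perturbed_tpsf(props, 3, pert, times,
                        source_pos = c(3, 0, z0),
                        detector_pos = c(0, 0, 0))
  expect_equal(as.numeric(fwd), as.numeric(swp), tolerance = 1e-12)
})

test_that("the Born response is first order in strength and volume", {
  props <- solid_props()
  pert <- perturbation(c(1.5, 0, 1.5), 98, 0.017)
  s1 <- scan_contrasts(props, 3, pert, seq(0.5, 2.5, 0.5))
  half <- perturbation(c(1.5, 0, 1.5), 49, 0.0085)
  s2 <- scan_contrasts(props, 3, half, seq(0.5, 2.5, 0.5))
  for (m in c("dA_total", "dm1", "dV"))
    expect_equal(s2[[m]], s1[[m]] / 4, tolerance = 0.02)
})

test_that("summed partial pathlengths reproduce the total mean pathlength", {
  props <- solid_props()
  times <- (seq_len(256) - 0.5) * 40
  r0 <- diffuse_reflectance_td(times, 3, props)
  v <- speed_in_medium(props$n_medium)
  vm1 <- v * sum(times * r0) / sum(r0)
  h <- 0.25
  grid <- expand.grid(x = seq(-2 + h / 2, 5, h),
                      y = seq(-3 + h / 2, 3, h),
                      z = seq(h / 2, 4.5, h))
  dmua <- 1e-4
  tot <- 0
  for (i in seq_len(nrow(grid))) {
    p <- perturbation(c(grid$x[i], grid$y[i], grid$z[i]), h^3 * 1000, dmua)
    cv <- suppressWarnings(perturbed_tpsf(props, 3, p, times))
    tot <- tot + (-log(sum(cv) / sum(attr(cv, "r0")))) / dmua
  }
  expect_equal(tot, vm1, tolerance = 0.05)
})

test_that("depth of maximum contrast is ordered dA < dm1 < dV on both phantoms", {
  for (phantom in c("solid", "liquid")) {
    pre <- neuropt_preset(phantom)
    sc <- scan_contrasts(pre$props, pre$rho, pre$pert, pre$depth_positions,
                         threshold_fraction = pre$threshold_fraction)
    depth_of <- function(m) sc$position[which.max(abs(sc[[m]]))]
    expect_lt(depth_of("dA_total"), depth_of("dm1"))
    expect_lt(depth_of("dm1"), depth_of("dV"))
    # early window peaks shallower than the late window
    expect_lte(depth_of("dA_early"), depth_of("dA_late"))
  }
})

test_that("moment contrasts flip sign between shallow and deep perturbations", {
  pre <- neuropt_preset("solid")
  sc <- scan_contrasts(pre$props, pre$rho, pre$pert, c(0.5, 2),
                       threshold_fraction = pre$threshold_fraction)
  expect_lt(sc$dm1[1], 0)  # shallow: m1 increases
  expect_lt(sc$dV[1], 0)
  expect_gt(sc$dm1[2], 0)  # deep: m1 decreases
  expect_gt(sc$dV[2], 0)
})

test_that("lateral scans are symmetric and widen with measurand order", {
  pre <- neuropt_preset("solid")
  sc <- scan_contrasts(pre$props, pre$rho, pre$pert, seq(-3, 3, 0.25),
                       mode = "lateral", lateral_depth = pre$lateral_depth,
                       threshold_fraction = pre$threshold_fraction)
  for (m in c("dA_early", "dA_total", "dA_late", "dm1", "dV"))
    expect_equal(sc[[m]], rev(sc[[m]]), tolerance = 1e-9)
  fw <- vapply(c("dA_early", "dA_total", "dA_late"),
               function(m) profile_fwhm(sc$position, sc[[m]]), numeric(1))
  expect_true(all(diff(fw) > 0))
  expect_gt(profile_fwhm(sc$position, sc$dV),
            profile_fwhm(sc$position, sc$dm1))
})

test_that("liquid-phantom contrasts at depth exceed the solid phantom's", {
  sol <- neuropt_preset("solid")
  liq <- neuropt_preset("liquid")
  s_sol <- scan_contrasts(sol$props, 3, sol$pert, 2,
                          threshold_fraction = sol$threshold_fraction)
  s_liq <- scan_contrasts(liq$props, 3, liq$pert, 2,
                          threshold_fraction = liq$threshold_fraction)
  for (m in c("dA_early", "dA_total", "dA_late", "dm1", "dV"))
    expect_gt(abs(s_liq[[m]]), abs(s_sol[[m]]))
})

test_that("sensitivity factors scale contrasts by the absorption step", {
  pre <- neuropt_preset("solid")
  sc <- scan_contrasts(pre$props, 3, pre$pert, seq(0.5, 4.5, 0.5),
                       threshold_fraction = pre$threshold_fraction)
  sf <- sensitivity_factors(sc)
  expect_equal(sf$MPP, sc$dA_total / 0.017)
  expect_equal(sf$MTSF, sc$dm1 / 0.017)
  expect_equal(sf$VSF, sc$dV / 0.017)
  # profiles decay to nothing beyond 4 cm depth
  deep <- sf$position > 4
  expect_lt(max(abs(sf$MPP[deep])), 1e-4 * max(abs(sf$MPP)))
  expect_error(sensitivity_factors(sc, 0), "nonzero")
})

test_that("the Monte Carlo oracle conserves energy and is seed-reproducible", {
  props <- solid_props()
  pert <- perturbation(c(1.5, 0, 1.5), 98, 0.017)
  mc <- mc_contrast(props, 3, pert, 5e4, seed = 11)
  closure <- (mc$detected + mc$escaped_other + mc$absorbed + mc$expired -
                mc$launched) / mc$launched
  expect_lt(abs(closure), 1e-6)
  mc2 <- mc_contrast(props, 3, pert, 5e4, seed = 11)
  expect_identical(mc$dA, mc2$dA)
  # absent perturbation: exactly zero contrast
  mc0 <- mc_contrast(props, 3, perturbation(c(1.5, 0, 1.5), 98, 0), 2e4,
                     seed = 12)
  expect_equal(mc0$dA, 0)
})

test_that("Born and Monte Carlo attenuation contrasts agree at depth", {
  props <- solid_props()
  pert <- perturbation(c(1.5, 0, 1.5), cylinder_volume_mm3(5, 5), 0.017)
  mc <- mc_contrast(props, 3, pert, 1e6, seed = 7)
  times <- (seq_len(1024) - 0.5) * 9.77
  curve <- perturbed_tpsf(props, 3, pert, times)
  born <- -log(sum(curve) / sum(attr(curve, "r0")))
  expect_lt(abs(born - mc$dA), 3 * mc$se)
})
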