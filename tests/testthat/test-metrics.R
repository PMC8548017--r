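# DTOF measurands: background subtraction, moments, windows, contrasts,
# DNL, fluctuations, drift correction, rebinning

test_that("moments of degenerate histograms follow the closed forms", {
  # single nonzero bin: m1 at its center, V = 0
  counts <- numeric(200); counts[123] <- 500
  d <- dtof(counts, bin_width = 9.77)
  m <- dtof_moments(d)
  expect_equal(m$m1, (123 - 0.5) * 9.77)
  expect_equal(m$V, 0)
  expect_equal(m$N, 500)
  # two equal bins: m1 at the midpoint, V = (half spacing)^2; explicit
  # integration limits (the threshold rule keeps only the contiguous run
  # around the peak, which would drop the second isolated bin)
  counts <- numeric(20); counts[c(5, 10)] <- 40
  d2 <- dtof(counts, bin_width = 200)
  m2 <- dtof_moments(d2, bins = c(1, 20))
  t1 <- (5 - 0.5) * 200; t2 <- (10 - 0.5) * 200
  expect_equal(m2$N, 80)
  expect_equal(m2$m1, (t1 + t2) / 2)
  expect_equal(m2$V, ((t2 - t1) / 2)^2)  # 250000 ps^2 for 1000 ps spacing
  # the threshold rule itself keeps only the peak-containing run
  expect_equal(dtof_moments(d2, threshold_fraction = 0)$N, 40)
  expect_error(dtof_moments(dtof(numeric(10) , 1)), "empty above-threshold")
})

test_that("moments equal the brute-force weighted-sum oracle", {
  cfg <- std_config()
  for (seed in 1:5) {
    d <- sim_dtof(solid_props(), photons = 1e5, seed = seed, config = cfg)
    for (thr in c(0.001, 0.01, 0.1)) {
      m <- dtof_moments(d, thr)
      reg <- oracle_threshold_region(d$counts, thr)
      expect_identical(m$bins_used, reg)
      o <- oracle_moments(d$counts, cfg$bin_width, reg[1]:reg[2])
      expect_equal(m$N, o$N, tolerance = 1e-12)
      expect_equal(m$m1, o$m1, tolerance = 1e-9)
      expect_equal(m$V, o$V, tolerance = 1e-9)
      expect_gte(m$V, 0)
    }
  }
})

test_that("raising the threshold never increases N", {
  d <- sim_dtof(solid_props(), photons = 1e5, seed = 3)
  Ns <- vapply(c(0, 0.001, 0.01, 0.05, 0.1, 0.5),
               function(f) dtof_moments(d, f)$N, numeric(1))
  expect_true(all(diff(Ns) <= 0))
})

test_that("background subtraction recovers the clean moments", {
  cfg <- std_config()
  clean <- sim_dtof(solid_props(), photons = 1e6, seed = 21, config = cfg)
  # same photon stream plus a uniform background of 10 counts/bin
  noisy <- sim_dtof(solid_props(), photons = 1e6, seed = 21, config = cfg,
                    background = 10)
  sub <- subtract_background(noisy)
  expect_equal(sub$background_level, 10, tolerance = 0.1)
  m_clean <- dtof_moments(clean)
  m_sub <- dtof_moments(sub)
  expect_equal(m_sub$N, m_clean$N, tolerance = 0.01)
  expect_lt(abs(m_sub$m1 - m_clean$m1), 5)
  # background-free input is unchanged up to the (near-zero) estimate
  sub0 <- subtract_background(clean)
  expect_lt(sub0$background_level, 0.5)
  # featureless input: the peak sits too early to bracket a background
  expect_error(subtract_background(dtof(rep(100, 1024), 9.77)),
               "peak too early")
})

test_that("window counts use a half-open interval referenced to the IRF maximum", {
  d <- sim_dtof(solid_props(), photons = 1e5, seed = 4)
  full <- window_counts(d, c(0, 1024 * 9.77), irf_max_time = 0)
  expect_equal(full, sum(d$counts))
  # on an everywhere-positive histogram the full window equals N at
  # threshold zero (no contiguity gaps)
  dp <- dtof(d$counts + 1, bin_width = d$bin_width)
  expect_equal(window_counts(dp, c(0, 1024 * 9.77)), dtof_moments(dp, 0)$N)
  expect_equal(window_counts(d, c(500, 500)), 0)
  expect_error(window_counts(d, c(9000, 12000)), "outside")
  # shifting the zero time by k bins shifts the selected bins by k
  counts <- seq_len(100)
  dd <- dtof(counts, bin_width = 10)
  w <- c(200, 400)
  a <- window_counts(dd, w, irf_max_time = 0)
  b <- window_counts(dd, w, irf_max_time = 30)
  idx_a <- which((1:100 - 0.5) * 10 >= w[1] & (1:100 - 0.5) * 10 < w[2])
  expect_equal(a, sum(counts[idx_a]))
  expect_equal(b, sum(counts[idx_a + 3]))
})

test_that("contrasts vanish at the reference, follow -ln ratios, and are antisymmetric", {
  # the simulated IRF peaks at 1000 ps: windows are referenced there
  d <- sim_dtof(solid_props(), photons = 1e6, seed = 8)
  z <- dtof_contrasts(d, d, irf_max_time = 1000)
  expect_equal(unlist(z[c("dA_early", "dA_total", "dA_late", "dm1", "dV")]),
               c(dA_early = 0, dA_total = 0, dA_late = 0, dm1 = 0, dV = 0))
  half <- d; half$counts <- d$counts / 2
  h <- dtof_contrasts(half, d, irf_max_time = 1000)
  expect_equal(h$dA_total, log(2), tolerance = 1e-12)
  expect_equal(h$dA_early, log(2), tolerance = 1e-12)
  expect_equal(h$dm1, 0)
  # antisymmetry of dA under swapping measured and reference
  other <- sim_dtof(optical_properties(0.12, 8, 1.55), photons = 1e6,
                    seed = 9)
  ab <- dtof_contrasts(d, other, irf_max_time = 1000)
  ba <- dtof_contrasts(other, d, irf_max_time = 1000)
  expect_equal(ab$dA_total, -ba$dA_total, tolerance = 1e-12)
  expect_equal(ab$dA_late, -ba$dA_late, tolerance = 1e-12)
  expect_error(dtof_contrasts(d, dtof(d$counts, bin_width = 5)),
               "binning differ")
})

test_that("epsilon_DNL is peak-to-peak over mean", {
  expect_equal(epsilon_dnl(rep(100, 1024), 9.77), 0)
  expect_equal(epsilon_dnl(rep(c(99, 101), 512), 9.77), 0.02)
  withr::with_seed(2, x <- rpois(1024, 1e5))
  t <- (seq_along(x) - 0.5) * 9.77
  sel <- x[t >= 1000 & t <= 10000]
  expect_equal(epsilon_dnl(x, 9.77, c(1000, 10000)),
               (max(sel) - min(sel)) / mean(sel))
  expect_error(epsilon_dnl(x, 9.77, c(20000, 30000)), "empty")
})

test_that("temporal fluctuations sit at the photon-noise floor", {
  cfg <- std_config()
  ex <- sim_dtof(optical_properties(0.07, 8, 1.55), photons = 1e6,
                 noise = FALSE, config = cfg)
  bins <- dtof_moments(ex, 0.01)$bins_used
  moms <- lapply(1:100, function(i)
    dtof_moments(sample_dtof(ex$counts, 3000 + i,
                             bin_width = cfg$bin_width), bins = bins))
  fl <- temporal_fluctuations(moms)
  m <- dtof_moments(ex, 0.01)
  floor_m1 <- sqrt(m$V / m$N)
  expect_gte(fl$m1_sd_ps, floor_m1 * 0.8)
  expect_lte(fl$m1_sd_ps, floor_m1 * 1.3)
  # identical records: zero spread
  same <- temporal_fluctuations(list(m, m, m))
  expect_equal(same$N_rel_sd_percent, 0)
  expect_equal(same$m1_sd_ps, 0)
})

test_that("drift correction removes a linear IRF drift", {
  base <- list(N = 1e6, m1 = 1000, V = 20000)
  drifted <- list(N = 1.02e6, m1 = 1005, V = 20500)
  ts <- seq(0, 3600, by = 360)
  series <- data.frame(timestamp = ts,
                       N = 5e5 * (1 + 0.02 * ts / 3600),
                       m1 = 1500 + 5 * ts / 3600,
                       V = 3e5 + 500 * ts / 3600)
  corr <- drift_correct(series, base, drifted, 0, 3600)
  expect_equal(corr$m1, rep(1500, length(ts)), tolerance = 1e-10)
  expect_equal(corr$V, rep(3e5, length(ts)), tolerance = 1e-10)
  expect_equal(corr$N, rep(5e5, length(ts)), tolerance = 1e-10)
  # identical IRFs leave the series untouched
  corr0 <- drift_correct(series, base, base, 0, 3600)
  expect_equal(corr0, series)
  # midpoint sample receives exactly half the endpoint correction
  mid <- data.frame(timestamp = 1800, N = 1e5, m1 = 1500, V = 3e5)
  cm <- drift_correct(mid, base, drifted, 0, 3600)
  expect_equal(cm$m1, 1500 - 2.5)
  expect_equal(cm$V, 3e5 - 250)
  expect_equal(cm$N, 1e5 / 1.01)
  expect_error(drift_correct(data.frame(timestamp = -5, N = 1, m1 = 1,
                                        V = 1), base, drifted, 0, 3600),
               "outside")
})

test_that("time rebinning sums frames and conserves photons", {
  cfg <- std_config()
  frames <- lapply(1:7, function(i)
    sim_dtof(solid_props(), photons = 1e4, seed = 40 + i, config = cfg))
  expect_identical(rebin_time(frames, 1), frames)
  expect_message(out <- rebin_time(frames, 3), "dropping 1")
  expect_length(out, 2)
  expect_equal(out[[1]]$counts,
               frames[[1]]$counts + frames[[2]]$counts + frames[[3]]$counts)
  tot_in <- sum(vapply(frames[1:6], function(d) sum(d$counts), numeric(1)))
  tot_out <- sum(vapply(out, function(d) sum(d$counts), numeric(1)))
  expect_equal(tot_out, tot_in)
  # 3 x 0.3 s frames give ~1 s effective sampling
  expect_equal(out[[1]]$acquisition_time, 0.9)
  expect_error(rebin_time(frames, 0), "positive integer")
})
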