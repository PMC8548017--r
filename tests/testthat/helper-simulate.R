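# shared builders for the test suite; everything is generated in code

std_config <- function(...) instrument_config(...)

std_irf_curve <- function(config = std_config(), model = irf_model()) {
  synthesize_irf(model, config)
}

# one simulated measurement DTOF (background-free unless asked)
sim_dtof <- function(props, rho = 3, photons = 1e6, seed = 1,
                     config = std_config(), irf_curve = std_irf_curve(config),
                     background = 0, noise = TRUE) {
  t <- bin_centers(config)
  r <- diffuse_reflectance_td(t, rho, props)
  ex <- expected_dtof(r, irf_curve, photons, background)
  if (noise) {
    sample_dtof(ex, seed, bin_width = config$bin_width, rho = rho,
                acquisition_time = config$frame_time,
                background_level = background)
  } else {
    dtof(ex, bin_width = config$bin_width, rho = rho,
         acquisition_time = config$frame_time,
         background_level = background)
  }
}

# brute-force moment oracle: direct weighted sums over an explicit index set
oracle_moments <- function(counts, bin_width, idx) {
  t <- (idx - 0.5) * bin_width
  c_ <- counts[idx]
  N <- sum(c_)
  m1 <- sum(t * c_) / N
  list(N = N, m1 = m1, V = sum(t^2 * c_) / N - m1^2)
}

# independent threshold-region oracle (rle-based, distinct from the
# implementation's peak-expansion walk)
oracle_threshold_region <- function(counts, fraction, strict = TRUE) {
  thr <- fraction * max(counts)
  ok <- if (strict) counts > thr else counts >= thr
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  peak <- which.max(counts)
  k <- which(r$values & starts <= peak & ends >= peak)
  c(starts[k], ends[k])
}

solid_props <- function() optical_properties(0.1, 8, 1.55)
liquid_props <- function() optical_properties(0.026, 10.5, 1.33)
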