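# Chromophore analysis: extinction tables, spectral channel selection,
# Beer-Lambert unmixing of absorption spectra into HbO2/Hb/water, the
# two-step water subtraction, and the modified Beer-Lambert law for
# concentration changes.

#' Load an extinction table
#'
#' Reads a CSV of chromophore spectra (columns `wavelength_nm`,
#' `eps_hbo2_molar_log10`, `eps_hb_molar_log10`, `mua_water_cm1`) and
#' converts hemoglobin extinction to natural-log units of cm^-1 uM^-1:
#' `eps = eps_molar_log10 * ln(10) * 1e-6`. Water is an absorption
#' coefficient (cm^-1) at unit volume fraction. The bundled default table
#' is an approximate literature compilation (see the file header).
#'
#' @param path CSV path; default: the bundled table.
#' @return object of class `extinction_table`: data.frame with columns
#'   `wavelength`, `eps_hbo2`, `eps_hb`, `mua_water`.
#' @export
extinction_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "extinction_hemoglobin_water.csv",
                        package = "tdnirs", mustWork = TRUE)
  raw <- read.csv(path, comment.char = "#")
  need <- c("wavelength_nm", "eps_hbo2_molar_log10", "eps_hb_molar_log10",
            "mua_water_cm1")
  if (!all(need %in% names(raw)))
    stop("extinction_table: missing required columns")
  tab <- data.frame(
    wavelength = raw$wavelength_nm,
    eps_hbo2 = raw$eps_hbo2_molar_log10 * log(10) * 1e-6,
    eps_hb = raw$eps_hb_molar_log10 * log(10) * 1e-6,
    mua_water = raw$mua_water_cm1)
  if (is.unsorted(tab$wavelength, strictly = TRUE))
    stop("extinction_table: wavelength grid must be strictly increasing")
  if (any(tab$eps_hbo2 <= 0 | tab$eps_hb <= 0 | tab$mua_water <= 0))
    stop("extinction_table: extinction values must be positive")
  class(tab) <- c("extinction_table", "data.frame")
  tab
}

#' Convert decadic molar extinction to the package's ln-based units
#'
#' @param eps_molar_log10 extinction in cm^-1 M^-1 (decadic).
#' @return extinction in cm^-1 uM^-1 (natural log).
#' @export
molar_log10_to_uM_ln <- function(eps_molar_log10) {
  eps_molar_log10 * log(10) * 1e-6
}

#' Interpolate an extinction table at given wavelengths
#'
#' Linear interpolation; wavelengths outside the tabulated range are an
#' error.
#'
#' @param table an [extinction_table()].
#' @param wavelengths nm.
#' @return data.frame with `wavelength`, `eps_hbo2`, `eps_hb`, `mua_water`.
#' @export
extinction_at <- function(table, wavelengths) {
  rng <- range(table$wavelength)
  if (any(wavelengths < rng[1] | wavelengths > rng[2]))
    stop("extinction_at: wavelength outside tabulated range")
  data.frame(
    wavelength = wavelengths,
    eps_hbo2 = approx(table$wavelength, table$eps_hbo2, wavelengths)$y,
    eps_hb = approx(table$wavelength, table$eps_hb, wavelengths)$y,
    mua_water = approx(table$wavelength, table$mua_water, wavelengths)$y)
}

#' Select spectral channels within a wavelength band
#'
#' @param channel_centers nm.
#' @param lo,hi inclusive band limits, nm (defaults: the 705-830 nm band
#'   used for chromophore estimation, which keeps 11 of the 16 default
#'   channels).
#' @return the selected centers, order preserved.
#' @export
select_channels <- function(channel_centers, lo = 705, hi = 830) {
  stopifnot(length(channel_centers) >= 1)
  out <- channel_centers[channel_centers >= lo & channel_centers <= hi]
  if (!length(out)) stop("select_channels: empty channel selection")
  out
}

# minimal Lawson-Hanson nonnegative least squares (only used when the
# nonnegativity flag is requested; default pipeline is plain OLS)
nnls_lh <- function(A, b, tol = 1e-10, max_iter = 10 * ncol(A)) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0
  while (any(!passive & w > tol) && iter < max_iter) {
    iter <- iter + 1
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      s[passive] <- qr.solve(A[, passive, drop = FALSE], b)
      if (all(s[passive] > tol)) break
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[passive & x <= tol] <- FALSE
    }
    x <- s
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}

#' Unmix chromophore concentrations from an absorption spectrum
#'
#' Ordinary least-squares solution of the Beer-Lambert system
#' `mua(lambda) = sum_c eps_c(lambda) * C_c` for the requested chromophore
#' subset. Concentrations are in uM (water as a volume fraction). No
#' nonnegativity constraint is imposed by default; `nonneg = TRUE` switches
#' to nonnegative least squares.
#'
#' @param mua absorption coefficients per wavelength, cm^-1.
#' @param wavelengths nm, same length as `mua`.
#' @param table an [extinction_table()].
#' @param chromophores subset of `c("HbO2", "Hb", "water")`.
#' @param nonneg impose nonnegativity (default `FALSE`).
#' @return object of class `concentration_record`: `HbO2`, `Hb` (uM),
#'   `water_fraction`, `HbT = HbO2 + Hb`, `StO2 = HbO2/HbT` (`NaN` when
#'   `HbT <= 0.1` uM), `residual_norm`.
#' @export
unmix_concentrations <- function(mua, wavelengths, table,
                                 chromophores = c("HbO2", "Hb", "water"),
                                 nonneg = FALSE) {
  stopifnot(length(mua) == length(wavelengths))
  chromophores <- match.arg(chromophores, c("HbO2", "Hb", "water"),
                            several.ok = TRUE)
  ext <- extinction_at(table, wavelengths)
  cols <- c(HbO2 = "eps_hbo2", Hb = "eps_hb", water = "mua_water")
  E <- as.matrix(ext[, cols[chromophores], drop = FALSE])
  colnames(E) <- chromophores
  if (length(mua) < ncol(E))
    stop("unmix_concentrations: fewer wavelengths than chromophores")
  if (qr(E)$rank < ncol(E))
    stop("unmix_concentrations: rank-deficient design")
  coefs <- if (nonneg) nnls_lh(E, mua) else qr.solve(E, mua)
  names(coefs) <- chromophores
  res <- mua - drop(E %*% coefs)
  get0 <- function(nm) if (nm %in% chromophores) unname(coefs[nm]) else 0
  HbO2 <- get0("HbO2")
  Hb <- get0("Hb")
  HbT <- HbO2 + Hb
  structure(list(
    HbO2 = HbO2, Hb = Hb,
    water_fraction = if ("water" %in% chromophores) unname(coefs["water"])
                     else NA_real_,
    HbT = HbT,
    StO2 = if (HbT > 0.1) HbO2 / HbT else NaN,
    residual_norm = sqrt(sum(res^2))),
    class = "concentration_record")
}

#' Two-step water subtraction for hemoglobin time series
#'
#' Step 1 unmixes HbO2, Hb and water at every time point; the water
#' fraction is averaged over the whole measurement (it is assumed
#' constant). Step 2 subtracts the mean water contribution from every
#' spectrum and re-unmixes only HbO2 and Hb, which gives less noisy
#' hemoglobin estimates.
#'
#' @param mua_mat matrix of absorption spectra, time points x wavelengths,
#'   cm^-1 (>= 2 rows).
#' @param wavelengths nm, one per column.
#' @param table an [extinction_table()].
#' @param nonneg passed to [unmix_concentrations()].
#' @return data.frame with per-time-point `HbO2`, `Hb`, `HbT`, `StO2`
#'   (step-2 values) and attributes `mean_water_fraction` and `step1`
#'   (the step-1 data.frame, including per-point water fractions).
#' @export
water_subtract_two_step <- function(mua_mat, wavelengths, table,
                                    nonneg = FALSE) {
  mua_mat <- as.matrix(mua_mat)
  stopifnot(nrow(mua_mat) >= 2, ncol(mua_mat) == length(wavelengths))
  step1 <- do.call(rbind, lapply(seq_len(nrow(mua_mat)), function(i) {
    r <- unmix_concentrations(mua_mat[i, ], wavelengths, table,
                              c("HbO2", "Hb", "water"), nonneg)
    data.frame(HbO2 = r$HbO2, Hb = r$Hb, HbT = r$HbT, StO2 = r$StO2,
               water_fraction = r$water_fraction)
  }))
  w_mean <- mean(step1$water_fraction)
  muaw <- extinction_at(table, wavelengths)$mua_water
  mua2 <- sweep(mua_mat, 2, w_mean * muaw)
  out <- do.call(rbind, lapply(seq_len(nrow(mua2)), function(i) {
    r <- unmix_concentrations(mua2[i, ], wavelengths, table,
                              c("HbO2", "Hb"), nonneg)
    data.frame(HbO2 = r$HbO2, Hb = r$Hb, HbT = r$HbT, StO2 = r$StO2)
  }))
  attr(out, "mean_water_fraction") <- w_mean
  attr(out, "step1") <- step1
  out
}

#' Concentration changes from attenuation changes (modified Beer-Lambert law)
#'
#' The mean optical pathlength per channel is derived from the mean time of
#' flight: `L(lambda) = (c / n_medium) * m1(lambda)` (Delpy-style
#' time-of-flight pathlength). Concentration changes solve
#' `dA(lambda) / L(lambda) = sum_c eps_c(lambda) * dC_c` by least squares
#' per time point, for HbO2 and Hb.
#'
#' @param dA_mat attenuation changes vs baseline, time points x
#'   wavelengths (dimensionless, natural log).
#' @param m1 mean time of flight per wavelength, ps: either a vector (the
#'   baseline m1, default behavior) or a matrix matching `dA_mat`
#'   (time-varying pathlength).
#' @param n_medium refractive index of the tissue.
#' @param wavelengths nm, one per column.
#' @param table an [extinction_table()].
#' @return data.frame with `dHbO2`, `dHb`, `dHbT` (uM) per time point.
#' @export
mbll_changes <- function(dA_mat, m1, n_medium, wavelengths, table) {
  dA_mat <- as.matrix(dA_mat)
  stopifnot(ncol(dA_mat) == length(wavelengths))
  v <- speed_in_medium(n_medium)
  if (is.matrix(m1)) {
    stopifnot(all(dim(m1) == dim(dA_mat)))
    if (any(m1 <= 0)) stop("mbll_changes: nonpositive mean time of flight")
    L <- v * m1
  } else {
    stopifnot(length(m1) == length(wavelengths))
    if (any(m1 <= 0)) stop("mbll_changes: nonpositive mean time of flight")
    L <- matrix(v * m1, nrow = nrow(dA_mat), ncol = length(m1), byrow = TRUE)
  }
  ext <- extinction_at(table, wavelengths)
  E <- cbind(HbO2 = ext$eps_hbo2, Hb = ext$eps_hb)
  out <- t(vapply(seq_len(nrow(dA_mat)), function(i) {
    dc <- qr.solve(E, dA_mat[i, ] / L[i, ])
    c(dc[1], dc[2])
  }, numeric(2)))
  data.frame(dHbO2 = out[, 1], dHb = out[, 2],
             dHbT = out[, 1] + out[, 2])
}

#' Mean optical pathlength from the mean time of flight
#'
#' @param m1 mean time of flight, ps.
#' @param n_medium refractive index.
#' @return pathlength, cm.
#' @export
mean_pathlength <- function(m1, n_medium) speed_in_medium(n_medium) * m1
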