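# Protocol-level reports: MEDPHOT linearity/coupling over the 32-phantom
# grid, nEUROPt scan summaries, oximeter comparison fits, and the
# co-oximetry dilution reference.

#' The 32-phantom MEDPHOT grid
#'
#' Labels A-D x 1-8: four nominal reduced scattering values (5 to 20 cm^-1
#' in steps of 5, letters) crossed with eight nominal absorption values
#' (0 to 0.35 cm^-1 in steps of 0.05, digits).
#'
#' @return data.frame with `label`, `letter`, `digit`, `nominal_musp`,
#'   `nominal_mua`.
#' @export
medphot_grid <- function() {
  letters4 <- LETTERS[1:4]
  g <- expand.grid(digit = 1:8, letter = letters4,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(label = paste0(g$letter, g$digit),
             letter = g$letter, digit = g$digit,
             nominal_musp = 5 * match(g$letter, letters4),
             nominal_mua = 0.05 * (g$digit - 1))
}

#' Apply the separation-dependent phantom exclusions
#'
#' At rho = 3 cm the most absorbing phantoms give too little signal and
#' digits 6-8 are excluded (20 phantoms remain); at rho = 2 cm only C8 is
#' excluded (31 remain). The rules are data-driven parameters with these
#' defaults.
#'
#' @param grid data.frame with `label` and `digit` columns (e.g.
#'   [medphot_grid()] or measured results joined to it).
#' @param rho source-detector separation, cm (used to pick default rules).
#' @param exclude_digits,exclude_labels explicit rules overriding the
#'   defaults; both empty (with `rho = NA`) keeps all phantoms.
#' @return the filtered data.frame.
#' @export
apply_exclusions <- function(grid, rho = NA, exclude_digits = NULL,
                             exclude_labels = NULL) {
  stopifnot(all(c("label", "digit") %in% names(grid)))
  if (is.null(exclude_digits) && is.null(exclude_labels)) {
    if (is.na(rho)) {
      exclude_digits <- integer(0)
      exclude_labels <- character(0)
    } else if (rho == 3) {
      exclude_digits <- 6:8
      exclude_labels <- character(0)
    } else if (rho == 2) {
      exclude_digits <- integer(0)
      exclude_labels <- "C8"
    } else {
      stop("apply_exclusions: no exclusion policy for rho = ", rho)
    }
  }
  grid[!(grid$digit %in% exclude_digits) &
       !(grid$label %in% exclude_labels), , drop = FALSE]
}

#' MEDPHOT mean deviation from linearity
#'
#' Within each phantom subset an ordinary least-squares line of measured vs
#' nominal values is fitted; the deviation is the mean of
#' `100 * |measured - line| / line` over the subset's points (fitted-line
#' denominator). Nominal values enter only as the abscissa.
#'
#' @param measured,nominal numeric vectors.
#' @param group subset labels (e.g. the phantom letter for mua rows, the
#'   digit for musp rows).
#' @param grand `"mean"` (default) or `"median"` for the summary row.
#' @return data.frame `group`, `deviation_percent` with attribute
#'   `grand` (the grand mean/median).
#' @export
medphot_linearity <- function(measured, nominal, group, grand = "mean") {
  stopifnot(length(measured) == length(nominal),
            length(measured) == length(group))
  grand <- match.arg(grand, c("mean", "median"))
  out <- do.call(rbind, lapply(unique(group), function(g) {
    i <- group == g
    if (sum(i) < 3) stop("medphot_linearity: < 3 points in subset ", g)
    if (length(unique(nominal[i])) < 2)
      stop("medphot_linearity: degenerate nominal values in subset ", g)
    fitv <- fitted(lm(measured[i] ~ nominal[i]))
    if (any(fitv <= 0))
      stop("medphot_linearity: nonpositive fitted line in subset ", g)
    data.frame(group = g,
               deviation_percent = mean(100 * abs(measured[i] - fitv) /
                                          fitv))
  }))
  attr(out, "grand") <- if (grand == "mean") mean(out$deviation_percent)
                        else median(out$deviation_percent)
  out
}

#' MEDPHOT coupling (crosstalk slope)
#'
#' Ordinary least-squares slope of a measured optical property against the
#' nominal value of the other property (both in cm^-1, so the slope is
#' dimensionless): e.g. measured musp vs nominal mua gives the coupling of
#' a mua change into musp. A slope of `s` means the cross variable changes
#' by `s` cm^-1 per 1 cm^-1 of the driving variable.
#'
#' @param measured measured values of one property, cm^-1.
#' @param nominal_cross nominal values of the other property, cm^-1.
#' @param group subset labels.
#' @param grand `"mean"` or `"median"` summary of `|slope|`-preserving
#'   subset slopes.
#' @return data.frame `group`, `coupling` with attribute `grand`.
#' @export
medphot_coupling <- function(measured, nominal_cross, group,
                             grand = "mean") {
  stopifnot(length(measured) == length(nominal_cross),
            length(measured) == length(group))
  grand <- match.arg(grand, c("mean", "median"))
  out <- do.call(rbind, lapply(unique(group), function(g) {
    i <- group == g
    if (sum(i) < 3) stop("medphot_coupling: < 3 points in subset ", g)
    if (length(unique(nominal_cross[i])) < 2)
      stop("medphot_coupling: degenerate nominal values in subset ", g)
    data.frame(group = g,
               coupling = unname(coef(lm(measured[i] ~
                                           nominal_cross[i]))[2]))
  }))
  attr(out, "grand") <- if (grand == "mean") mean(abs(out$coupling))
                        else median(abs(out$coupling))
  out
}

# parabolic refinement of a discrete extremum (sub-step vertex)
parabolic_peak <- function(x, y, i) {
  n <- length(x)
  if (i <= 1 || i >= n) return(list(x = x[i], y = y[i]))
  d <- (y[i - 1] - 2 * y[i] + y[i + 1])
  if (d == 0) return(list(x = x[i], y = y[i]))
  h <- x[i + 1] - x[i]
  delta <- 0.5 * (y[i - 1] - y[i + 1]) / d
  list(x = x[i] + delta * h, y = y[i] - 0.25 * (y[i - 1] - y[i + 1]) * delta)
}

#' Full width at half maximum of a sampled profile
#'
#' FWHM of `|y|` by linear interpolation of the half-maximum crossings on
#' either side of the peak; `NA` when a side never crosses its half
#' maximum within the sampled range (reported as absent).
#'
#' @param x ordinate (positions or times).
#' @param y profile values.
#' @return FWHM in units of `x`, or `NA`.
#' @export
profile_fwhm <- function(x, y) {
  ya <- abs(y)
  i <- which.max(ya)
  half <- ya[i] / 2
  left <- NA_real_
  for (j in seq(i, 2)) {
    if (ya[j - 1] < half) {
      left <- approx(ya[c(j - 1, j)], x[c(j - 1, j)], half)$y
      break
    }
  }
  right <- NA_real_
  if (i < length(x)) {
    for (j in seq(i, length(x) - 1)) {
      if (ya[j + 1] < half) {
        right <- approx(ya[c(j, j + 1)], x[c(j, j + 1)], half)$y
        break
      }
    }
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  right - left
}

#' nEUROPt scan summary
#'
#' Per-measurand summary of a depth scan and a lateral scan: maximum
#' contrast by magnitude (with parabolic sub-step refinement of the depth),
#' the contrast at a fixed reference depth (linear interpolation), and the
#' full width at half maximum of the lateral profile (linear interpolation
#' of the half-maximum crossings; absent when a profile does not cross its
#' half maximum within the scan).
#'
#' @param depth_scan,lateral_scan [scan_contrasts()] data.frames.
#' @param reference_depth fixed depth for the quoted contrast, cm (1.5 for
#'   the solid phantom preset, 1.2 for the liquid).
#' @return data.frame with `measurand`, `depth_of_max`, `max_contrast`,
#'   `contrast_at_reference`, `fwhm_lateral_cm`.
#' @export
neuropt_summary <- function(depth_scan, lateral_scan,
                            reference_depth = 1.5) {
  meas <- c("dA_early", "dA_total", "dA_late", "dm1", "dV")
  do.call(rbind, lapply(meas, function(m) {
    yd <- depth_scan[[m]]
    xd <- depth_scan$position
    i <- which.max(abs(yd))
    pk <- parabolic_peak(xd, yd, i)
    at_ref <- approx(xd, yd, reference_depth)$y
    fw <- if (!is.null(lateral_scan))
      profile_fwhm(lateral_scan$position, lateral_scan[[m]])
      else NA_real_
    data.frame(measurand = m, depth_of_max = pk$x, max_contrast = pk$y,
               contrast_at_reference = at_ref, fwhm_lateral_cm = fw)
  }))
}

#' Affine comparison of two oximeter StO2 traces
#'
#' Both traces are linearly resampled to a common 10 s grid over their
#' overlapping support; points with the reference trace inside
#' `fit_range` are kept and a first-degree polynomial
#' `StO2_a = a * StO2_b + b` is fitted by ordinary least squares.
#'
#' @param time_a,sto2_a first device: time (s) and StO2 (percent).
#' @param time_b,sto2_b second (reference) device.
#' @param fit_range StO2 window of the reference trace kept for the fit,
#'   percent (default 30-90).
#' @param resample_s common sampling interval, s.
#' @return list with `slope`, `intercept`, `r_squared`, `n_points`.
#' @export
oximeter_comparison <- function(time_a, sto2_a, time_b, sto2_b,
                                fit_range = c(30, 90), resample_s = 10) {
  lo <- max(min(time_a), min(time_b))
  hi <- min(max(time_a), max(time_b))
  if (hi <= lo) stop("oximeter_comparison: no overlapping time support")
  grid <- seq(lo, hi, by = resample_s)
  a <- approx(time_a, sto2_a, grid)$y
  b <- approx(time_b, sto2_b, grid)$y
  keep <- is.finite(a) & is.finite(b) & b >= fit_range[1] & b <= fit_range[2]
  if (sum(keep) < 5)
    stop("oximeter_comparison: fewer than 5 points in the fit range")
  fit <- lm(a[keep] ~ b[keep])
  ss_res <- sum(residuals_of <- fit$residuals^2)
  ss_tot <- sum((a[keep] - mean(a[keep]))^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = 1 - ss_res / ss_tot, n_points = sum(keep))
}

#' Co-oximetry dilution reference for total hemoglobin
#'
#' The erythrocyte bag's total hemoglobin, diluted into the phantom:
#' `HbT_k = bag_tHb * blood_k / (base + blood_k + other_k)` after each
#' addition, with `blood_k` and `other_k` the cumulative blood and
#' non-blood volumes present.
#'
#' @param bag_tHb total hemoglobin of the blood bag, uM.
#' @param blood_ml cumulative blood volume after each addition, ml.
#' @param base_volume_ml base liquid volume (saline), ml.
#' @param other_ml cumulative other additions (e.g. Intralipid), ml;
#'   scalar or vector matching `blood_ml`.
#' @return HbT per addition, uM.
#' @export
co_oximetry_reference <- function(bag_tHb, blood_ml, base_volume_ml,
                                  other_ml = 0) {
  stopifnot(bag_tHb >= 0, all(blood_ml >= 0), base_volume_ml > 0,
            all(other_ml >= 0))
  total <- base_volume_ml + blood_ml + other_ml
  if (any(total <= 0)) stop("co_oximetry_reference: zero total volume")
  bag_tHb * blood_ml / total
}
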