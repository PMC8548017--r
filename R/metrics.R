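# Statistical measurands of DTOFs: background subtraction, thresholded
# moments, time-window counts, perturbation contrasts, differential
# nonlinearity, temporal fluctuations, drift correction and time rebinning.

#' Subtract the background level of a DTOF
#'
#' The background is estimated as the mean of early pre-peak bins: up to
#' `n_bg` bins taken from the start of the histogram, all of which must lie
#' more than `guard_ps` before the peak. Negative residuals are clipped at
#' zero so that downstream moment computations stay well defined.
#'
#' @param d a [dtof()].
#' @param guard_ps guard interval before the peak excluded from the
#'   background region, ps.
#' @param n_bg maximum number of background bins used.
#' @return the background-subtracted [dtof()] (real-valued counts) with the
#'   estimate recorded in `background_level`.
#' @export
subtract_background <- function(d, guard_ps = 500, n_bg = 100) {
  stopifnot(inherits(d, "dtof"))
  peak <- which.max(d$counts)
  cutoff <- peak - ceiling(guard_ps / d$bin_width)
  n_avail <- max(0L, cutoff - 1L)
  if (n_avail < 50L)
    stop("subtract_background: cannot estimate background (peak too early)")
  bg <- mean(d$counts[seq_len(min(n_bg, n_avail))])
  out <- d
  out$counts <- pmax(d$counts - bg, 0)
  out$background_level <- bg
  out
}

#' Statistical moments of a DTOF
#'
#' Total photon count N, mean time of flight m1 (ps) and variance of the
#' time of flight V (ps^2), computed over the contiguous run of bins around
#' the global maximum whose counts exceed `threshold_fraction` of the
#' maximum. Input should be background subtracted. Bin times are at bin
#' centers; no Sheppard correction is applied to V.
#'
#' @param d a [dtof()].
#' @param threshold_fraction fraction of the maximum defining the
#'   integration region (default 1%).
#' @param strict if `TRUE` bins must be strictly greater than the threshold
#'   (as for the fluctuation analysis); if `FALSE`, `>=` (as for the
#'   perturbation contrasts).
#' @param bins optional fixed integration limits `c(first, last)` (1-based
#'   bin indices) overriding the threshold rule. Repeated-acquisition
#'   analyses (temporal fluctuations, drift) should determine the limits
#'   once — e.g. on the summed or expected curve — and reuse them, so that
#'   threshold jitter does not inflate the moment noise above the photon
#'   floor.
#' @return object of class `dtof_moments` with fields `N`, `m1`, `V`,
#'   `threshold_fraction`, `bins_used` (first, last 1-based index).
#' @export
dtof_moments <- function(d, threshold_fraction = 0.01, strict = TRUE,
                         bins = NULL) {
  stopifnot(inherits(d, "dtof"), threshold_fraction >= 0,
            threshold_fraction < 1)
  counts <- d$counts
  if (!is.null(bins)) {
    stopifnot(length(bins) == 2, bins[1] >= 1,
              bins[2] <= length(counts), bins[1] <= bins[2])
    lo <- as.integer(bins[1]); hi <- as.integer(bins[2])
  } else {
    mx <- max(counts)
    if (mx <= 0) stop("dtof_moments: empty above-threshold region")
    thr <- threshold_fraction * mx
    ok <- if (strict) counts > thr else counts >= thr
    peak <- which.max(counts)
    lo <- peak
    while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
    hi <- peak
    while (hi < length(counts) && ok[hi + 1L]) hi <- hi + 1L
  }
  idx <- lo:hi
  t <- dtof_times(d)[idx]
  c_ <- counts[idx]
  N <- sum(c_)
  if (N <= 0) stop("dtof_moments: empty above-threshold region")
  m1 <- sum(t * c_) / N
  V <- sum(t^2 * c_) / N - m1^2
  structure(list(N = N, m1 = m1, V = max(V, 0),
                 threshold_fraction = threshold_fraction,
                 bins_used = c(lo, hi)),
            class = "dtof_moments")
}

#' Photon counts in a time window
#'
#' Counts in the half-open interval `[t_start, t_end)` measured from the
#' IRF maximum (the conventional zero time of the time-window analysis).
#'
#' @param d a [dtof()].
#' @param window numeric `c(t_start, t_end)`, ps relative to the IRF
#'   maximum; `t_end > t_start` (equal gives 0 counts).
#' @param irf_max_time time of the IRF maximum on the DTOF time axis, ps.
#' @return total counts in the window.
#' @export
window_counts <- function(d, window, irf_max_time = 0) {
  stopifnot(inherits(d, "dtof"), length(window) == 2)
  if (window[2] < window[1]) stop("window_counts: t_end must be >= t_start")
  if (window[2] == window[1]) return(0)
  rel <- dtof_times(d) - irf_max_time
  half <- d$bin_width / 2
  if (window[1] < min(rel) - half || window[2] > max(rel) + half)
    stop("window_counts: window outside histogram support")
  sum(d$counts[rel >= window[1] & rel < window[2]])
}

#' Perturbation contrasts of a measured DTOF against a reference
#'
#' Attenuation changes `dA = -ln(N_TW / N_TW0)` for the total count and for
#' early/late time windows, plus moment changes `dm1 = m1_0 - m1` and
#' `dV = V_0 - V`. The reference is the measurement with the perturbation
#' furthest away.
#'
#' @param measured,reference [dtof()]s with identical binning.
#' @param irf_max_time zero time for the windows, ps.
#' @param early,late time windows `c(start, end)` in ps relative to the IRF
#'   maximum (defaults 0.5-1 ns and 3-4 ns).
#' @param threshold_fraction,strict moment threshold parameters, see
#'   [dtof_moments()].
#' @param position optional perturbation position, cm, carried through.
#' @return object of class `contrast_record` with fields `dA_early`,
#'   `dA_total`, `dA_late`, `dm1`, `dV`, `position`.
#' @export
dtof_contrasts <- function(measured, reference, irf_max_time = 0,
                           early = c(500, 1000), late = c(3000, 4000),
                           threshold_fraction = 0.01, strict = TRUE,
                           position = NA_real_) {
  stopifnot(inherits(measured, "dtof"), inherits(reference, "dtof"))
  if (length(measured$counts) != length(reference$counts) ||
      measured$bin_width != reference$bin_width)
    stop("dtof_contrasts: measured and reference binning differ")
  mm <- dtof_moments(measured, threshold_fraction, strict)
  m0 <- dtof_moments(reference, threshold_fraction, strict)
  wins <- list(early = early, late = late)
  dA_tw <- vapply(wins, function(w) {
    n <- window_counts(measured, w, irf_max_time)
    n0 <- window_counts(reference, w, irf_max_time)
    if (n <= 0 || n0 <= 0)
      stop("dtof_contrasts: zero window counts, attenuation undefined")
    -log(n / n0)
  }, numeric(1))
  structure(list(dA_early = unname(dA_tw["early"]),
                 dA_total = -log(mm$N / m0$N),
                 dA_late = unname(dA_tw["late"]),
                 dm1 = m0$m1 - mm$m1,
                 dV = m0$V - mm$V,
                 position = position),
            class = "contrast_record")
}

#' Differential nonlinearity of the TCSPC time base
#'
#' Under constant illumination the counts per bin should be flat; the DNL
#' metric is the peak-to-peak deviation normalized to the mean,
#' `(max - min) / mean`, over the bins inside `t_range`.
#'
#' @param counts counts per bin under constant illumination.
#' @param bin_width bin width, ps.
#' @param t_range time interval `c(lo, hi)`, ps (default 1-10 ns).
#' @return dimensionless epsilon_DNL.
#' @export
epsilon_dnl <- function(counts, bin_width, t_range = c(1000, 10000)) {
  stopifnot(is.numeric(counts), bin_width > 0, length(t_range) == 2,
            t_range[2] > t_range[1])
  t <- (seq_along(counts) - 0.5) * bin_width
  sel <- counts[t >= t_range[1] & t <= t_range[2]]
  if (!length(sel)) stop("epsilon_dnl: empty time range")
  m <- mean(sel)
  if (m <= 0) stop("epsilon_dnl: mean count in range must be > 0")
  (max(sel) - min(sel)) / m
}

#' Temporal fluctuations of DTOF moments
#'
#' Standard deviations of repeated moment measurements: N as percent of its
#' mean, m1 in ps, V in ps^2.
#'
#' @param moments_list list of [dtof_moments()] (>= 2).
#' @return list with `N_rel_sd_percent`, `m1_sd_ps`, `V_sd_ps2`, `n`.
#' @export
temporal_fluctuations <- function(moments_list) {
  stopifnot(length(moments_list) >= 2)
  N <- vapply(moments_list, `[[`, numeric(1), "N")
  m1 <- vapply(moments_list, `[[`, numeric(1), "m1")
  V <- vapply(moments_list, `[[`, numeric(1), "V")
  list(N_rel_sd_percent = 100 * sd(N) / mean(N),
       m1_sd_ps = sd(m1), V_sd_ps2 = sd(V), n = length(N))
}

#' Correct instrument drift using bracketing IRF measurements
#'
#' IRFs measured before and after a session quantify the instrument drift;
#' assuming the drift is linear in time, the interpolated IRF moment offset
#' is removed from each sample: additively for m1 and V, multiplicatively
#' for N.
#'
#' @param series data.frame with columns `timestamp` (s), `N`, `m1`, `V`.
#' @param irf_start,irf_end [dtof_moments()] of the bracketing IRFs.
#' @param t_start,t_end timestamps (s) of the two IRF acquisitions.
#' @return the corrected series (same shape).
#' @export
drift_correct <- function(series, irf_start, irf_end, t_start, t_end) {
  stopifnot(is.data.frame(series),
            all(c("timestamp", "N", "m1", "V") %in% names(series)),
            t_end > t_start)
  if (any(series$timestamp < t_start | series$timestamp > t_end))
    stop("drift_correct: timestamps outside the IRF bracket")
  frac <- (series$timestamp - t_start) / (t_end - t_start)
  out <- series
  out$m1 <- series$m1 - frac * (irf_end$m1 - irf_start$m1)
  out$V <- series$V - frac * (irf_end$V - irf_start$V)
  out$N <- series$N / (1 + frac * (irf_end$N / irf_start$N - 1))
  out
}

#' Sum consecutive DTOFs k at a time
#'
#' Post-acquisition rebinning in time: summing e.g. 3 consecutive 0.3 s
#' frames gives an effective ~1 s sampling with higher signal-to-noise.
#' A non-multiple tail is dropped with a message.
#'
#' @param dtofs list of [dtof()]s with identical binning.
#' @param k positive integer group size.
#' @return list of summed [dtof()]s, `acquisition_time` multiplied by `k`.
#' @export
rebin_time <- function(dtofs, k) {
  if (!is.numeric(k) || k < 1 || k != round(k))
    stop("rebin_time: k must be a positive integer")
  k <- as.integer(k)
  if (k == 1L) return(dtofs)
  n_groups <- length(dtofs) %/% k
  if (length(dtofs) %% k != 0)
    message(sprintf("rebin_time: dropping %d trailing frame(s)",
                    length(dtofs) %% k))
  lapply(seq_len(n_groups), function(g) {
    grp <- dtofs[((g - 1L) * k + 1L):(g * k)]
    out <- grp[[1L]]
    out$counts <- Reduce(`+`, lapply(grp, `[[`, "counts"))
    if (!is.na(out$acquisition_time))
      out$acquisition_time <- out$acquisition_time * k
    out
  })
}
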