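#' Peak filling rate
#'
#' Maximum of the filling-rate curve over diastole (strictly after
#' end-systole, up to the end of the cycle), with ties broken toward the
#' earlier phase.
#'
#' @param rates Rate series from [derivative()] or [raw_rate()].
#' @param fid [find_fiducials()] output for the same curve.
#' @return A list with `pfr` (ml/s) and `pfr_time` (ms from cycle start).
#' @export
peak_filling_rate <- function(rates, fid) {
  dia <- rates$time_ms > fid$es_time & rates$time_ms <= fid$rr_ms
  r <- rates$rate_ml_s[dia]
  t <- rates$time_ms[dia]
  if (length(r) == 0 || all(r <= 0)) {
    abort("no filling detected: all diastolic rates are non-positive",
      class = "lvfill_no_filling"
    )
  }
  i <- which.max(r)
  list(pfr = r[i], pfr_time = t[i])
}

#' Stroke-volume normalized peak filling rate
#'
#' @param pfr Peak filling rate, ml/s.
#' @param sv Stroke volume, ml (`> 0`).
#' @return nPFR in stroke volumes per second.
#' @export
normalized_pfr <- function(pfr, sv) {
  if (sv <= 0) abort("sv must be positive", class = "lvfill_bad_sv")
  pfr / sv
}

#' Time from end-systole to peak filling
#'
#' @param pfr_time Time of the diastolic rate maximum, ms from cycle start.
#' @param fid [find_fiducials()] output.
#' @return TPFR in ms.
#' @export
time_to_pfr <- function(pfr_time, fid) {
  if (pfr_time <= fid$es_time) {
    abort("peak filling must occur after end-systole",
      class = "lvfill_bad_tpfr"
    )
  }
  pfr_time - fid$es_time
}

#' Diastolic volume recovery
#'
#' The percentage of the diastolic interval needed for the volume curve to
#' recover a given fraction (default 80%) of stroke volume above ESV. The
#' crossing time is located by linear interpolation between the bracketing
#' phases (the cycle wrap back to the phase-0 volume is included), so the
#' result is finer than the phase resolution.
#'
#' @param curve Filtered `volume_curve`.
#' @param fid [find_fiducials()] output for `curve`.
#' @param fraction Recovered fraction of stroke volume, in (0, 1).
#' @return DVR as % of diastole.
#' @export
diastolic_volume_recovery <- function(curve, fid, fraction = 0.8) {
  if (fraction <= 0 || fraction >= 1) {
    abort("fraction must lie in (0, 1)", class = "lvfill_bad_fraction")
  }
  target <- fid$esv + fraction * fid$sv
  idx <- seq(fid$es_index, length(curve$volume_ml))
  t <- c(curve$time_ms[idx], fid$rr_ms)
  v <- c(curve$volume_ml[idx], curve$volume_ml[1])
  hit <- which(v >= target)
  hit <- hit[hit > 1]
  if (length(hit) == 0) {
    abort(
      sprintf(
        "recovery target %.2f ml never reached (max diastolic volume %.2f ml)",
        target, max(v)
      ),
      class = "lvfill_dvr_unreached"
    )
  }
  j <- hit[1]
  # linear interpolation inside the bracketing phase interval
  tstar <- t[j - 1] + (t[j] - t[j - 1]) * (target - v[j - 1]) / (v[j] - v[j - 1])
  # a two-point interpolation is ill-conditioned when the curve approaches
  # the target on a flat plateau (the bracketing chord can be nearly
  # horizontal, so noise ripple moves the crossing by tens of ms and the
  # first passage is biased early); a local regression through the phases
  # around the crossing conditions the estimate on the neighborhood slope
  w <- max(2, j - 2):min(length(v), j + 2)
  if (length(w) >= 3) {
    fit <- stats::lm.fit(cbind(1, t[w]), v[w])
    slope <- fit$coefficients[2]
    # on a steep approach shrink the window: the regression is then only
    # correcting interpolation noise and a wide window would pick up
    # curvature bias from the sigmoidal rise
    if (is.finite(slope) && slope >= 0.5 * fid$sv / fid$diastole_duration) {
      w <- max(2, j - 1):min(length(v), j + 1)
      if (length(w) >= 3) fit <- stats::lm.fit(cbind(1, t[w]), v[w])
      slope <- fit$coefficients[2]
    }
    tc <- (target - fit$coefficients[1]) / slope
    if (is.finite(slope) && slope > 0 &&
      is.finite(tc) && tc >= t[w[1]] - 50 && tc <= t[w[length(w)]] + 50) {
      tstar <- tc
    }
  }
  as.numeric(100 * (tstar - fid$es_time) / fid$diastole_duration)
}

#' Early and late diastolic filling peaks (E:A profile)
#'
#' Scans the diastolic filling-rate series for local maxima above a noise
#' floor (default 5% of the peak filling rate). The candidate waves are
#' the global maximum and the tallest other maximum at least
#' `min_separation_ms` away; the earlier of the two is the early (E) wave
#' and the later the atrial (A) wave. (Choosing the tallest separated pair
#' rather than the earliest and latest qualifying maxima keeps residual
#' noise ripples from masquerading as an extra wave.) The two waves are
#' reported as discernable only when at least two peaks exist and the rate
#' dips, between them, below half of the smaller peak; otherwise the ratio
#' is absent (a flagged outcome, not an error), mirroring filling profiles
#' whose E and A waves merge.
#'
#' @inheritParams peak_filling_rate
#' @param noise_floor Peaks below `noise_floor * max(rate)` are ignored.
#' @param valley_frac Required inter-peak dip, as a fraction of the smaller
#'   peak.
#' @param min_separation_ms Minimum E-to-A peak separation; closer maxima
#'   are treated as one (merged) wave.
#' @return A list: `e_peak`, `a_peak` (ml/s), `e_time`, `a_time` (ms),
#'   `ea_ratio` (NA when not discernable), `discernable` (logical).
#' @export
ea_profile <- function(rates, fid, noise_floor = 0.05, valley_frac = 0.5,
                       min_separation_ms = 150) {
  dia <- rates$time_ms > fid$es_time & rates$time_ms <= fid$rr_ms
  r <- rates$rate_ml_s[dia]
  t <- rates$time_ms[dia]
  n <- length(r)
  if (n < 3 || all(r <= 0)) {
    return(list(
      e_peak = NA_real_, a_peak = NA_real_,
      e_time = NA_real_, a_time = NA_real_,
      ea_ratio = NA_real_, discernable = FALSE
    ))
  }
  floor_val <- noise_floor * max(r)
  left <- c(-Inf, r[-n])
  right <- c(r[-1], -Inf)
  is_peak <- r > left & r >= right & r >= floor_val
  pk <- which(is_peak)
  single <- function(i) {
    list(
      e_peak = r[i], a_peak = NA_real_,
      e_time = t[i], a_time = NA_real_,
      ea_ratio = NA_real_, discernable = FALSE
    )
  }
  if (length(pk) < 2) {
    return(single(if (length(pk) == 1) pk else which.max(r)))
  }
  # the global maximum plus the tallest peak at least min_separation_ms
  # away: without the separation requirement, residual noise ripples on
  # the flank of one wide wave would be read as a second wave
  i1 <- pk[which.max(r[pk])]
  far <- pk[abs(t[pk] - t[i1]) >= min_separation_ms]
  if (length(far) == 0) {
    return(single(i1))
  }
  i2 <- far[which.max(r[far])]
  ei <- min(i1, i2)
  ai <- max(i1, i2)
  valley <- min(r[ei:ai])
  disc <- valley < valley_frac * min(r[ei], r[ai])
  list(
    e_peak = r[ei], a_peak = r[ai],
    e_time = t[ei], a_time = t[ai],
    ea_ratio = if (disc) r[ei] / r[ai] else NA_real_,
    discernable = disc
  )
}

#' Left-ventricular mass from epicardial and endocardial volumes
#'
#' Myocardial volume (epicardial minus endocardial end-diastolic volume)
#' times the specific gravity of myocardium, 1.05 g/ml.
#'
#' @param epi_edv Epicardial end-diastolic volume, ml.
#' @param edv Endocardial end-diastolic volume, ml.
#' @return Mass in grams.
#' @export
lv_mass <- function(epi_edv, edv) {
  if (any(epi_edv < edv)) {
    abort("epi_edv must be >= edv", class = "lvfill_bad_mass")
  }
  (epi_edv - edv) * 1.05
}

#' Global infarct size from 17-segment transmurality scores
#'
#' Each segment is scored 0-4 for the transmural extent of delayed
#' hyperenhancement (0 = none, 1 = 1-25%, 2 = 26-50%, 3 = 51-75%,
#' 4 = 76-100%). Global infarct size is the mean over the 17 segments of
#' the midpoint of each score's range: weights 0, 13, 38, 63, 88 percent.
#'
#' @param scores Integer vector of length 17, each in 0..4.
#' @return Infarct size as % of LV myocardium.
#' @export
infarct_size <- function(scores) {
  if (length(scores) != 17 || any(scores != as.integer(scores)) ||
    any(scores < 0 | scores > 4)) {
    abort("scores must be 17 integers in 0..4", class = "lvfill_bad_scores")
  }
  weights <- c(0, 13, 38, 63, 88)
  sum(weights[scores + 1]) / 17
}

#' Compute all diastolic indices for one volume curve
#'
#' The full single-curve chain: low-pass filter, fiducial detection,
#' filling-rate computation, and the diastolic indices (PFR, nPFR, TPFR,
#' DVR, E:A profile).
#'
#' In the default `"derivative"` mode the filling-rate curve is the
#' analytic derivative of the truncated Fourier series, evaluated on a
#' dense time grid. The peak is estimated in two stages: a heavily
#' smoothed rate curve (`pfr_loc_harmonics`) fixes the approximate peak
#' location -- the aggressive band keeps the location estimate from
#' chasing noise maxima -- and the peak is then read off as the nearest
#' local maximum of the standard-band rate curve, which avoids the
#' systematic upward bias a global maximum over a noisy curve incurs.
#'
#' @param curve A `volume_curve`.
#' @param n_harmonics Fourier passband for [lowpass()] and [derivative()].
#' @param pfr_mode `"derivative"` (filtered Fourier derivative, default) or
#'   `"raw_diff"` (raw successive phase differences, the unfiltered
#'   between-phase definition).
#' @param dvr_fraction Recovered stroke-volume fraction for DVR.
#' @param pfr_loc_harmonics Coarse passband used only to locate the peak.
#' @param pfr_amp_harmonics Passband from which the peak amplitude is read
#'   at the located time. Noise in the rate curve grows roughly with the
#'   three-halves power of the passband, so the amplitude read uses a
#'   moderately narrower band than wave detection.
#' @param n_dense Dense evaluation grid size for the rate curve.
#' @return A one-row tibble: `edv`, `esv`, `sv`, `ef`, `pfr_ml_s`,
#'   `pfr_time_ms`, `npfr_per_s`, `tpfr_ms`, `dvr80_pct`, `e_peak`,
#'   `a_peak`, `ea_ratio`, `ea_discernable`.
#' @export
#' @examples
#' pt <- sample_patient("normal", seed = 1)
#' compute_indices(generate_volume_curve(pt, 30, noise_sd = 2, seed = 2))
compute_indices <- function(curve, n_harmonics = 10,
                            pfr_mode = c("derivative", "raw_diff"),
                            dvr_fraction = 0.8, pfr_loc_harmonics = 3,
                            pfr_amp_harmonics = 6, n_dense = 1024) {
  pfr_mode <- match.arg(pfr_mode)
  n_harmonics <- min(n_harmonics, (length(curve$volume_ml) - 1) %/% 2)
  sm <- lowpass(curve, n_harmonics)
  fid <- find_fiducials(sm)
  if (pfr_mode == "raw_diff") {
    rates <- raw_rate(curve)
    pk <- peak_filling_rate(rates, fid)
    ea <- ea_profile(rates, fid)
  } else {
    nh <- n_harmonics
    nl <- min(pfr_loc_harmonics, nh)
    rates <- derivative(curve, nh, n_out = n_dense)
    coarse <- derivative(curve, nl, n_out = n_dense)
    guess <- peak_filling_rate(coarse, fid)
    ea <- ea_profile(rates, fid)
    # amplitude read at the coarse-band peak location rather than as a
    # maximum (a fixed-location read has zero-mean noise; the maximum of a
    # noisy curve is biased upward); timing from the dominant discernable
    # wave when there is one, since the coarse band cannot separate
    # near-merged E and A waves
    pfr_time <- if (ea$discernable) {
      if (ea$e_peak >= ea$a_peak) ea$e_time else ea$a_time
    } else {
      guess$pfr_time
    }
    na <- min(pfr_amp_harmonics, nh)
    amp <- if (na == nh) rates else derivative(curve, na, n_out = n_dense)
    pk <- list(
      pfr = amp$rate_ml_s[which.min(abs(amp$time_ms - guess$pfr_time))],
      pfr_time = pfr_time
    )
  }
  dvr <- diastolic_volume_recovery(sm, fid, dvr_fraction)
  tibble(
    edv = fid$edv, esv = fid$esv, sv = fid$sv, ef = fid$ef,
    pfr_ml_s = pk$pfr, pfr_time_ms = pk$pfr_time,
    npfr_per_s = normalized_pfr(pk$pfr, fid$sv),
    tpfr_ms = time_to_pfr(pk$pfr_time, fid),
    dvr80_pct = dvr,
    e_peak = ea$e_peak, a_peak = ea$a_peak,
    ea_ratio = ea$ea_ratio, ea_discernable = ea$discernable
  )
}

#' Compute diastolic indices for every patient in a cohort
#'
#' @param cohort A cohort tibble with `id`, `grade` and a `curve`
#'   list-column (from [generate_cohort()] or assembled from files).
#' @inheritParams compute_indices
#' @return A tibble with one row per patient: `id`, `grade`, then the
#'   [compute_indices()] columns.
#' @export
cohort_indices <- function(cohort, n_harmonics = 10,
                           pfr_mode = c("derivative", "raw_diff"),
                           dvr_fraction = 0.8) {
  pfr_mode <- match.arg(pfr_mode)
  idx <- purrr::map_dfr(
    cohort$curve,
    compute_indices,
    n_harmonics = n_harmonics, pfr_mode = pfr_mode,
    dvr_fraction = dvr_fraction
  )
  dplyr::bind_cols(cohort %>% select("id", "grade"), idx)
}
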