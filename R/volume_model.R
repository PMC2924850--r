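#' Construct the ground-truth description of one synthetic patient
#'
#' A `patient_truth` object holds the generative parameters of one synthetic
#' left ventricle: chamber volumes, cycle timing, and the two raised-cosine
#' diastolic filling lobes (early "E" and late atrial "A"). All analytic
#' index values implied by these parameters (peak filling rate, time to peak
#' filling, diastolic 80% volume recovery, E:A peak-rate ratio) are computed
#' in closed form and stored, so downstream estimators can be scored against
#' exact ground truth.
#'
#' The volume model is: a smooth half-cosine systolic ramp from EDV at the
#' cycle start down to ESV at `ts_ms`, then two non-overlapping raised-cosine
#' filling-rate lobes inside diastole. A lobe of width `w` ms carrying volume
#' `v` ml has rate `(v/w) * (1 - cos(2*pi*(t - t0)/w))`, so its peak rate is
#' exactly `2*v/w` (ml/ms; reported in ml/s) at the lobe midpoint and it
#' integrates exactly to `v`.
#'
#' @param grade Diastolic-dysfunction grade label: `"normal"`, `"1"`, `"2"`
#'   or `"3"`.
#' @param edv,esv End-diastolic and end-systolic volume, ml.
#' @param rr_ms Cardiac cycle length (RR interval), ms.
#' @param ts_ms Systolic duration, ms (end-systole occurs at `ts_ms`).
#' @param e_fraction Fraction of stroke volume filled by the early (E) lobe,
#'   in `[0, 1]`. `1` gives a single-lobe (E-only) ventricle.
#' @param e_onset_ms,e_width_ms Early-lobe onset (ms after end-systole) and
#'   width (ms).
#' @param a_onset_ms,a_width_ms Late-lobe onset and width, ms after
#'   end-systole. Ignored (forced empty) when `e_fraction == 1`.
#'
#' @return An object of class `patient_truth`: a named list with the
#'   parameters above plus `sv` and the closed-form `analytic_pfr` (ml/s),
#'   `analytic_npfr` (/s), `analytic_tpfr` (ms after end-systole),
#'   `analytic_dvr80` (% of diastole), and `analytic_ea` (unitless; `NA`
#'   for a single-lobe ventricle).
#' @seealso [sample_patient()] to draw grade-typical parameters,
#'   [volume_function()] for the continuous volume curve.
#' @export
#' @examples
#' pt <- patient_truth(
#'   grade = "normal", edv = 151, esv = 66, rr_ms = 1000, ts_ms = 350,
#'   e_fraction = 1, e_onset_ms = 0, e_width_ms = 400
#' )
#' pt$analytic_pfr # exactly 2 * 85 / 0.4 = 425 ml/s
patient_truth <- function(grade, edv, esv, rr_ms, ts_ms = 0.35 * rr_ms,
                          e_fraction, e_onset_ms, e_width_ms,
                          a_onset_ms = NA_real_, a_width_ms = NA_real_) {
  assert_grade(grade)
  if (!(esv > 0 && edv > esv)) {
    abort("need 0 < esv < edv", class = "lvfill_bad_truth")
  }
  if (!(ts_ms > 0 && ts_ms < rr_ms)) {
    abort("need 0 < ts_ms < rr_ms", class = "lvfill_bad_truth")
  }
  if (e_fraction < 0 || e_fraction > 1) {
    abort("e_fraction must lie in [0, 1]", class = "lvfill_bad_truth")
  }
  diastole <- rr_ms - ts_ms
  single <- e_fraction >= 1 - 1e-12
  if (single) {
    a_onset_ms <- NA_real_
    a_width_ms <- NA_real_
    e_fraction <- 1
  }
  if (e_fraction <= 1e-12) {
    abort("e_fraction = 0 (A-only ventricle) is not supported; swap lobes",
      class = "lvfill_bad_truth"
    )
  }
  if (!(e_onset_ms >= 0 && e_width_ms > 0 &&
    e_onset_ms + e_width_ms <= diastole + 1e-9)) {
    abort("E lobe must lie within diastole", class = "lvfill_bad_truth")
  }
  if (!single) {
    if (!(is.finite(a_onset_ms) && is.finite(a_width_ms) && a_width_ms > 0 &&
      a_onset_ms + a_width_ms <= diastole + 1e-9)) {
      abort("A lobe must lie within diastole", class = "lvfill_bad_truth")
    }
    if (a_onset_ms < e_onset_ms + e_width_ms - 1e-9) {
      abort("filling lobes must not overlap (E before A)",
        class = "lvfill_bad_truth"
      )
    }
  }

  truth <- structure(
    list(
      grade = grade, edv = edv, esv = esv, sv = edv - esv,
      rr_ms = rr_ms, ts_ms = ts_ms,
      e_fraction = e_fraction,
      e_onset_ms = e_onset_ms, e_width_ms = e_width_ms,
      a_onset_ms = a_onset_ms, a_width_ms = a_width_ms
    ),
    class = "patient_truth"
  )
  truth[names(analytic_indices(truth))] <- analytic_indices(truth)
  truth
}

#' @export
print.patient_truth <- function(x, ...) {
  cat(
    sprintf(
      paste0(
        "<patient_truth> grade %s | EDV %.1f ESV %.1f SV %.1f ml | RR %.0f ms\n",
        "  analytic: PFR %.1f ml/s, TPFR %.1f ms, DVR80 %.1f%%, E:A %s\n"
      ),
      x$grade, x$edv, x$esv, x$sv, x$rr_ms,
      x$analytic_pfr, x$analytic_tpfr, x$analytic_dvr80,
      if (is.na(x$analytic_ea)) "-" else sprintf("%.2f", x$analytic_ea)
    ),
    ...
  )
  invisible(x)
}

# Cumulative volume (ml) filled by a raised-cosine lobe of volume v and
# width w, at time tau after the lobe onset (clamped outside the lobe).
lobe_cumvol <- function(tau, v, w) {
  x <- pmin(pmax(tau, 0), w)
  v * (x / w - sin(2 * pi * x / w) / (2 * pi))
}

# Instantaneous lobe filling rate, ml/ms.
lobe_rate <- function(tau, v, w) {
  inside <- tau >= 0 & tau <= w
  r <- numeric(length(tau))
  r[inside] <- (v / w) * (1 - cos(2 * pi * tau[inside] / w))
  r
}

# Total diastolic volume filled at time tau (ms) after end-systole.
diastolic_fill <- function(truth, tau) {
  ve <- truth$e_fraction * truth$sv
  out <- lobe_cumvol(tau - truth$e_onset_ms, ve, truth$e_width_ms)
  if (truth$e_fraction < 1) {
    va <- (1 - truth$e_fraction) * truth$sv
    out <- out + lobe_cumvol(tau - truth$a_onset_ms, va, truth$a_width_ms)
  }
  out
}

#' Continuous volume-time model of a synthetic patient
#'
#' Returns the closed-form periodic map from time (ms, modulo the RR
#' interval) to LV volume (ml) implied by a [patient_truth()]: EDV at the
#' cycle start, a half-cosine systolic ramp to ESV at end-systole, then the
#' cumulative raised-cosine filling lobes back up to EDV.
#'
#' @param truth A [patient_truth()].
#' @return A vectorized function `f(t_ms) -> volume_ml`.
#' @export
volume_function <- function(truth) {
  stopifnot(inherits(truth, "patient_truth"))
  force(truth)
  function(t_ms) {
    t <- t_ms %% truth$rr_ms
    v <- numeric(length(t))
    sys <- t <= truth$ts_ms
    v[sys] <- truth$esv +
      (truth$edv - truth$esv) * (1 + cos(pi * t[sys] / truth$ts_ms)) / 2
    v[!sys] <- truth$esv + diastolic_fill(truth, t[!sys] - truth$ts_ms)
    v
  }
}

#' Continuous filling-rate model (dV/dt) of a synthetic patient
#'
#' Exact time derivative of [volume_function()], in ml/s.
#'
#' @inheritParams volume_function
#' @return A vectorized function `f(t_ms) -> rate_ml_per_s`.
#' @export
rate_function <- function(truth) {
  stopifnot(inherits(truth, "patient_truth"))
  force(truth)
  function(t_ms) {
    t <- t_ms %% truth$rr_ms
    r <- numeric(length(t))
    sys <- t <= truth$ts_ms
    r[sys] <- -(truth$edv - truth$esv) *
      (pi / truth$ts_ms) * sin(pi * t[sys] / truth$ts_ms) / 2
    tau <- t[!sys] - truth$ts_ms
    ve <- truth$e_fraction * truth$sv
    rd <- lobe_rate(tau - truth$e_onset_ms, ve, truth$e_width_ms)
    if (truth$e_fraction < 1) {
      va <- (1 - truth$e_fraction) * truth$sv
      rd <- rd + lobe_rate(tau - truth$a_onset_ms, va, truth$a_width_ms)
    }
    r[!sys] <- rd
    r * 1000 # ml/ms -> ml/s
  }
}

# Closed-form diastolic indices implied by the lobe geometry.
analytic_indices <- function(truth) {
  sv <- truth$sv
  ve <- truth$e_fraction * sv
  pe <- 2000 * ve / truth$e_width_ms # ml/s
  if (truth$e_fraction < 1) {
    va <- (1 - truth$e_fraction) * sv
    pa <- 2000 * va / truth$a_width_ms
    ea <- pe / pa
  } else {
    pa <- -Inf
    ea <- NA_real_
  }
  if (pe >= pa) { # earliest lobe wins a tie
    pfr <- pe
    tpfr <- truth$e_onset_ms + truth$e_width_ms / 2
  } else {
    pfr <- pa
    tpfr <- truth$a_onset_ms + truth$a_width_ms / 2
  }
  diastole <- truth$rr_ms - truth$ts_ms
  target <- 0.8 * sv
  f <- function(tau) diastolic_fill(truth, tau) - target
  tstar <- uniroot(f, c(0, diastole), tol = 1e-10)$root
  list(
    analytic_pfr = pfr,
    analytic_npfr = pfr / sv,
    analytic_tpfr = tpfr,
    analytic_dvr80 = 100 * tstar / diastole,
    analytic_ea = ea
  )
}
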