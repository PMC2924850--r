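#' Grade-stratified parameter templates for the synthetic cohort
#'
#' One row per diastolic-dysfunction grade, giving the mean and SD of the
#' end-diastolic volume (ml) and ejection fraction (%; ESV is derived from
#' the two so the chamber volumes stay physiologically coupled), cycle
#' length (RR, ms) and the four target
#' filling indices (nPFR /s, TPFR ms, DVR80 % of diastole, E:A ratio) that
#' [sample_patient()] draws from. The peak-filling-rate target is the
#' sampled nPFR times the sampled stroke volume, which keeps the two
#' indices coupled the way they are in patients. The index and volume moments are those of
#' a post-myocardial-infarction population stratified by echo-assigned
#' diastolic grade; RR means are a package choice (beta-blocked post-MI
#' patients; longer cycles for impaired-relaxation grades keep the slow,
#' late-skewed filling lobes inside diastole).
#'
#' @return A tibble with one row per grade.
#' @export
grade_templates <- function() {
  tibble(
    grade     = dd_grades(),
    edv_mean  = c(151, 141, 149, 220), edv_sd  = c(34, 32, 45, 49),
    ef_mean   = c(57, 55, 54, 41),     ef_sd   = c(8, 9, 12, 10),
    rr_mean   = c(1000, 1100, 1050, 850), rr_sd = c(70, 70, 70, 70),
    npfr_mean = c(3.3, 2.7, 3.0, 4.1), npfr_sd = c(1.2, 0.6, 0.7, 0.8),
    tpfr_mean = c(174, 321, 221, 136), tpfr_sd = c(119, 205, 136, 36),
    dvr_mean  = c(65, 81, 73, 58),     dvr_sd  = c(16, 5, 13, 15),
    ea_mean   = c(3.1, 1.1, 1.9, 4.8), ea_sd   = c(2.4, 0.4, 1.4, 3.3)
  )
}

# Achieved DVR80 (% of diastole) for a candidate lobe geometry.
dvr_of_geometry <- function(sv, f, eo, ew, ao, aw, diastole) {
  target <- 0.8 * sv
  cum <- function(tau) {
    out <- lobe_cumvol(tau - eo, f * sv, ew)
    if (f < 1) out <- out + lobe_cumvol(tau - ao, (1 - f) * sv, aw)
    out - target
  }
  100 * uniroot(cum, c(0, diastole), tol = 1e-9)$root / diastole
}

# Solve two-lobe geometry hitting the sampled index targets as closely as
# the one-cycle raised-cosine form allows. The lobe peaks are fixed by the
# PFR and E:A targets (rescaled together only when even the narrowest
# admissible split cannot fit inside the longest admissible diastole), so
# PFR and E:A are exact up to that rescaling. The filling lobes are packed
# immediately after end-systole (no isovolumic flat segment, so the
# volumetric minimum is a unique, detectable point), and DVR80 is matched
# through the systolic duration: with the packed pattern's 80%-recovery
# time t0 fixed for a given E-volume fraction, dvr = 100 * t0 / (rr - ts)
# inverts exactly in ts within physiologic bounds (28-48% of RR). Among
# E-fractions that reach the DVR target, the one whose peak-filling time
# lands closest to the TPFR target wins. Priority under infeasibility:
# PFR > E:A > DVR80 > TPFR.
solve_lobes <- function(sv, rr, pfr_t, tpfr_t, dvr_t, ea_t) {
  ts_lim <- c(0.28, 0.48) * rr
  cap <- 0.97 * (rr - ts_lim[1])
  e_dom <- ea_t >= 1
  if (e_dom) {
    pe <- pfr_t
    pa <- pfr_t / ea_t
  } else {
    pa <- pfr_t
    pe <- pfr_t * ea_t
  }

  span <- function(f) 2000 * sv * (f / pe + (1 - f) / pa)
  f_lim <- c(0.05, 0.98)
  min_span <- min(span(f_lim[1]), span(f_lim[2]))
  if (min_span > cap) {
    scale <- min_span / cap
    pe <- pe * scale
    pa <- pa * scale
  }

  # admissible f interval under span(f) <= cap
  c0 <- 2000 * sv / pa
  c1 <- 2000 * sv * (1 / pe - 1 / pa)
  if (abs(c1) < 1e-12) {
    f_rng <- f_lim
  } else if (c1 > 0) {
    f_rng <- c(f_lim[1], min(f_lim[2], (cap - c0) / c1))
  } else {
    f_rng <- c(max(f_lim[1], (cap - c0) / c1), f_lim[2])
  }
  f_rng <- sort(pmin(pmax(f_rng, f_lim[1]), f_lim[2]))

  cand <- lapply(seq(f_rng[1], f_rng[2], length.out = 25), function(f) {
    ew <- 2000 * f * sv / pe
    aw <- 2000 * (1 - f) * sv / pa
    ts_hi <- min(ts_lim[2], rr - (ew + aw) / 0.995)
    if (ts_hi < ts_lim[1] - 1e-6) {
      return(NULL)
    }
    ts_hi <- max(ts_hi, ts_lim[1])
    # 80%-recovery time of the packed pattern, from end-systole
    t0 <- local({
      target <- 0.8 * sv
      cum <- function(tau) {
        lobe_cumvol(tau, f * sv, ew) +
          lobe_cumvol(tau - ew, (1 - f) * sv, aw) - target
      }
      uniroot(cum, c(0, ew + aw), tol = 1e-7)$root
    })
    ts <- min(max(rr - 100 * t0 / dvr_t, ts_lim[1]), ts_hi)
    dvr_err <- abs(dvr_t - 100 * t0 / (rr - ts))
    tpfr_ach <- if (pe >= pa) ew / 2 else ew + aw / 2
    list(
      f = f, ts = ts, eo = 0, ew = ew, ao = ew, aw = aw,
      dvr_err = dvr_err, tpfr_err = abs(tpfr_ach - tpfr_t)
    )
  })
  cand <- cand[!vapply(cand, is.null, logical(1))]
  dvr_errs <- vapply(cand, `[[`, numeric(1), "dvr_err")
  tpfr_errs <- vapply(cand, `[[`, numeric(1), "tpfr_err")
  ok <- dvr_errs <= min(dvr_errs) + 0.1
  best <- which(ok)[which.min(tpfr_errs[ok])]
  cand[[best]][c("f", "ts", "eo", "ew", "ao", "aw")]
}

#' Draw one synthetic patient of a given diastolic grade
#'
#' Samples chamber volumes, cycle timing and target filling indices from the
#' grade's template distribution (truncated normal at 2.5 SD plus hard
#' physiologic floors), then solves a two-lobe raised-cosine filling geometry
#' that realizes those targets. The returned [patient_truth()] stores the
#' analytic index values implied by the final geometry — the exact ground
#' truth used by recovery tests — which can differ from the sampled targets
#' when a target combination is not geometrically realizable in one cycle.
#'
#' @param grade `"normal"`, `"1"`, `"2"` or `"3"`.
#' @param seed Optional integer; when given, the draw is reproducible and
#'   the caller's RNG stream is left untouched.
#' @param overrides Optional named list. Names matching [grade_templates()]
#'   columns (e.g. `pfr_mean`) override distribution parameters; names
#'   matching truth fields (`edv`, `esv`, `rr_ms`, `ts_ms`, `e_fraction`,
#'   `e_onset_ms`, `e_width_ms`, `a_onset_ms`, `a_width_ms`) pin those
#'   values directly. Infeasible pinned geometry (e.g. lobes wider than
#'   diastole) is rejected.
#' @return A [patient_truth()].
#' @export
#' @examples
#' sample_patient("3", seed = 7)
sample_patient <- function(grade, seed = NULL, overrides = NULL) {
  assert_grade(grade)
  tmpl <- as.list(grade_templates()[grade_templates()$grade == grade, ])
  truth_fields <- c(
    "edv", "esv", "rr_ms", "ts_ms", "e_fraction",
    "e_onset_ms", "e_width_ms", "a_onset_ms", "a_width_ms"
  )
  pinned <- list()
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), c(names(tmpl), truth_fields))
    if (length(bad)) {
      abort(paste0("unknown override(s): ", paste(bad, collapse = ", ")),
        class = "lvfill_bad_override"
      )
    }
    tmpl <- modifyList(tmpl, overrides[names(overrides) %in% names(tmpl)])
    pinned <- overrides[names(overrides) %in% truth_fields]
  }
  if (any(unlist(tmpl[-1]) <= 0)) {
    abort("template distribution parameters must be positive",
      class = "lvfill_bad_override"
    )
  }

  with_seed_if(seed, {
    edv <- rtruncnorm(1, tmpl$edv_mean, tmpl$edv_sd, lower = 60)
    ef <- rtruncnorm(1, tmpl$ef_mean, tmpl$ef_sd, lower = 20, upper = 75)
    esv <- edv * (1 - ef / 100)
    rr <- rtruncnorm(1, tmpl$rr_mean, tmpl$rr_sd, lower = 600, upper = 1500)
    npfr_t <- rtruncnorm(1, tmpl$npfr_mean, tmpl$npfr_sd, lower = 1.6)
    tpfr_t <- rtruncnorm(1, tmpl$tpfr_mean, tmpl$tpfr_sd, lower = 40)
    dvr_t <- rtruncnorm(1, tmpl$dvr_mean, tmpl$dvr_sd, lower = 25, upper = 95)
    ea_t <- rtruncnorm(1, tmpl$ea_mean, tmpl$ea_sd, lower = 0.3, upper = 12)

    if ("edv" %in% names(pinned)) edv <- pinned$edv
    if ("esv" %in% names(pinned)) esv <- pinned$esv
    if ("rr_ms" %in% names(pinned)) rr <- pinned$rr_ms
    tpfr_t <- min(max(tpfr_t, 40), 0.6 * rr)
    pfr_t <- npfr_t * (edv - esv)

    geom <- solve_lobes(edv - esv, rr, pfr_t, tpfr_t, dvr_t, ea_t)
    args <- list(
      grade = grade, edv = edv, esv = esv, rr_ms = rr, ts_ms = geom$ts,
      e_fraction = geom$f,
      e_onset_ms = geom$eo, e_width_ms = geom$ew,
      a_onset_ms = geom$ao, a_width_ms = geom$aw
    )
    args <- modifyList(args, pinned)
    do.call(patient_truth, args)
  })
}

new_volume_curve <- function(time_ms, volume_ml, rr_ms,
                             provenance = "analytic", truth = NULL) {
  out <- tibble(time_ms = time_ms, volume_ml = volume_ml)
  attr(out, "rr_ms") <- rr_ms
  attr(out, "provenance") <- provenance
  if (!is.null(truth)) attr(out, "truth") <- truth
  class(out) <- c("volume_curve", class(out))
  out
}

#' Sample a volume-time curve from a synthetic patient
#'
#' Samples [volume_function()] at uniformly spaced cardiac phases and adds
#' i.i.d. Gaussian segmentation noise, emulating the per-phase volume series
#' a short-axis cine segmentation produces.
#'
#' @inheritParams volume_function
#' @param n_phases Number of reconstructed phases per cycle. Default picks
#'   the count whose phase spacing is closest to 36.5 ms (a typical cine
#'   reconstructed temporal resolution), with a floor of 12.
#' @param noise_sd SD of additive volume noise, ml (`>= 0`).
#' @param seed Optional integer for a reproducible draw.
#' @return A `volume_curve`: a tibble with `time_ms`, `volume_ml`, plus
#'   `rr_ms`, `provenance` and the generating truth as attributes.
#' @export
generate_volume_curve <- function(truth, n_phases = NULL, noise_sd = 0,
                                  seed = NULL) {
  stopifnot(inherits(truth, "patient_truth"))
  n_phases <- n_phases %||% max(12L, as.integer(round(truth$rr_ms / 36.5)))
  if (n_phases < 12) {
    abort("n_phases must be at least 12", class = "lvfill_bad_curve")
  }
  if (noise_sd < 0) {
    abort("noise_sd must be non-negative", class = "lvfill_bad_curve")
  }
  times <- (seq_len(n_phases) - 1) * truth$rr_ms / n_phases
  clean <- volume_function(truth)(times)
  vols <- with_seed_if(seed, clean + rnorm(n_phases, 0, noise_sd))
  new_volume_curve(times, vols, truth$rr_ms,
    provenance = "analytic", truth = truth
  )
}

# Uniform-within-criteria echo sampling ranges per grade. Open-ended
# criteria are bounded at physiologic limits (grade-1 DT up to 340 ms,
# grade-3 DT down to 80 ms, grade-3 E/A up to 5, e' floor 2 cm/s).
echo_ranges <- function(grade) {
  switch(grade,
    normal = list(
      ea = c(0.8, 2.0), se = c(8, 14), le = c(10, 16), dt = c(140, 240)
    ),
    "1" = list(
      ea = c(0.3, 0.79), se = c(2, 7.9), le = c(2, 9.9), dt = c(241, 340)
    ),
    "2" = list(
      ea = c(0.8, 1.5), se = c(2, 7.9), le = c(2, 9.9), dt = c(140, 240)
    ),
    "3" = list(
      ea = c(2, 5), se = c(2, 7.9), le = c(2, 9.9), dt = c(80, 139)
    )
  )
}

#' Sample an echocardiographic parameter panel consistent with a DD grade
#'
#' Draws mitral inflow E/A, septal and lateral tissue-Doppler e', and
#' deceleration time uniformly inside the grade's diagnostic criteria, so
#' every sampled panel re-grades to its generating grade under
#' [grade_echo()]. Tissue-Doppler e'/a' ratios are also emitted: below 1
#' for the dysfunction grades, above 1 for normals.
#'
#' @inheritParams sample_patient
#' @return A one-row tibble with columns `e_over_a`, `septal_e_prime`,
#'   `lateral_e_prime`, `dt_ms`, `eprime_over_aprime_septal`,
#'   `eprime_over_aprime_lateral`.
#' @export
sample_echo_panel <- function(grade, seed = NULL) {
  assert_grade(grade)
  rg <- echo_ranges(grade)
  with_seed_if(seed, {
    epap <- if (grade == "normal") runif(2, 1.05, 1.8) else runif(2, 0.4, 0.95)
    tibble(
      e_over_a = runif(1, rg$ea[1], rg$ea[2]),
      septal_e_prime = runif(1, rg$se[1], rg$se[2]),
      lateral_e_prime = runif(1, rg$le[1], rg$le[2]),
      dt_ms = runif(1, rg$dt[1], rg$dt[2]),
      eprime_over_aprime_septal = epap[1],
      eprime_over_aprime_lateral = epap[2]
    )
  })
}

#' Specify a synthetic cohort
#'
#' @param counts Named integer vector of patients per grade. The default
#'   40/21/45/9 mirrors a 115-patient post-MI population with 40 normals and
#'   mild/moderate/severe dysfunction in 21/45/9.
#' @param n_phases Phases per cardiac cycle for the sampled curves.
#' @param noise_sd Additive volume noise SD, ml.
#' @param seed Optional integer seed making the whole cohort reproducible.
#' @param overrides Optional per-grade override list passed to
#'   [sample_patient()] (a single list applied to every grade, or a named
#'   list of lists keyed by grade).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(counts = c(normal = 40, "1" = 21, "2" = 45, "3" = 9),
                        n_phases = 30, noise_sd = 2, seed = NULL,
                        overrides = NULL) {
  counts <- counts[dd_grades()[dd_grades() %in% names(counts)]]
  if (!all(names(counts) %in% dd_grades()) || any(counts < 0)) {
    abort("counts must be named by grade and non-negative",
      class = "lvfill_bad_spec"
    )
  }
  if (n_phases < 12) abort("n_phases must be >= 12", class = "lvfill_bad_spec")
  if (noise_sd < 0) abort("noise_sd must be >= 0", class = "lvfill_bad_spec")
  structure(
    list(
      counts = counts, n_phases = n_phases, noise_sd = noise_sd,
      seed = seed, overrides = overrides
    ),
    class = "cohort_spec"
  )
}

#' Generate a grade-stratified synthetic cohort
#'
#' Draws, for every patient: a ground-truth filling geometry
#' ([sample_patient()]), a noisy sampled volume curve
#' ([generate_volume_curve()]) and a grade-consistent echo panel
#' ([sample_echo_panel()]).
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per patient: `id`, `grade`, the echo
#'   columns, the analytic ground-truth indices (`analytic_pfr`,
#'   `analytic_npfr`, `analytic_tpfr`, `analytic_dvr80`, `analytic_ea`,
#'   `edv`, `esv`, `sv`, `rr_ms`), and list-columns `truth` and `curve`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(
#'   counts = c(normal = 2, "3" = 2), seed = 1
#' ))
#' cohort$grade
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  grades <- rep(names(spec$counts), times = spec$counts)
  if (length(grades) == 0) {
    return(tibble(
      id = character(), grade = character(),
      truth = list(), curve = list()
    ))
  }
  with_seed_if(spec$seed, {
    rows <- purrr::imap(grades, function(g, i) {
      ov <- spec$overrides
      if (!is.null(ov) && !is.null(names(ov)) && any(names(ov) %in% dd_grades())) {
        ov <- ov[[g]]
      }
      truth <- sample_patient(g, overrides = ov)
      curve <- generate_volume_curve(truth, spec$n_phases, spec$noise_sd)
      echo <- sample_echo_panel(g)
      dplyr::bind_cols(
        tibble(
          id = sprintf("pt%03d", i), grade = g,
          edv = truth$edv, esv = truth$esv, sv = truth$sv,
          rr_ms = truth$rr_ms,
          analytic_pfr = truth$analytic_pfr,
          analytic_npfr = truth$analytic_npfr,
          analytic_tpfr = truth$analytic_tpfr,
          analytic_dvr80 = truth$analytic_dvr80,
          analytic_ea = truth$analytic_ea
        ),
        echo,
        tibble(truth = list(truth), curve = list(curve))
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Write a cohort to disk as plain-text files
#'
#' Writes `patients.csv` (truth parameters, analytic indices and echo
#' panel), a `curves/` directory of two-column `time_ms,volume_ml` files,
#' and a `manifest.json` recording the generating spec and seed.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param spec The generating [cohort_spec()], recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, spec = NULL) {
  dir.create(file.path(dir, "curves"), recursive = TRUE, showWarnings = FALSE)
  flat <- cohort %>%
    select(-dplyr::any_of(c("truth", "curve"))) %>%
    dplyr::bind_cols(
      purrr::map_dfr(cohort$truth, function(tr) {
        tibble(
          ts_ms = tr$ts_ms, e_fraction = tr$e_fraction,
          e_onset_ms = tr$e_onset_ms, e_width_ms = tr$e_width_ms,
          a_onset_ms = tr$a_onset_ms, a_width_ms = tr$a_width_ms
        )
      })
    )
  write.csv(flat, file.path(dir, "patients.csv"), row.names = FALSE)
  purrr::walk2(cohort$curve, cohort$id, function(cv, id) {
    write_volume_curve(cv, file.path(dir, "curves", paste0(id, ".csv")))
  })
  manifest <- list(
    package = "lvfill",
    version = as.character(utils::packageVersion("lvfill")),
    n_patients = nrow(cohort),
    seed = if (is.null(spec)) NULL else spec$seed,
    spec = if (is.null(spec)) {
      NULL
    } else {
      list(
        counts = as.list(spec$counts), n_phases = spec$n_phases,
        noise_sd = spec$noise_sd
      )
    }
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, null = "null"
  )
  invisible(dir)
}
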