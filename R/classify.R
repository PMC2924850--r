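#' Diagnostic thresholds for the cine-CMR filling indices
#'
#' Default cutoffs: diastolic volume recovery abnormal above 77% of
#' diastole (normal filling recovers 80% of stroke volume in under 77% of
#' diastole), time to peak filling abnormal above 221 ms, peak filling
#' rate abnormal above 344 ml/s, and stroke-volume normalized peak filling
#' rate abnormal above 4.02/s. All inequalities are strict: a value equal
#' to the cutoff is on the normal side.
#'
#' @param dvr80_cut,tpfr_cut,pfr_cut,npfr_cut Cutoff values.
#' @param directions Named character vector giving the abnormal side
#'   (`"above"` or `"below"`) per index.
#' @return A `dd_thresholds` list.
#' @export
dd_thresholds <- function(dvr80_cut = 77, tpfr_cut = 221, pfr_cut = 344,
                          npfr_cut = 4.02,
                          directions = c(
                            dvr80 = "above", tpfr = "above",
                            pfr = "above", npfr = "above"
                          )) {
  cuts <- c(dvr80 = dvr80_cut, tpfr = tpfr_cut, pfr = pfr_cut, npfr = npfr_cut)
  if (any(cuts <= 0) || !all(directions %in% c("above", "below"))) {
    abort("thresholds must be positive and directions 'above' or 'below'",
      class = "lvfill_bad_thresholds"
    )
  }
  structure(list(cuts = cuts, directions = directions[names(cuts)]),
    class = "dd_thresholds"
  )
}

flag_abnormal <- function(value, cut, direction) {
  if (direction == "above") value > cut else value < cut
}

#' Flag abnormal cine-CMR filling indices
#'
#' Applies the index thresholds to a per-patient index table, adding one
#' logical flag column per index plus the aggregate dysfunction criterion.
#'
#' @param indices Index table from [cohort_indices()] (or any tibble with
#'   `dvr80_pct`, `tpfr_ms`, `pfr_ml_s`, `npfr_per_s`).
#' @param thresholds A [dd_thresholds()].
#' @return `indices` with added logical columns `prolonged_dvr`,
#'   `long_tpfr`, `high_pfr`, `high_npfr`, `aggregate_abnormal`.
#' @export
classify_cmr <- function(indices, thresholds = dd_thresholds()) {
  stopifnot(inherits(thresholds, "dd_thresholds"))
  cuts <- thresholds$cuts
  dirs <- thresholds$directions
  indices %>%
    mutate(
      prolonged_dvr = flag_abnormal(.data$dvr80_pct, cuts["dvr80"], dirs["dvr80"]),
      long_tpfr = flag_abnormal(.data$tpfr_ms, cuts["tpfr"], dirs["tpfr"]),
      high_pfr = flag_abnormal(.data$pfr_ml_s, cuts["pfr"], dirs["pfr"]),
      high_npfr = flag_abnormal(.data$npfr_per_s, cuts["npfr"], dirs["npfr"]),
      aggregate_abnormal = aggregate_criterion(
        .data$prolonged_dvr, .data$high_pfr
      )
    )
}

#' Aggregate dysfunction criterion
#'
#' A patient is flagged as having abnormal diastolic filling when either
#' diastolic volume recovery is prolonged (sensitive to impaired
#' relaxation) or peak filling rate is high (sensitive to restrictive
#' filling) — the disjunction of the two complementary flags.
#'
#' @param prolonged_dvr,high_pfr Logical flags.
#' @return Logical.
#' @export
aggregate_criterion <- function(prolonged_dvr, high_pfr) {
  prolonged_dvr | high_pfr
}

#' Grade diastolic dysfunction from echocardiographic criteria
#'
#' Applies the four grading rules in order (normal, then grades 1 to 3;
#' first match wins):
#' * normal: E/A >= 0.8, septal e' >= 8 cm/s, lateral e' >= 10 cm/s,
#'   DT 140-240 ms
#' * grade 1 (mild): E/A < 0.8, septal e' < 8, lateral e' < 10, DT > 240 ms
#' * grade 2 (moderate): E/A 0.8-1.5, septal e' < 8, lateral e' < 10,
#'   DT 140-240 ms
#' * grade 3 (severe): E/A >= 2, septal e' < 8, lateral e' < 10, DT < 140 ms
#'
#' Panels matching no rule return `"indeterminate"` — never silently
#' coerced. Equivocal tissue Doppler (abnormal lateral but normal septal
#' e') is resolved using e'/a' reversal when supplied: with e'/a' < 1 the
#' e' criteria are treated as dysfunctional and the E/A + DT rules decide
#' the grade; without it the panel stays indeterminate.
#'
#' @param panel A data frame with columns `e_over_a`, `septal_e_prime`,
#'   `lateral_e_prime`, `dt_ms` and optionally
#'   `eprime_over_aprime_septal` / `eprime_over_aprime_lateral` (one row
#'   per patient).
#' @return A character vector of grades
#'   (`"normal"`, `"1"`, `"2"`, `"3"`, `"indeterminate"`).
#' @export
#' @examples
#' grade_echo(data.frame(
#'   e_over_a = 0.7, septal_e_prime = 6, lateral_e_prime = 8, dt_ms = 260
#' ))
grade_echo <- function(panel) {
  needed <- c("e_over_a", "septal_e_prime", "lateral_e_prime", "dt_ms")
  if (!all(needed %in% names(panel))) {
    abort(paste("panel needs columns:", paste(needed, collapse = ", ")),
      class = "lvfill_bad_panel"
    )
  }
  if (any(panel[needed] <= 0, na.rm = TRUE)) {
    abort("echo panel values must be strictly positive",
      class = "lvfill_bad_panel"
    )
  }
  vapply(seq_len(nrow(panel)), function(i) {
    ea <- panel$e_over_a[i]
    se <- panel$septal_e_prime[i]
    le <- panel$lateral_e_prime[i]
    dt <- panel$dt_ms[i]
    if (ea >= 0.8 && se >= 8 && le >= 10 && dt >= 140 && dt <= 240) {
      return("normal")
    }
    low_e <- se < 8 && le < 10
    if (low_e && ea < 0.8 && dt > 240) {
      return("1")
    }
    if (low_e && ea >= 0.8 && ea <= 1.5 && dt >= 140 && dt <= 240) {
      return("2")
    }
    if (low_e && ea >= 2 && dt < 140) {
      return("3")
    }
    # equivocal tissue Doppler: abnormal lateral, normal septal amplitude
    if (le < 10 && se >= 8) {
      rev_sept <- panel[["eprime_over_aprime_septal"]][i] %||% NA_real_
      rev_lat <- panel[["eprime_over_aprime_lateral"]][i] %||% NA_real_
      reversed <- isTRUE(rev_sept < 1) || isTRUE(rev_lat < 1)
      if (reversed) {
        if (ea < 0.8 && dt > 240) {
          return("1")
        }
        if (ea >= 0.8 && ea <= 1.5 && dt >= 140 && dt <= 240) {
          return("2")
        }
        if (ea >= 2 && dt < 140) {
          return("3")
        }
      }
    }
    "indeterminate"
  }, character(1))
}

#' Calibrate an index cutoff at a matched specificity
#'
#' Scans candidate cutoffs (midpoints between sorted distinct values of
#' the normal group, plus one candidate below the minimum and one above
#' the maximum) and returns the most sensitive cutoff whose specificity on
#' the normal group reaches the target: the smallest such cutoff when the
#' abnormal side is `"above"`, the largest when `"below"`. This is how a
#' cohort-specific cutoff is matched to a reference index's specificity
#' (e.g. 83%, 33/40 normals correctly classified).
#'
#' @param normal_values Index values of the normal group (length >= 5).
#' @param direction Abnormal side, `"above"` or `"below"`.
#' @param target_specificity Required specificity, in (0, 1).
#' @return The cutoff, with attributes `specificity` (achieved fraction)
#'   and `n_normal`.
#' @export
#' @examples
#' calibrate_threshold(1:40, "above", 33 / 40) # leaves 7 of 40 above
calibrate_threshold <- function(normal_values, direction = c("above", "below"),
                                target_specificity = 0.83) {
  direction <- match.arg(direction)
  v <- sort(unique(normal_values))
  if (length(normal_values) < 5) {
    abort("need at least 5 normal values", class = "lvfill_bad_calibration")
  }
  if (target_specificity <= 0 || target_specificity >= 1) {
    abort("target_specificity must lie in (0, 1)",
      class = "lvfill_bad_calibration"
    )
  }
  step <- if (length(v) > 1) min(diff(v)) / 2 else max(abs(v[1]) * 1e-6, 1e-6)
  cands <- c(v[1] - step, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2,
    v[length(v)] + step
  )
  spec <- vapply(cands, function(cut) {
    mean(!flag_abnormal(normal_values, cut, direction))
  }, numeric(1))
  ok <- spec >= target_specificity - 1e-12
  if (!any(ok)) {
    abort("target specificity unattainable on these values",
      class = "lvfill_calibration_unattainable"
    )
  }
  cut <- if (direction == "above") min(cands[ok]) else max(cands[ok])
  structure(cut,
    specificity = spec[match(cut, cands)],
    n_normal = length(normal_values)
  )
}

#' Confusion matrix and diagnostic metrics for paired predictions
#'
#' Cross-tabulates predicted abnormality against true labels and reports
#' sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy, positive
#' and negative predictive value, each both as a fraction and as an
#' integer percent (round half up). A metric with a zero denominator is
#' reported as `NA`.
#'
#' @param predicted Logical vector of predicted-abnormal flags.
#' @param truth Logical vector of true-abnormal labels (same length).
#' @return A one-row tibble: `tp`, `fn`, `fp`, `tn`, the five metric
#'   fractions, and `*_pct` integer-percent columns.
#' @export
#' @examples
#' diagnostic_performance(
#'   predicted = rep(c(TRUE, FALSE, TRUE, FALSE), c(15, 6, 7, 33)),
#'   truth = rep(c(TRUE, FALSE), c(21, 40))
#' )
diagnostic_performance <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    abort("predicted and truth must have equal length",
      class = "lvfill_length_mismatch"
    )
  }
  tp <- sum(predicted & truth)
  fn <- sum(!predicted & truth)
  fp <- sum(predicted & !truth)
  tn <- sum(!predicted & !truth)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  acc <- ratio(tp + tn, tp + fn + fp + tn)
  ppv <- ratio(tp, tp + fp)
  npv <- ratio(tn, tn + fn)
  tibble(
    tp = tp, fn = fn, fp = fp, tn = tn,
    sensitivity = sens, specificity = spec, accuracy = acc,
    ppv = ppv, npv = npv,
    sensitivity_pct = round_half_up(100 * sens),
    specificity_pct = round_half_up(100 * spec),
    accuracy_pct = round_half_up(100 * acc),
    ppv_pct = round_half_up(100 * ppv),
    npv_pct = round_half_up(100 * npv)
  )
}
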