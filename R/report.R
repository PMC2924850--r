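#' Per-grade diagnostic-performance report for the cine-CMR indices
#'
#' For each dysfunction grade and each index flag, patients of that grade
#' are tested against the common normal group: predicted = the index flag,
#' truth = membership in the grade. Thresholds can be the shipped defaults
#' or cohort-calibrated via [calibrate_cohort_thresholds()].
#'
#' @param indices Index table from [cohort_indices()], with a `grade`
#'   column containing `"normal"` and graded labels.
#' @param thresholds A [dd_thresholds()].
#' @param flags Which flags to report.
#' @return A `dd_report`: tibble with `grade`, `index`, `threshold`,
#'   `direction`, the confusion counts and metrics of
#'   [diagnostic_performance()]; thresholds kept as an attribute.
#' @export
diagnostic_report <- function(indices, thresholds = dd_thresholds(),
                              flags = c(
                                "prolonged_dvr", "long_tpfr",
                                "high_pfr", "high_npfr",
                                "aggregate_abnormal"
                              )) {
  flagged <- classify_cmr(indices, thresholds)
  graded <- setdiff(unique(flagged$grade), c("normal", "indeterminate"))
  graded <- graded[order(graded)]
  cut_of <- c(
    prolonged_dvr = unname(thresholds$cuts["dvr80"]),
    long_tpfr = unname(thresholds$cuts["tpfr"]),
    high_pfr = unname(thresholds$cuts["pfr"]),
    high_npfr = unname(thresholds$cuts["npfr"]),
    aggregate_abnormal = NA_real_
  )
  dir_of <- c(thresholds$directions, aggregate_abnormal = NA_character_)
  names(dir_of) <- names(cut_of)
  rows <- purrr::map_dfr(graded, function(g) {
    sub <- flagged %>% filter(.data$grade %in% c(g, "normal"))
    purrr::map_dfr(flags, function(fl) {
      dplyr::bind_cols(
        tibble(
          grade = g, index = fl,
          threshold = cut_of[[fl]], direction = dir_of[[fl]]
        ),
        diagnostic_performance(sub[[fl]], sub$grade == g)
      )
    })
  })
  structure(rows,
    class = c("dd_report", class(rows)),
    thresholds = thresholds
  )
}

#' Calibrate cohort-specific thresholds at a matched specificity
#'
#' Mirrors the matched-specificity design: the diastolic-volume-recovery
#' cutoff is fixed at its normative value (abnormal above 77% of
#' diastole), its achieved specificity on the cohort's normal group is
#' measured, and the TPFR, PFR and nPFR cutoffs are then calibrated with
#' [calibrate_threshold()] to reach (at least) that same specificity.
#'
#' @param indices Index table with a `grade` column.
#' @param dvr80_cut Fixed normative DVR cutoff, % of diastole.
#' @param target_specificity Optional explicit target; default is the
#'   specificity the fixed DVR cutoff achieves on the normals.
#' @return A [dd_thresholds()] with calibrated cutoffs and attribute
#'   `target_specificity`.
#' @export
calibrate_cohort_thresholds <- function(indices, dvr80_cut = 77,
                                        target_specificity = NULL) {
  normals <- indices %>% filter(.data$grade == "normal")
  if (nrow(normals) < 5) {
    abort("need at least 5 normal patients to calibrate",
      class = "lvfill_bad_calibration"
    )
  }
  target <- target_specificity %||% mean(normals$dvr80_pct <= dvr80_cut)
  # a spotless normal group (specificity 1) still defines a valid match:
  # the calibrated cutoff must then clear every normal value
  target <- min(target, 1 - 1e-9)
  th <- dd_thresholds(
    dvr80_cut = dvr80_cut,
    tpfr_cut = as.numeric(calibrate_threshold(normals$tpfr_ms, "above", target)),
    pfr_cut = as.numeric(calibrate_threshold(normals$pfr_ml_s, "above", target)),
    npfr_cut = as.numeric(calibrate_threshold(normals$npfr_per_s, "above", target))
  )
  attr(th, "target_specificity") <- target
  th
}

index_labels <- c(
  prolonged_dvr = "Diastolic Volume Recovery (80%)",
  long_tpfr = "Time to Peak Filling Rate",
  high_pfr = "Peak Filling Rate",
  high_npfr = "Normalized Peak Filling Rate",
  aggregate_abnormal = "DVR80 or PFR (aggregate)"
)

format_cell <- function(num, den) {
  ifelse(den > 0,
    sprintf("%d%% (%d/%d)", as.integer(round_half_up(100 * num / den)), num, den),
    "-"
  )
}

#' Render a diagnostic report as a formatted table
#'
#' Formats each metric cell as `"NN% (a/b)"` in the conventional column
#' order (threshold, sensitivity, specificity, accuracy, PPV, NPV).
#'
#' @param report A [diagnostic_report()].
#' @return A tibble of formatted character cells (header-only when the
#'   report is empty).
#' @export
render_performance_table <- function(report) {
  if (nrow(report) == 0) {
    return(tibble(
      grade = character(), index = character(), threshold = character(),
      sensitivity = character(), specificity = character(),
      accuracy = character(), ppv = character(), npv = character()
    ))
  }
  report %>%
    mutate(
      index = unname(index_labels[.data$index]),
      threshold = ifelse(is.na(.data$threshold), "-",
        format(.data$threshold, digits = 4)
      ),
      sensitivity = format_cell(.data$tp, .data$tp + .data$fn),
      specificity = format_cell(.data$tn, .data$tn + .data$fp),
      accuracy = format_cell(
        .data$tp + .data$tn,
        .data$tp + .data$fn + .data$fp + .data$tn
      ),
      ppv = format_cell(.data$tp, .data$tp + .data$fp),
      npv = format_cell(.data$tn, .data$tn + .data$fn)
    ) %>%
    select(
      "grade", "index", "threshold", "sensitivity", "specificity",
      "accuracy", "ppv", "npv"
    ) %>%
    as_tibble()
}

#' @export
print.dd_report <- function(x, ...) {
  cat("<dd_report> diagnostic performance vs the common normal group\n")
  print(render_performance_table(x), n = nrow(x), ...)
  invisible(x)
}

#' Tidy a diagnostic report
#'
#' @param x A `dd_report`.
#' @param ... Unused.
#' @return The underlying tibble (one row per grade x index).
#' @export
tidy.dd_report <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "dd_report")
  attr(out, "thresholds") <- NULL
  out
}

#' One-row summary of a diagnostic report
#'
#' @param x A `dd_report`.
#' @param ... Unused.
#' @return A one-row tibble: number of grades and indices reported, the
#'   common-normal specificity (fraction), and the mean sensitivity.
#' @export
glance.dd_report <- function(x, ...) {
  tibble(
    n_grades = dplyr::n_distinct(x$grade),
    n_indices = dplyr::n_distinct(x$index),
    specificity = mean(x$specificity, na.rm = TRUE),
    mean_sensitivity = mean(x$sensitivity, na.rm = TRUE)
  )
}

#' Plot per-grade sensitivities of the index flags
#'
#' @param object A `dd_report`.
#' @param ... Unused.
#' @return A ggplot bar chart of sensitivity by grade and index, showing
#'   the dissociation between relaxation-sensitive (DVR, TPFR) and
#'   restriction-sensitive (PFR, nPFR) indices.
#' @export
autoplot.dd_report <- function(object, ...) {
  dat <- tidy(object) %>%
    mutate(index = unname(index_labels[.data$index]))
  ggplot2::ggplot(dat, ggplot2::aes(.data$grade, .data$sensitivity,
    fill = .data$index
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(
      x = "echo-assigned DD grade", y = "sensitivity", fill = NULL
    ) +
    ggplot2::theme_minimal()
}
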