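panel <- function(ea, se, le, dt, ...) {
  tibble::tibble(
    e_over_a = ea, septal_e_prime = se, lateral_e_prime = le, dt_ms = dt, ...
  )
}

test_that("echo grading follows the four-rule cascade", {
  expect_equal(grade_echo(panel(0.7, 6, 8, 260)), "1")
  expect_equal(grade_echo(panel(2.5, 5, 7, 120)), "3")
  expect_equal(grade_echo(panel(1.0, 9, 11, 180)), "normal")
  expect_equal(grade_echo(panel(1.2, 6, 8, 200)), "2")
  # matches no rule: E/A 1.7 with low e' and mid DT
  expect_equal(grade_echo(panel(1.7, 6, 8, 200)), "indeterminate")
  expect_error(grade_echo(panel(-1, 6, 8, 200)), class = "lvfill_bad_panel")
  expect_error(grade_echo(tibble::tibble(e_over_a = 1)),
    class = "lvfill_bad_panel"
  )
})

test_that("equivocal tissue Doppler resolves through e'/a' reversal", {
  # abnormal lateral but normal septal e': indeterminate without e'/a'
  eq <- panel(0.7, 9, 8, 260)
  expect_equal(grade_echo(eq), "indeterminate")
  # with reversal supplied the E/A + DT rules decide the grade
  eq$eprime_over_aprime_lateral <- 0.8
  expect_equal(grade_echo(eq), "1")
  eq$eprime_over_aprime_lateral <- 1.4
  expect_equal(grade_echo(eq), "indeterminate")
})

test_that("sampled panels always re-grade to their generating grade", {
  set.seed(77)
  for (g in c("normal", "1", "2", "3")) {
    panels <- dplyr::bind_rows(lapply(1:50, function(i) sample_echo_panel(g)))
    expect_true(all(grade_echo(panels) == g))
  }
})

test_that("index flags use strict inequalities on the abnormal side", {
  th <- dd_thresholds()
  idx <- tibble::tibble(
    dvr80_pct = c(81, 77, 65), tpfr_ms = c(250, 221, 174),
    pfr_ml_s = c(300, 344, 266), npfr_per_s = c(4.1, 4.02, 3.3)
  )
  fl <- classify_cmr(idx, th)
  expect_equal(fl$prolonged_dvr, c(TRUE, FALSE, FALSE))
  expect_equal(fl$long_tpfr, c(TRUE, FALSE, FALSE))
  expect_equal(fl$high_npfr, c(TRUE, FALSE, FALSE))
  expect_equal(fl$high_pfr, c(FALSE, FALSE, FALSE))
  expect_equal(fl$aggregate_abnormal, c(TRUE, FALSE, FALSE))

  expect_true(aggregate_criterion(TRUE, FALSE))
  expect_true(aggregate_criterion(FALSE, TRUE))
  expect_false(aggregate_criterion(FALSE, FALSE))
  expect_error(dd_thresholds(dvr80_cut = -1), class = "lvfill_bad_thresholds")
})

test_that("matched-specificity calibration picks the most sensitive cutoff", {
  cut <- calibrate_threshold(1:40, "above", 0.825)
  expect_equal(sum(1:40 > cut), 7)
  expect_equal(attr(cut, "specificity"), 33 / 40)

  same <- calibrate_threshold(rep(5, 10), "above", 0.99)
  expect_gt(as.numeric(same), 5)
  expect_equal(attr(same, "specificity"), 1)

  expect_error(calibrate_threshold(1:3, "above", 0.8),
    class = "lvfill_bad_calibration"
  )
  expect_error(calibrate_threshold(1:40, "above", 1),
    class = "lvfill_bad_calibration"
  )
})

test_that("calibration agrees with an exhaustive scan in both directions", {
  set.seed(8)
  for (i in 1:10) {
    vals <- rnorm(200, 65, 16)
    for (dir in c("above", "below")) {
      for (target in c(0.7, 0.83, 0.9)) {
        got <- calibrate_threshold(vals, dir, target)
        want <- brute_force_cutoff(vals, dir, target)
        expect_equal(as.numeric(got), want$cutoff, tolerance = 1e-9)
        expect_equal(attr(got, "specificity"), want$specificity)
      }
    }
  }
})

test_that("loosening the specificity target never loses sensitivity", {
  set.seed(15)
  normals <- rnorm(40, 65, 16)
  abnormals <- rnorm(30, 85, 10)
  sens <- vapply(c(0.95, 0.9, 0.85, 0.8, 0.7, 0.6), function(tg) {
    cut <- calibrate_threshold(normals, "above", tg)
    mean(abnormals > cut)
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
})

test_that("diagnostic metrics follow confusion-matrix arithmetic", {
  perf <- diagnostic_performance(
    predicted = rep(c(TRUE, FALSE, TRUE, FALSE), c(15, 6, 7, 33)),
    truth = rep(c(TRUE, FALSE), c(21, 40))
  )
  expect_equal(perf$tp, 15)
  expect_equal(perf$sensitivity_pct, 71)
  expect_equal(perf$specificity_pct, 83)
  expect_equal(perf$accuracy_pct, 79)
  expect_equal(perf$ppv_pct, 68)
  expect_equal(perf$npv_pct, 85)

  none <- diagnostic_performance(rep(FALSE, 10), rep(FALSE, 10))
  expect_true(is.na(none$sensitivity))
  expect_equal(none$specificity_pct, 100)
  expect_true(is.na(none$ppv))

  expect_error(diagnostic_performance(c(TRUE, FALSE), TRUE),
    class = "lvfill_length_mismatch"
  )
})
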