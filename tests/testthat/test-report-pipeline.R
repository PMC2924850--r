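small_spec <- function(seed = 6) {
  cohort_spec(
    counts = c(normal = 10, "1" = 4, "2" = 6, "3" = 3),
    n_phases = 24, noise_sd = 1.5, seed = seed
  )
}

test_that("the diagnostic report scores each grade against the normals", {
  idx <- cohort_indices(generate_cohort(small_spec()))
  rep <- diagnostic_report(idx)
  expect_s3_class(rep, "dd_report")
  expect_equal(nrow(rep), 3 * 5) # grades 1..3 x five flags
  by_grade <- dplyr::count(dplyr::as_tibble(rep), grade)
  expect_true(all(by_grade$n == 5))
  # denominators: tp+fn = grade size, tn+fp = number of normals
  g2 <- rep[rep$grade == "2", ]
  expect_true(all(g2$tp + g2$fn == 6))
  expect_true(all(g2$tn + g2$fp == 10))
})

test_that("cohort-calibrated cutoffs reach the matched specificity", {
  idx <- cohort_indices(generate_cohort(cohort_spec(seed = 13)))
  th <- calibrate_cohort_thresholds(idx)
  target <- attr(th, "target_specificity")
  normals <- idx[idx$grade == "normal", ]
  expect_gte(mean(normals$tpfr_ms <= th$cuts["tpfr"]), target)
  expect_gte(mean(normals$pfr_ml_s <= th$cuts["pfr"]), target)
  expect_gte(mean(normals$npfr_per_s <= th$cuts["npfr"]), target)
})

test_that("rendered cells follow the NN% (a/b) convention", {
  idx <- tibble::tibble(
    grade = rep(c("normal", "1"), c(40, 21)),
    dvr80_pct = c(rep(60, 33), rep(90, 7), rep(90, 15), rep(60, 6)),
    tpfr_ms = 100, pfr_ml_s = 200, npfr_per_s = 2
  )
  rep <- diagnostic_report(idx)
  tab <- render_performance_table(rep)
  dvr_row <- tab[tab$index == "Diastolic Volume Recovery (80%)", ]
  expect_equal(dvr_row$sensitivity, "71% (15/21)")
  expect_equal(dvr_row$specificity, "83% (33/40)")

  empty <- render_performance_table(diagnostic_report(idx[0, ]))
  expect_equal(nrow(empty), 0)
  expect_true(all(c("sensitivity", "npv") %in% names(empty)))

  # a zero denominator renders as a dash, not a division by zero
  cell <- lvfill:::format_cell(0L, 0L)
  expect_equal(cell, "-")
  expect_equal(lvfill:::format_cell(0L, 9L), "0% (0/9)")
})

test_that("tidy, glance and autoplot expose the report", {
  rep <- diagnostic_report(cohort_indices(generate_cohort(small_spec())))
  td <- tidy(rep)
  expect_false(inherits(td, "dd_report"))
  expect_true(all(c("grade", "index", "sensitivity") %in% names(td)))
  gl <- glance(rep)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_grades, 3)
  p <- ggplot2::autoplot(rep)
  expect_s3_class(p, "ggplot")
})

test_that("the pipeline is deterministic and self-describing", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- run_config(cohort = small_spec(), seed = 11, thresholds = NULL)
  r1 <- run_pipeline(cfg, d1)
  r2 <- run_pipeline(cfg, d2)
  expect_identical(tidy(r1), tidy(r2))
  expect_false(file.exists(file.path(d1, "RUN_INCOMPLETE")))

  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$seed, 11)
  expect_equal(man$n_patients, 23)
  expect_true(all(c("dvr80", "tpfr", "pfr", "npfr") %in% names(man$thresholds)))
  expect_true(file.exists(file.path(d1, "indices.csv")))
  expect_true(file.exists(file.path(d1, "report.json")))
})

test_that("indices from a curves directory match the generated path", {
  d1 <- withr::local_tempdir()
  cfg <- run_config(cohort = small_spec(seed = 21), seed = 21)
  run_pipeline(cfg, d1)
  idx1 <- read.csv(file.path(d1, "indices.csv"))

  d2 <- withr::local_tempdir()
  cfg2 <- run_config(curves_dir = file.path(d1, "curves"), seed = 21)
  run_pipeline(cfg2, d2)
  idx2 <- read.csv(file.path(d2, "indices.csv"))

  m <- match(idx1$id, idx2$id)
  expect_equal(idx2$pfr_ml_s[m], idx1$pfr_ml_s, tolerance = 1e-6)
  expect_equal(idx2$dvr80_pct[m], idx1$dvr80_pct, tolerance = 1e-6)
  expect_equal(idx2$grade[m], idx1$grade)
})

test_that("run configurations load from YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(
    c(
      "counts:", "  normal: 5", "  '3': 2",
      "n_phases: 20", "noise_sd: 1", "seed: 3",
      "thresholds:", "  dvr80: 75", "  pfr: 300"
    ),
    path
  )
  cfg <- read_run_config(path)
  expect_equal(unname(cfg$cohort$counts), c(5, 2))
  expect_equal(cfg$cohort$n_phases, 20)
  expect_equal(unname(cfg$thresholds$cuts["dvr80"]), 75)
  expect_equal(unname(cfg$thresholds$cuts["npfr"]), 4.02)
})
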