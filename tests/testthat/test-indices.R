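test_that("linear diastolic filling recovers volume in exact proportion", {
  lf <- linear_filling_curve()
  expect_equal(diastolic_volume_recovery(lf$curve, lf$fid, 0.8), 80,
    tolerance = 1e-9
  )
  # monotone in the recovered fraction
  fr <- c(0.2, 0.5, 0.8, 0.95)
  dvr <- vapply(fr, function(f) {
    diastolic_volume_recovery(lf$curve, lf$fid, f)
  }, numeric(1))
  expect_true(all(diff(dvr) > 0))
  expect_error(diastolic_volume_recovery(lf$curve, lf$fid, 1.2),
    class = "lvfill_bad_fraction"
  )
})

test_that("peak filling rate matches raised-cosine and constant-rate forms", {
  pt <- single_lobe_truth()
  tt <- seq(0, pt$rr_ms - 0.125, by = 0.125)
  rates <- tibble::tibble(time_ms = tt, rate_ml_s = rate_function(pt)(tt))
  attr(rates, "rr_ms") <- pt$rr_ms
  fid <- find_fiducials(lowpass(generate_volume_curve(pt, 400, 0), 64))
  pk <- peak_filling_rate(rates, fid)
  expect_equal(pk$pfr, 400, tolerance = 1e-6)
  expect_equal(pk$pfr_time, 550, tolerance = 0.2)
  expect_equal(time_to_pfr(pk$pfr_time, fid), 200, tolerance = 1)

  # constant filling of 80 ml over 500 ms of diastole
  lf <- linear_filling_curve(rr = 900, ts = 400, edv = 150, esv = 70)
  rr <- raw_rate(lf$curve)
  pk2 <- peak_filling_rate(rr, lf$fid)
  expect_equal(pk2$pfr, 160, tolerance = 1e-9)

  # no filling at all is a named error
  down <- lvfill:::new_volume_curve((0:19) * 50, seq(150, 74, length.out = 20), 1000)
  expect_error(
    peak_filling_rate(
      tibble::tibble(time_ms = down$time_ms, rate_ml_s = rep(-1, 20)),
      lf$fid
    ),
    class = "lvfill_no_filling"
  )
})

test_that("normalized PFR is a plain stroke-volume quotient", {
  expect_equal(normalized_pfr(266, 85), 3.129, tolerance = 1e-3)
  expect_equal(normalized_pfr(85, 85), 1)
  expect_equal(normalized_pfr(344, 85.6), 4.02, tolerance = 0.005)
  expect_error(normalized_pfr(300, 0), class = "lvfill_bad_sv")
  expect_error(time_to_pfr(300, list(es_time = 350)),
    class = "lvfill_bad_tpfr"
  )
})

test_that("E and A waves are resolved when separated and flagged when not", {
  pt <- patient_truth(
    grade = "2", edv = 150, esv = 70, rr_ms = 1000, ts_ms = 350,
    e_fraction = 0.5, e_onset_ms = 0, e_width_ms = 280,
    a_onset_ms = 330, a_width_ms = 280
  )
  tt <- seq(0, pt$rr_ms - 0.25, by = 0.25)
  rates <- tibble::tibble(time_ms = tt, rate_ml_s = rate_function(pt)(tt))
  attr(rates, "rr_ms") <- pt$rr_ms
  fid <- find_fiducials(lowpass(generate_volume_curve(pt, 400, 0), 64))
  ea <- ea_profile(rates, fid)
  expect_true(ea$discernable)
  expect_equal(ea$ea_ratio, 1, tolerance = 1e-6)

  single <- single_lobe_truth()
  tt2 <- seq(0, single$rr_ms - 0.25, by = 0.25)
  r2 <- tibble::tibble(time_ms = tt2, rate_ml_s = rate_function(single)(tt2))
  attr(r2, "rr_ms") <- single$rr_ms
  ea2 <- ea_profile(r2, fid)
  expect_false(ea2$discernable)
  expect_true(is.na(ea2$ea_ratio))
})

test_that("a mild-dysfunction E:A ratio is recovered from noisy curves", {
  pt <- two_lobe_truth_ea11()
  expect_equal(pt$analytic_ea, 1.1, tolerance = 0.01)
  ratios <- vapply(1:50, function(i) {
    cv <- generate_volume_curve(pt, 30, 2, seed = 2000 + i)
    compute_indices(cv)$ea_ratio
  }, numeric(1))
  expect_gt(mean(!is.na(ratios)), 0.5)
  rel <- (mean(ratios, na.rm = TRUE) - pt$analytic_ea) / pt$analytic_ea
  expect_lt(abs(rel), 0.1)
})

test_that("LV mass and infarct size follow their tabulated arithmetic", {
  expect_equal(lv_mass(200, 120), 84)
  expect_equal(lv_mass(120, 120), 0)
  expect_equal(lv_mass(215, 151), 67.2)
  expect_error(lv_mass(100, 120), class = "lvfill_bad_mass")

  expect_equal(infarct_size(rep(0L, 17)), 0)
  expect_equal(infarct_size(rep(4L, 17)), 88)
  expect_equal(infarct_size(c(4L, rep(0L, 16))), 88 / 17, tolerance = 1e-9)
  expect_error(infarct_size(rep(1L, 16)), class = "lvfill_bad_scores")
  expect_error(infarct_size(c(rep(0L, 16), 5L)), class = "lvfill_bad_scores")
})

test_that("indices scale correctly under a volume rescaling", {
  pt <- sample_patient("2", seed = 21)
  cv <- generate_volume_curve(pt, 30, 0)
  scaled <- lvfill:::new_volume_curve(cv$time_ms, 3 * cv$volume_ml,
    attr(cv, "rr_ms")
  )
  a <- compute_indices(cv)
  b <- compute_indices(scaled)
  expect_equal(b$pfr_ml_s, 3 * a$pfr_ml_s, tolerance = 1e-9)
  expect_equal(b$sv, 3 * a$sv, tolerance = 1e-9)
  expect_equal(b$npfr_per_s, a$npfr_per_s, tolerance = 1e-9)
  expect_equal(b$dvr80_pct, a$dvr80_pct, tolerance = 1e-9)
  expect_equal(b$ef, a$ef, tolerance = 1e-9)
  expect_equal(b$ea_ratio, a$ea_ratio, tolerance = 1e-9)
})

test_that("peak rate always exceeds the mean diastolic rate when filling varies", {
  set.seed(14)
  for (g in c("normal", "1", "3")) {
    pt <- sample_patient(g)
    ix <- compute_indices(generate_volume_curve(pt, 30, 0))
    mean_rate <- 1000 * pt$sv / (pt$rr_ms - pt$ts_ms)
    expect_gt(ix$pfr_ml_s, 0.999 * mean_rate)
  }
})

test_that("raw successive-difference mode reproduces piecewise-constant rates", {
  lf <- linear_filling_curve(rr = 900, ts = 400, edv = 150, esv = 70)
  ix <- compute_indices(lf$curve, n_harmonics = 10, pfr_mode = "raw_diff")
  expect_gt(ix$pfr_ml_s, 100)
  expect_true(is.finite(ix$dvr80_pct))
})
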