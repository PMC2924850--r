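make_curve <- function(v, rr = 1000) {
  n <- length(v)
  lvfill:::new_volume_curve((0:(n - 1)) * rr / n, v, rr)
}

test_that("harmonic truncation passes the passband and kills the stopband", {
  rr <- 1000
  t <- (0:29) * rr / 30
  in_band <- 100 + 5 * sin(2 * pi * 3 * t / rr)
  out_band <- 100 + 5 * sin(2 * pi * 8 * t / rr)

  expect_equal(lowpass(make_curve(in_band), 5)$volume_ml, in_band,
    tolerance = 1e-9
  )
  expect_equal(lowpass(make_curve(out_band), 5)$volume_ml, rep(100, 30),
    tolerance = 1e-9
  )

  # cycle mean preserved exactly, and the filter is idempotent
  set.seed(2)
  v <- 100 + rnorm(30, 0, 5)
  f1 <- lowpass(make_curve(v), 10)
  f2 <- lowpass(f1, 10)
  expect_equal(mean(f1$volume_ml), mean(v), tolerance = 1e-12)
  expect_equal(f2$volume_ml, f1$volume_ml, tolerance = 1e-12)

  expect_error(lowpass(make_curve(v), 15), class = "lvfill_bad_filter")
  expect_error(lowpass(make_curve(v), 0), class = "lvfill_bad_filter")
})

test_that("filtering strictly reduces RMS noise on clean-plus-noise curves", {
  pt <- sample_patient("2", seed = 3)
  clean <- generate_volume_curve(pt, 30, 0)$volume_ml
  improved <- vapply(1:100, function(i) {
    noisy <- generate_volume_curve(pt, 30, 2, seed = 500 + i)
    filt <- lowpass(noisy, 10)
    sqrt(mean((filt$volume_ml - clean)^2)) <
      sqrt(mean((noisy$volume_ml - clean)^2))
  }, logical(1))
  expect_true(all(improved))
})

test_that("the Fourier derivative matches closed forms and integrates to zero", {
  rr <- 1000
  t <- (0:29) * rr / 30

  expect_equal(derivative(make_curve(rep(120, 30)), 5)$rate_ml_s,
    rep(0, 30),
    tolerance = 1e-9
  )

  v <- 100 + 5 * sin(2 * pi * t / rr)
  r <- derivative(make_curve(v), 5)
  expect_equal(r$rate_ml_s, 5 * (2 * pi / rr) * 1000 * cos(2 * pi * t / rr),
    tolerance = 1e-9
  )
  # net volume change over one period is zero
  expect_lt(abs(sum(r$rate_ml_s) * (rr / 30) / 1000), 1e-6)
})

test_that("the dense rate curve peaks within half a phase of the true peak", {
  set.seed(6)
  for (i in 1:3) {
    pt <- sample_patient("3")
    cv <- generate_volume_curve(pt, 30, 0)
    r <- derivative(cv, 10, n_out = 2048)
    sm <- lowpass(cv, 10)
    fid <- find_fiducials(sm)
    dia <- r$time_ms > fid$es_time
    t_peak <- r$time_ms[dia][which.max(r$rate_ml_s[dia])]
    expect_lt(abs(t_peak - (pt$ts_ms + pt$analytic_tpfr)), pt$rr_ms / 60)
  }
})

test_that("fiducials reproduce closed-form volumes and ejection fraction", {
  rr <- 1000
  t <- (0:39) * rr / 40
  # cosine cycle: starts at the 110 ml maximum, minimum 90 ml at mid-cycle
  cosv <- make_curve(100 + 10 * cos(2 * pi * t / rr))
  fid <- find_fiducials(cosv)
  expect_equal(fid$edv, 110, tolerance = 1e-9)
  expect_equal(fid$esv, 90, tolerance = 1e-9)
  expect_equal(fid$ef, 100 * 20 / 110, tolerance = 1e-4)
  expect_equal(fid$es_time, 500, tolerance = 1)

  # representative post-MI chamber volumes
  lv <- make_curve(66 + 85 * (1 + cos(2 * pi * t / rr)) / 2)
  expect_equal(find_fiducials(lv)$ef, 56.29, tolerance = 1e-3)

  expect_error(find_fiducials(make_curve(rep(100, 40))),
    class = "lvfill_degenerate_curve"
  )
})

test_that("end-systole is stable under segmentation-scale noise", {
  pt <- sample_patient("2", seed = 42)
  es0 <- find_fiducials(lowpass(generate_volume_curve(pt, 30, 0), 10))$es_time
  phase <- pt$rr_ms / 30
  shifts <- vapply(1:200, function(i) {
    cv <- generate_volume_curve(pt, 30, 2, seed = 1000 + i)
    abs(find_fiducials(lowpass(cv, 10))$es_time - es0)
  }, numeric(1))
  expect_gte(mean(shifts < phase), 0.85)
  expect_lt(abs(mean(shifts)), phase / 2) # no systematic drift
})

test_that("curve files round-trip through both delimiters", {
  pt <- sample_patient("normal", seed = 10)
  cv <- generate_volume_curve(pt, 25, 1, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_volume_curve(cv, path)
  back <- read_volume_curve(path)
  expect_equal(back$volume_ml, cv$volume_ml, tolerance = 1e-9)
  expect_equal(attr(back, "rr_ms"), attr(cv, "rr_ms"), tolerance = 1e-9)
  expect_identical(attr(back, "provenance"), "file")

  tabbed <- withr::local_tempfile(fileext = ".tsv")
  writeLines(
    c(
      "time_ms\tvolume_ml",
      paste(cv$time_ms, cv$volume_ml, sep = "\t")
    ),
    tabbed
  )
  expect_equal(read_volume_curve(tabbed)$volume_ml, cv$volume_ml,
    tolerance = 1e-9
  )

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), bad)
  expect_error(read_volume_curve(bad), class = "lvfill_bad_curve_file")
})
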