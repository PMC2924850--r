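#' Low-pass filter a sampled volume curve
#'
#' Smooths a periodic volume-time series to remove non-physiologic
#' high-frequency components before differentiation, so small per-phase
#' segmentation errors are not amplified in the filling-rate curve. The
#' default realization is periodic Fourier truncation: the series is
#' expanded in harmonics of the cardiac cycle and only the DC term plus
#' harmonics `1..n_harmonics` are retained. The cycle mean is preserved
#' exactly and the filter is idempotent. A centered circular moving-average
#' alternative is available via `method = "moving_average"`.
#'
#' @param curve A `volume_curve` (see [generate_volume_curve()] or
#'   [read_volume_curve()]).
#' @param n_harmonics Number of harmonics retained (Fourier method);
#'   must satisfy `1 <= n_harmonics < N/2` for `N` phases.
#' @param method `"fourier"` (default) or `"moving_average"`.
#' @param ma_window Odd window length for the moving-average method.
#' @param n_out Optional number of uniform output times (Fourier method
#'   only): the retained harmonics are re-evaluated on a finer grid.
#' @return A `volume_curve` with filtered volumes; attribute
#'   `n_harmonics` records the passband.
#' @export
lowpass <- function(curve, n_harmonics = 10, method = c("fourier", "moving_average"),
                    ma_window = 3, n_out = NULL) {
  method <- match.arg(method)
  v <- curve$volume_ml
  n <- length(v)
  times <- curve$time_ms
  if (method == "fourier") {
    check_harmonics(n_harmonics, n)
    co <- fft(v) / n
    keep <- harmonic_mask(n, n_harmonics)
    if (is.null(n_out) || n_out == n) {
      out <- Re(fft(co * keep, inverse = TRUE))
    } else {
      ck <- co * keep
      pad <- complex(n_out)
      pos <- seq_len(n_harmonics + 1)
      pad[pos] <- ck[pos]
      pad[n_out - seq_len(n_harmonics) + 1] <- ck[n - seq_len(n_harmonics) + 1]
      out <- Re(fft(pad, inverse = TRUE))
      times <- (seq_len(n_out) - 1) * attr(curve, "rr_ms") / n_out
    }
  } else {
    if (ma_window %% 2 != 1 || ma_window < 1) {
      abort("ma_window must be odd and positive", class = "lvfill_bad_filter")
    }
    half <- (ma_window - 1) / 2
    idx <- outer(seq_len(n), -half:half, `+`)
    idx <- ((idx - 1) %% n) + 1
    out <- rowMeans(matrix(v[idx], nrow = n))
  }
  res <- new_volume_curve(times, out, attr(curve, "rr_ms"),
    provenance = attr(curve, "provenance"), truth = attr(curve, "truth")
  )
  attr(res, "n_harmonics") <- if (method == "fourier") n_harmonics else NA
  res
}

check_harmonics <- function(n_harmonics, n) {
  if (n_harmonics < 1 || n_harmonics >= n / 2) {
    abort("n_harmonics must satisfy 1 <= n_harmonics < N/2",
      class = "lvfill_bad_filter"
    )
  }
}

# Logical mask over FFT bins keeping DC and harmonics 1..nh (both sides).
harmonic_mask <- function(n, nh) {
  k <- c(0, seq_len(n - 1))
  k <- pmin(k, n - k)
  as.numeric(k <= nh)
}

#' Filling-rate curve by analytic Fourier differentiation
#'
#' Differentiates the truncated Fourier representation of a periodic volume
#' curve term by term and evaluates the exact derivative of the retained
#' harmonics at the phase times. Because the DC term differentiates to
#' zero, the returned rate integrates to zero over the cycle.
#'
#' @inheritParams lowpass
#' @param n_out Optional number of uniform output times. The truncated
#'   Fourier series is an entire function of time, so it can be evaluated
#'   on a grid finer than the acquired phases (via zero-padded inverse
#'   FFT); the default evaluates at the phase times themselves.
#' @return A tibble with `time_ms` and `rate_ml_s` (ml/s), with the cycle
#'   length in attribute `rr_ms`.
#' @export
derivative <- function(curve, n_harmonics = 10, n_out = NULL) {
  v <- curve$volume_ml
  n <- length(v)
  check_harmonics(n_harmonics, n)
  rr <- attr(curve, "rr_ms")
  co <- fft(v) / n
  k <- c(0, seq_len(n - 1))
  ksym <- ifelse(k <= n / 2, k, k - n) # signed harmonic index
  omega <- 2 * pi * ksym / rr # rad per ms
  keep <- harmonic_mask(n, n_harmonics)
  if (n %% 2 == 0) keep[n / 2 + 1] <- 0 # Nyquist bin has no odd derivative
  dco <- co * (1i * omega) * keep
  if (is.null(n_out) || n_out == n) {
    rates <- Re(fft(dco, inverse = TRUE)) * 1000 # ml/ms -> ml/s
    times <- curve$time_ms
  } else {
    pad <- complex(n_out)
    pos <- seq_len(n_harmonics + 1) # DC..nh
    pad[pos] <- dco[pos]
    pad[n_out - seq_len(n_harmonics) + 1] <- dco[n - seq_len(n_harmonics) + 1]
    rates <- Re(fft(pad, inverse = TRUE)) * 1000
    times <- (seq_len(n_out) - 1) * rr / n_out
  }
  out <- tibble(time_ms = times, rate_ml_s = rates)
  attr(out, "rr_ms") <- rr
  out
}

#' Raw successive-difference filling rate
#'
#' The unfiltered alternative to [derivative()]: forward differences
#' `(V[i+1] - V[i]) / dt` between sequential phases (periodic wrap),
#' reported at the midpoint-free convention of the leading phase time.
#'
#' @inheritParams lowpass
#' @return A tibble like [derivative()].
#' @export
raw_rate <- function(curve) {
  v <- curve$volume_ml
  n <- length(v)
  rr <- attr(curve, "rr_ms")
  dt <- diff(c(curve$time_ms, rr))
  dv <- diff(c(v, v[1]))
  out <- tibble(time_ms = curve$time_ms, rate_ml_s = 1000 * dv / dt)
  attr(out, "rr_ms") <- rr
  out
}

#' Locate the cycle fiducials of a (filtered) volume curve
#'
#' End-diastole is the cycle start (phase 0, the gated acquisition
#' trigger). End-systole is the global volume minimum, located to
#' sub-phase precision: starting from the discrete minimum (earliest
#' phase on an exact tie), the upward zero-crossing of dV/dt nearest that
#' phase is found by linear interpolation. The crossing refinement matters
#' because the volume curve approaches its minimum steeply from the
#' ejection side but leaves it very flatly into early filling, so the raw
#' argmin is biased late under noise while the rate crossing is not.
#' Ejection fraction is `(EDV - ESV)/EDV * 100` and the diastolic interval
#' is `rr_ms - es_time`.
#'
#' @param curve A `volume_curve`, normally already passed through
#'   [lowpass()].
#' @return A list of class `fiducials`: `ed_index`, `ed_time`, `es_index`,
#'   `es_time`, `edv`, `esv`, `sv`, `ef`, `diastole_duration`, `rr_ms`.
#' @export
find_fiducials <- function(curve) {
  v <- curve$volume_ml
  n <- length(v)
  rr <- attr(curve, "rr_ms")
  es_index <- which.min(v)
  esv <- v[es_index]
  edv <- v[1]
  if (edv - esv < 1e-9) {
    abort("degenerate flat curve: EDV equals ESV",
      class = "lvfill_degenerate_curve"
    )
  }
  # sub-phase refinement: the ejection branch of dV/dt falls through zero
  # almost linearly while early filling leaves the rate hugging zero, so
  # the zero of the line through the last two negative-rate phases before
  # the upward crossing locates end-systole without the late bias a plain
  # argmin (or a crossing interpolation against the flat side) would have
  es_time <- curve$time_ms[es_index]
  nh_es <- min(max(6L, n %/% 5L), (n - 1L) %/% 2L)
  r <- derivative(curve, n_harmonics = nh_es)$rate_ml_s
  nxt <- c(seq_len(n)[-1], 1L)
  up <- which(r < 0 & r[nxt] >= 0)
  if (length(up) > 0) {
    dist <- pmin(abs(up - es_index), n - abs(up - es_index))
    near <- up[dist <= 6]
    if (length(near) > 0) {
      # among nearby upward crossings take the one terminating the
      # ejection branch (most negative rates just before it) -- under
      # noise the crossing closest to the argmin is often spurious
      score <- vapply(near, function(j) {
        jm <- ((j - 2L:1L - 1L) %% n) + 1L
        mean(r[jm])
      }, numeric(1))
      j <- near[which.min(score)]
      dt <- rr / n
      jm <- if (j == 1L) n else j - 1L
      cand <- if (r[jm] < 0 && r[j] < 0 && r[j] > r[jm]) {
        curve$time_ms[j] - r[j] * dt / (r[j] - r[jm])
      } else {
        NA_real_
      }
      es_time <- if (is.finite(cand) &&
        abs(cand - curve$time_ms[j]) <= 2.5 * dt) {
        cand %% rr
      } else {
        (curve$time_ms[j] + dt * r[j] / (r[j] - r[nxt[j]])) %% rr
      }
    }
  }
  structure(
    list(
      ed_index = 1L, ed_time = curve$time_ms[1],
      es_index = es_index, es_time = es_time,
      edv = edv, esv = esv, sv = edv - esv,
      ef = 100 * (edv - esv) / edv,
      diastole_duration = rr - es_time,
      rr_ms = rr
    ),
    class = "fiducials"
  )
}

#' Read / write two-column volume-curve files
#'
#' Curve files are plain text with a required header and two columns,
#' `time_ms` and `volume_ml`; comma and tab dialects are auto-detected on
#' read. The cycle length is taken as the time of the last phase plus one
#' phase spacing (uniform sampling), unless given.
#'
#' @param path File path.
#' @param rr_ms Optional cycle length override, ms.
#' @return `read_volume_curve()`: a `volume_curve` with provenance
#'   `"file"`. `write_volume_curve()`: `path`, invisibly.
#' @export
read_volume_curve <- function(path, rr_ms = NULL) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep)
  if (!all(c("time_ms", "volume_ml") %in% names(df))) {
    abort("curve file must have columns time_ms, volume_ml",
      class = "lvfill_bad_curve_file"
    )
  }
  t <- df$time_ms
  if (length(t) < 2 || any(diff(t) <= 0)) {
    abort("curve times must be strictly increasing",
      class = "lvfill_bad_curve_file"
    )
  }
  rr <- rr_ms %||% (t[length(t)] + (t[length(t)] - t[1]) / (length(t) - 1))
  new_volume_curve(t, df$volume_ml, rr, provenance = "file")
}

#' @rdname read_volume_curve
#' @param curve A `volume_curve`.
#' @export
write_volume_curve <- function(curve, path) {
  write.csv(
    data.frame(time_ms = curve$time_ms, volume_ml = curve$volume_ml),
    path,
    row.names = FALSE
  )
  invisible(path)
}

#' @export
print.volume_curve <- function(x, ...) {
  cat(sprintf(
    "<volume_curve> %d phases, RR %.0f ms, provenance %s\n",
    nrow(x), attr(x, "rr_ms"), attr(x, "provenance")
  ))
  NextMethod()
}

#' Plot a volume curve with its filtered curve and filling rate
#'
#' @param object A `volume_curve`.
#' @param n_harmonics Passband used for the overlay and rate panel.
#' @param ... Unused.
#' @return A ggplot object: sampled volumes, the Fourier-filtered curve,
#'   and the filling-rate curve on a secondary facet.
#' @export
autoplot.volume_curve <- function(object, n_harmonics = 10, ...) {
  sm <- lowpass(object, n_harmonics)
  rt <- derivative(object, n_harmonics)
  dat <- dplyr::bind_rows(
    tibble(
      time_ms = object$time_ms, value = object$volume_ml,
      what = "volume (ml)", series = "sampled"
    ),
    tibble(
      time_ms = sm$time_ms, value = sm$volume_ml,
      what = "volume (ml)", series = "filtered"
    ),
    tibble(
      time_ms = rt$time_ms, value = rt$rate_ml_s,
      what = "filling rate (ml/s)", series = "filtered"
    )
  )
  ggplot2::ggplot(dat, ggplot2::aes(.data$time_ms, .data$value,
    colour = .data$series
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = dat[dat$series == "sampled", ], size = 0.8) +
    ggplot2::facet_wrap(~what, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
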