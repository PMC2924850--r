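# Shared fixtures and independent oracles, all built in code.

# Single raised-cosine lobe: SV 80 ml filled over a 400 ms early wave,
# peak rate exactly 2 * 80 / 0.4 = 400 ml/s at the lobe midpoint.
single_lobe_truth <- function(edv = 146, esv = 66, rr = 1000, ts = 350,
                              width = 400) {
  patient_truth(
    grade = "normal", edv = edv, esv = esv, rr_ms = rr, ts_ms = ts,
    e_fraction = 1, e_onset_ms = 0, e_width_ms = width
  )
}

# Two-lobe truth with an analytic E:A peak-rate ratio close to 1.1 (an
# impaired-relaxation pattern with clearly separated waves).
two_lobe_truth_ea11 <- function() {
  patient_truth(
    grade = "1", edv = 141, esv = 66, rr_ms = 1100, ts_ms = 350,
    e_fraction = 0.5, e_onset_ms = 0, e_width_ms = 330,
    a_onset_ms = 330, a_width_ms = 363
  )
}

# Volume curve with exactly linear filling over diastole, plus hand-built
# fiducials: the DVR of any fraction f is then exactly 100 * f.
linear_filling_curve <- function(rr = 1000, ts = 400, edv = 150, esv = 70,
                                 n = 40) {
  t <- (0:(n - 1)) * rr / n
  v <- ifelse(t <= ts,
    esv + (edv - esv) * (1 - t / ts),
    esv + (edv - esv) * (t - ts) / (rr - ts)
  )
  curve <- lvfill:::new_volume_curve(t, v, rr)
  fid <- structure(
    list(
      ed_index = 1L, ed_time = 0, es_index = which.min(v),
      es_time = ts, edv = edv, esv = esv, sv = edv - esv,
      ef = 100 * (edv - esv) / edv, diastole_duration = rr - ts,
      rr_ms = rr
    ),
    class = "fiducials"
  )
  list(curve = curve, fid = fid)
}

# Brute-force index oracle: everything from a dense uniform sampling of
# volume_function and first-principles definitions (forward differences,
# argmin/argmax scans, crossing interpolation). Independent of the FFT
# production path.
dense_oracle <- function(truth, n = 10000) {
  tt <- (0:(n - 1)) * truth$rr_ms / n
  V <- volume_function(truth)(tt)
  dt <- truth$rr_ms / n
  es_i <- which.min(V)
  es_t <- tt[es_i]
  r <- 1000 * (V[c(2:n, 1)] - V) / dt
  dia <- tt > es_t
  rd <- r[dia]
  td <- tt[dia]
  pfr <- max(rd)
  tpfr <- td[which.max(rd)] - es_t
  esv <- V[es_i]
  edv <- V[1]
  target <- esv + 0.8 * (edv - esv)
  j <- which(V >= target & tt > es_t)[1]
  tstar <- tt[j - 1] + dt * (target - V[j - 1]) / (V[j] - V[j - 1])
  dvr <- 100 * (tstar - es_t) / (truth$rr_ms - es_t)
  nn <- length(rd)
  pk <- which(rd > c(-Inf, rd[-nn]) & rd >= c(rd[-1], -Inf) & rd >= 0.05 * pfr)
  ea <- NA_real_
  if (length(pk) >= 2) {
    i1 <- pk[which.max(rd[pk])]
    far <- pk[abs(td[pk] - td[i1]) >= 150]
    if (length(far) > 0) {
      i2 <- far[which.max(rd[far])]
      ea <- rd[min(i1, i2)] / rd[max(i1, i2)]
    }
  }
  list(
    pfr = pfr, tpfr = tpfr, dvr = dvr, ea = ea,
    edv = edv, esv = esv, es_t = es_t
  )
}

# Exhaustive-scan calibration oracle: evaluates every candidate cutoff
# (midpoints of sorted distinct values plus outside extremes) directly.
brute_force_cutoff <- function(values, direction, target) {
  v <- sort(unique(values))
  step <- if (length(v) > 1) min(diff(v)) / 2 else 1e-6
  cands <- c(v[1] - step, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2,
    v[length(v)] + step
  )
  spec <- vapply(cands, function(cut) {
    if (direction == "above") mean(values <= cut) else mean(values >= cut)
  }, numeric(1))
  ok <- which(spec >= target - 1e-12)
  cut <- if (direction == "above") min(cands[ok]) else max(cands[ok])
  list(cutoff = cut, specificity = spec[match(cut, cands)])
}
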