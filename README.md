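# lvfill

Quantitative left-ventricular (LV) diastolic function from cine
cardiovascular magnetic resonance (CMR) volume–time curves.

Segmenting every short-axis slice at every reconstructed cardiac phase of
a cine CMR exam yields the LV volume curve V(t) over one gated cycle. The
diastolic limb of that curve carries the filling physiology that
echocardiography reads from mitral inflow velocities. `lvfill` implements
the full analysis chain:

* **Filling indices.** After periodic Fourier low-pass filtering, the
  analytic derivative dV/dt gives the peak filling rate
  (PFR, ml/s), its stroke-volume–normalized form (nPFR = PFR/SV, 1/s),
  the time from end-systole to peak filling (TPFR, ms), the diastolic 80%
  volume recovery (DVR80, the % of diastole needed to regain 0.8·SV above
  ESV), and the E:A peak-rate ratio of the early and atrial filling
  waves (with an explicit non-discernable outcome). Systolic measures
  (EDV, ESV, EF = 100·(EDV−ESV)/EDV), LV mass ((EpiEDV−EDV)·1.05 g) and
  17-segment infarct size (midpoint-weighted transmurality scores) round
  out the panel.
* **Diastolic-dysfunction grading.** Echo parameter panels (E/A, septal
  and lateral e′, deceleration time) are graded normal / 1 / 2 / 3 by the
  standard rule cascade; cine-CMR index flags (prolonged DVR80, long
  TPFR, high PFR/nPFR, and their aggregate) are tabulated against the
  grades as per-grade confusion matrices with sensitivity, specificity,
  accuracy, PPV and NPV.
* **Matched-specificity calibration.** Cohort-specific cutoffs are
  derived by an exhaustive candidate scan that returns the most sensitive
  cutoff achieving a reference specificity on the normal group.
* **Synthetic cohort with exact ground truth.** Grade-stratified
  ventricles built from raised-cosine filling lobes, for which every
  index has a closed form; sampled noisy curves, grade-consistent echo
  panels, and a short-axis cine phantom (rasterization + stand-in
  region-growing segmentation) exercise the whole chain end to end.

Everything is tidyverse-native: data-frame-first functions returning
tibbles, `tidy()`/`glance()` on reports, `autoplot()` on curves and
reports.

## Worked example

```r
library(lvfill)

# one synthetic impaired-relaxation patient, known ground truth
pt <- sample_patient("1", seed = 7)
pt
#> <patient_truth> grade 1 | EDV 208.7 ESV 98.9 SV 109.9 ml | RR 1018 ms
#>   analytic: PFR 309.9 ml/s, TPFR 374.1 ms, DVR80 67.1%, E:A 0.95

# a 30-phase cine-resolution curve with 2 ml segmentation noise,
# and the recovered indices
cv <- generate_volume_curve(pt, n_phases = 30, noise_sd = 2, seed = 8)
compute_indices(cv)
#>     edv   esv    ef pfr_ml_s npfr_per_s tpfr_ms dvr80_pct
#>  208.51 96.48 53.73   321.69       2.87  378.33      67.2
```

The recovered PFR (322 vs 310 ml/s true), TPFR (378 vs 374 ms) and DVR80
(67.2 vs 67.1%) land on the analytic truth to within the noise; the E:A
ratio is flagged non-discernable for this near-unity-ratio ventricle, as
it would be for ~6% of real filling profiles.

```r
# full default cohort: 40 normals + 21/45/9 graded patients
cohort <- generate_cohort(cohort_spec(seed = 1))
idx    <- cohort_indices(cohort)
th     <- calibrate_cohort_thresholds(idx, target_specificity = 33/40)
render_performance_table(diagnostic_report(idx, th))
#>  grade index                           threshold sensitivity specificity
#>  1     Diastolic Volume Recovery (80%)  77.00    29% (6/21)  98% (39/40)
#>  1     Peak Filling Rate               375.96    0% (0/21)   83% (33/40)
#>  2     Diastolic Volume Recovery (80%)  77.00    4% (2/45)   98% (39/40)
#>  2     Peak Filling Rate               375.96    7% (3/45)   83% (33/40)
#>  3     Diastolic Volume Recovery (80%)  77.00    0% (0/9)    98% (39/40)
#>  3     Peak Filling Rate               375.96    78% (7/9)   83% (33/40)
```

The table shows the characteristic dissociation: the prolonged-DVR80 flag
picks out impaired relaxation (grade 1: 29%, grade 3: 0%) while the
high-PFR flag picks out restrictive filling (grade 3: 78%, grade 1: 0%),
each scored against the same 40-normal control group.

A thin command-line wrapper over the same pipeline lives at
`inst/cli/lvfill.R`:

```sh
Rscript inst/cli/lvfill.R --seed 1 --out my_run
```

It writes the cohort files, index table, diagnostic report, a manifest
(seed, config hash, per-stage timings) and a log into `my_run/`.

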