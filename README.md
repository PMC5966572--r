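# tremordiff

Differentiating Parkinsonian tremor (PD) from essential tremor (ET) with
wrist accelerometry is a long-standing clinical problem: the two
conditions overlap in appearance but differ in treatment, and published
misdiagnosis rates are substantial.  `tremordiff` implements a complete,
operator-independent differentiation pipeline for 3-axis acceleration
recordings of the hand under two elicitation postures — the conventional
arm-stretching posture (P1) and an arm-rested posture (P2, arms
supported only at the wrists so the forearm muscles are passively
strained) — together with a calibrated synthetic cohort generator, so
that every stage is testable without patient data.

The package is aimed at movement-disorder researchers and biomedical
signal-processing engineers who want a reproducible reference
implementation of higher-order-spectral tremor analysis.

## The analysis

1. **Preprocessing** (per recording): split into non-overlapping
   segments (30 s by default, never across trial boundaries); notch out
   50 Hz mains and its harmonics; zero-phase order-2 Butterworth
   bandpass, 1–20 Hz; decimate 1000 Hz → 100 Hz; reduce the three axes
   to one channel by projection on the first principal direction.
2. **Features** (per segment `x(n)`, `n = 1..N`):
   - tremor intensity: `MAV = (1/N) Σ |x(n)|`, analysed as `ln(MAV)`;
   - dominant frequency, the argmax over 1–20 Hz of
     * the Welch power spectral density (Hann windows, averaged
       periodograms), and
     * the magnitude of the diagonal slice `|B(f, f)|` of the bispectrum,
       estimated indirectly as the 2-D Fourier transform of the
       Hann-lag-windowed third-order cumulant
       `C(k, l) = (1/N) Σ x(n) x(n+k) x(n+l)`.
     The bispectrum is sensitive to the quadratic phase coupling between
     a tremor fundamental and its harmonics and ignores (symmetric)
     Gaussian noise.
3. **Differentiation** (segments as instances):
   - discrimination coefficient between groups A and B,
     `α = |mean_A − mean_B| / (sd_A + sd_B)`, with `α > 0.7` marking good
     separation;
   - binary logistic regression `P(ET | x) = plogis(β0 + β1 x)` fitted by
     IRLS, ROC curve and trapezoidal AUC (equal to the Mann–Whitney rank
     statistic), and the Youden-optimal cut-off (max TPR − FPR) mapped
     back to feature units.
4. **Recording-length sweep**: α of the dominant frequency recomputed at
   segment lengths 5–300 s.

The synthetic generator draws per-subject tremor fundamentals and target
log-intensities from group models calibrated to published PD/ET cohort
summary statistics (shipped in
`inst/extdata/reference_group_stats.csv`), synthesises phase-coupled
harmonic stacks with slow amplitude/frequency modulation, postural
drift, 50 Hz mains and sensor noise, and is deterministic given a seed.

## Worked example

```r
library(tremordiff)
cfg <- experiment_config(
  cohort = cohort_config(n_per_subgroup = c(PD1 = 5, PD2 = 5, ET1 = 5, ET2 = 5),
                         recording_duration = 150, seed = 42),
  segment_length_s = 30)
report <- run_experiment(cfg)
report
```

```
<experiment_report> 200 segments, 18 analysis cells
                                 feature posture group_a group_b  alpha passes_level   auc  tpr  fpr  acc
ln_mav|P1|PD-ET                   ln_mav      P1      PD      ET 0.2191        FALSE 0.630 0.54 0.20 0.67
ln_mav|P2|PD-ET                   ln_mav      P2      PD      ET 1.1357         TRUE 0.966 0.80 0.00 0.90
domfreq_psd|P1|PD-ET         domfreq_psd      P1      PD      ET 0.2554        FALSE 0.626 0.60 0.20 0.70
domfreq_psd|P2|PD-ET         domfreq_psd      P2      PD      ET 0.7263         TRUE 0.834 0.70 0.16 0.77
domfreq_bispec|P1|PD-ET   domfreq_bispec      P1      PD      ET 0.2553        FALSE 0.622 0.60 0.20 0.70
domfreq_bispec|P2|PD-ET   domfreq_bispec      P2      PD      ET 0.7307         TRUE 0.832 0.70 0.14 0.78
```
(abridged to the pooled PD–ET rows; the full report also carries the
stage-subgroup pairs PD1–ET1 and PD2–ET2)

Every arm-rested (P2) cell clears the 0.7 differentiation level while no
arm-stretching (P1) cell does — the qualitative pattern the analysis is
designed to expose.  Drilling into one cell:

```r
res <- analyze_pair(report$feature_table, "domfreq_bispec", c("PD", "ET"), "P2")
res$discrimination
#> <discrimination> domfreq_bispec, PD (4.95 +/- 1.12) vs ET (6.58 +/- 1.11): alpha = 0.731 (> 0.70)
res$roc[c("auc", "youden_cutoff_feature", "tpr", "fpr", "acc")]
#> AUC 0.832, cut-off 6.08 Hz, TPR 0.70, FPR 0.14, ACC 0.78
```

PD tremor concentrates near 4–6 Hz and ET near 6–9 Hz, so a cut-off
around 6 Hz separates the cohorts; α ≈ 0.73 here reflects the configured
group models (means 4.7 vs 6.7 Hz, SDs 1.0 / 1.4 → analytic α = 0.83)
plus finite-cohort noise at 10 subjects per group.

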