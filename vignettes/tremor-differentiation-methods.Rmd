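---
title: "Methods: tremor differentiation from wrist accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tremor differentiation from wrist accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, numerical choices and limitations of
`tremordiff`.  It states no empirical result that the test suite or the
acceptance script does not itself compute.

## 1. The problem and the measurement model

Parkinsonian (PD) and essential tremor (ET) overlap clinically but
differ in tremor physiology: PD tremor classically sits at 4–6 Hz and is
prominent with the limb at rest or passively supported; ET is a
postural/action tremor at roughly 6–12 Hz.  The package analyses 3-axis
acceleration recorded at the third knuckle at 1000 Hz under two
postures: the conventional arm-stretching posture (P1, five 60-s trials)
and an arm-rested posture (P2, one continuous 5-min recording with the
arms supported only at the wrists).  Each subject contributes one
recording per posture; segments of a recording are the units of
analysis.

## 2. Preprocessing

The chain is: segment → notch → bandpass → decimate → axis-reduce.

* **Segmentation.** Non-overlapping consecutive windows (default 30 s)
  cut *within* trials; a window never spans a trial boundary (inter-trial
  rests are not tremor data) and trailing remainders are discarded.
* **Mains notch.** Cascaded biquad notches at 50, 100, …, 450 Hz
  (every harmonic below the 500-Hz Nyquist), quality factor `Q = 35`
  (−3 dB width `f0/Q`).  Each notch has a true zero at its centre, so
  rejection there is complete; the 1–20 Hz band is altered by
  < 0.5 dB.
* **Bandpass.** Order-2 Butterworth with edges 1–20 Hz, removing
  sub-1-Hz postural drift / sensor offset and content above the
  kinematic band.  "Zero-phase" is realised as forward–backward
  application of that design (effective order 4, squared magnitude, zero
  group delay); a linear-phase FIR would contradict the Butterworth
  specification.  Numerically, filters are designed by the analog
  prototype → bandpass transform → bilinear transform route with
  pre-warped edges, and applied in direct-form II transposed with
  steady-state initial conditions after an odd reflection of 1 s at each
  end (trimmed afterwards).  This suppresses start-up transients; it is
  the same construction as `scipy.signal.filtfilt`, against which the
  implementation was verified during development.  Edge ringing of the
  high-Q notches survives within ~0.5 s of the segment ends, which is
  why the filtering contracts in the test suite are evaluated excluding
  1-s edges.
* **Decimation.** Keep every 10th sample (1000 → 100 Hz).  Legitimate
  because the bandpass has already confined the signal far below the new
  50-Hz Nyquist.
* **Axis reduction (a design choice the measurement protocol leaves
  open).**  The three axes are projected onto the first principal
  direction of their sample covariance.  The common alternative — the
  vector magnitude — rectifies a zero-mean oscillation and doubles its
  apparent frequency, which would corrupt the dominant-frequency
  features; PC1 preserves the spectrum and maximises captured variance.
  The projection sign is fixed by requiring nonnegative sample skewness
  (the bispectrum magnitude used later is sign-invariant, so this only
  stabilises diagnostics).

## 3. Features

* **Intensity.** `MAV = mean(|x|)` per segment, analysed as `ln(MAV)`
  because intensities are heavily right-skewed across patients.  An
  exactly-zero segment yields a flagged `NA`, never `-Inf`.
* **Welch PSD.** Hann windows of 10 s (capped at the segment length),
  50% overlap, blocks mean-removed, zero-padded to a grid step of
  ≤ 0.05 Hz.  One-sided density scaling: the integral of the PSD equals
  the windowed variance (Parseval), which the tests check.  The 10-s
  window resolves the ~1–2 Hz PD/ET gap with margin; both window and
  overlap are exposed parameters.
* **Bispectrum diagonal slice.**  The third-order cumulant
  `C(k, l) = (1/N) Σ x(n) x(n+k) x(n+l)` is estimated with the biased
  `1/N` normalisation up to lag `L = 100` samples (1 s at 100 Hz,
  covering ≥ 3 cycles of the slowest tremor) and tapered by a 2-D Hann
  lag window; the bispectrum is its 2-D Fourier transform and the
  feature is `|B(f, f)|` on the diagonal.  Along the diagonal the 2-D
  transform reduces exactly to a 1-D transform of the anti-diagonal sums
  of the windowed cumulant, which is what the implementation computes
  (the test suite verifies agreement with the explicit 2-D transform and
  its `B(f1, f2) = B(f2, f1)` symmetry).  The estimator is the indirect
  (cumulant-based) one: where a text description and an equation of the
  source analysis disagree (FFT "direct" wording vs an explicitly
  cumulant-based formula), the formula was implemented; the two agree on
  coupled-harmonic signals, which is the regime of interest.  Peak
  picking uses the magnitude, not the real part, because the slice phase
  depends on the arbitrary projection orientation.
  A subtlety worth recording: for a *single* realisation the magnitude
  of the diagonal slice at `f` does not distinguish phase-coupled from
  independent tones (the triple-product phase cancels either way).  The
  classic quadratic-phase-coupling contrast appears in the magnitude of
  the *complex mean* across realisations (coupled → bispectrum phase
  locked at 0; independent → uniform phase, cancels).  `bispectrum_diag`
  therefore also returns the complex slice, and the coupling tests
  average it.
* **Dominant frequency.** Argmax of the spectrum restricted to 1–20 Hz
  (the bandpass support); ties break to the lowest frequency; an
  all-zero band yields a flagged `NA`.

## 4. Differentiation statistics

* **Discrimination coefficient** `α = |mean_A − mean_B|/(sd_A + sd_B)`
  with sample (n−1) SDs, compared against the 0.7 level.  Symmetric and
  affine-invariant; undefined (flagged) only when both SDs vanish with
  unequal means.
* **Logistic ROC.**  Single-feature binary logistic regression (ET is
  the positive class), fitted by IRLS with a deviance tolerance of 1e-8
  and ≤ 100 iterations.  Complete separation — which clean cohorts
  reach — makes the MLE diverge; it is detected by a direct separability
  check, flagged, and the slope reported at the capped magnitude.  All
  ROC quantities are rank-based, so the curve is computed from the raw
  feature oriented by the fitted slope's sign: by strict monotonicity of
  the logistic map this is identical to ranking by fitted probability
  (tested), and it remains well-defined under separation.  AUC is
  trapezoidal and equals the Mann–Whitney statistic with ties counted
  1/2 (tested exactly).  The Youden-optimal cut-off maximises TPR − FPR
  over midpoints of adjacent distinct values plus sentinels; ties break
  by higher accuracy, then lower FPR, then lower cut-off (a reporting
  convention — the source analysis states none).  Cut-offs are reported
  in feature units (Hz, or ln m/s²).
* **Unit of analysis.**  Each segment is one instance, pooling segments
  across subjects exactly as the published degrees of freedom imply
  (e.g. t(498) → 500 instances for 50 subjects × 10 segments).  The
  within-subject correlation this ignores is a known limitation of that
  design and is deliberately not corrected here.

## 5. The synthetic cohort generator

No recordings were deposited with the source study, so the generator is
the package's stand-in for patients.  It is a *stated world*: its
defaults are fixed by published group summary statistics plus a small
number of one-time choices, and tests measure the world as stated.

Per subject and posture, with an independent RNG substream keyed on
(subgroup, within-subgroup index, posture):

* fundamental `f0 ~ N(μ_f, σ_f)` truncated to (1.5, 15) Hz, and target
  intensity `ln(MAV) ~ N(μ_m, σ_m)`, with `(μ, σ)` per (group, posture)
  taken from the calibration table `inst/extdata/reference_group_stats.csv`
  (frequency targets from the bispectrum dominant-frequency rows,
  intensity from the ln MAV rows);
* tremor signal: amplitude-modulated stack of `H = 3` fully
  phase-coupled harmonics (amplitude ratios 1, 0.4, 0.15 — kept ≤ 45 Hz
  at the 15-Hz fundamental cap), with phase of harmonic `h` equal to `h`
  times the fundamental phase so the bispectrum diagonal is
  non-degenerate;
* slow modulation: instantaneous frequency wanders as an AR(1) process
  with stationary SD 0.15 Hz and 10-s time constant; the envelope is
  `1 + 0.3 sin(2π f_am t + ψ)` with `f_am ~ U(0.05, 0.2)` Hz (depth < 1
  keeps it positive);
* nuisance components: per-axis low-pass drift (SD 0.2 m/s², < 1 Hz),
  a 50-Hz mains sinusoid (0.05 m/s²) along a random direction, and white
  sensor noise (SD 0.02 m/s² per axis); tremor energy is distributed
  along a random unit direction held fixed per subject;
* session structure: P1 = five 60-s trials (trial bounds recorded), P2 =
  one 300-s trial, so both postures yield ten 30-s segments — the P1
  trial length is inferred from that bookkeeping, not stated by the
  protocol;
* intensity calibration is analytic, not iterative: the MAV of one cycle
  of the unit coupled-harmonic waveform is computed once with each
  harmonic scaled by the preprocessing chain's amplitude gain at `h·f0`,
  and the tremor amplitude is `exp(target ln MAV)` divided by that.  The
  per-subject post-pipeline ln MAV then matches its target draw to ~1%
  (tested), because PC1 recovers the tremor direction and the slow
  envelope has unit mean.

What the generator emulates: the published between-subject feature
distributions, harmonic phase coupling, mains/drift/noise nuisance that
the preprocessing must remove, determinism, and subgroup structure.
What it does not: re-emergent-tremor latency dynamics, medication
effects, within-session nonstationarity beyond the stationary AR(1)
wander, EMG, or any kinematic cross-axis structure beyond a fixed
direction.  A green cohort-level test therefore establishes calibration
and pipeline correctness — not clinical realism.

Units: accelerations are nominally m/s²; the calibration tables are
reproduced in whatever unit the published intensities used, which the
source never states.  All ln MAV values are relative to that unit.

## 6. Numerical choices and degenerate inputs

* Frequency grids: FFTs zero-padded to the next power of two giving
  ≤ 0.05 Hz spacing; dominant-frequency agreement tests allow one grid
  step.
* Biased (`1/N`) cumulant normalisation: tapers large lags, combines
  cleanly with the Hann lag window, and is standard for indirect
  bispectrum estimation.
* All-zero segments: flagged `degenerate` in provenance; features become
  flagged `NA`s and are carried, never silently dropped.
* Logistic IRLS caps the standardised slope at 30 (probabilities
  saturate at machine precision far below that); weights are floored at
  1e-12.
* The analysis treats `sd` with denominator n−1 throughout; with
  segments as instances this makes the per-segment SD of a cohort of n
  subjects slightly smaller (factor ≈ √((n−1)/n)) than the n-subject SD,
  which matters when comparing segment lengths (see §7).

## 7. Known limitations

* **Recording-length trend.**  In real tremor data the discrimination
  coefficient of dominant frequency rises with segment length, because
  short segments carry substantial estimator variance and tremor is
  nonstationary.  In this generator's stated world the signals are
  near-periodic at high SNR, so 5-s estimates are almost as good as
  300-s ones, and the small-sample SD arithmetic above even gives short
  segments a slight systematic advantage.  The rising-trend acceptance
  property therefore fails honestly here; the test is retained and the
  discrepancy is analysed rather than the generator being re-tuned after
  the fact.
* The within-subject correlation of pooled segments is ignored by
  design (matching the source analysis); α values and AUCs are
  optimistic relative to a subject-level analysis.
* No confidence intervals on AUC, no ANOVA/normality-test battery, no
  EMG handling, no clinical scales: out of scope.
* P1 recordings cannot supply segments longer than one trial (60 s);
  sweep cells beyond that are marked unavailable rather than spliced
  across rests, which would manufacture spectral artefacts.
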