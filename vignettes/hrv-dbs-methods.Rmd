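---
title: "Methods: HRV analysis of DBS block paradigms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HRV analysis of DBS block paradigms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hrvdbs)
```

# The problem

Central-thalamic deep brain stimulation (DBS) in disorders-of-consciousness
(DOC) patients is typically tested with a block paradigm: the stimulator is
switched on for 30 minutes, then off for 90, four times across a day, on
consecutive days at different stimulation frequencies (25, 50, 100 Hz).
Heart-rate variability (HRV) around each block quantifies how the
stimulation perturbs the autonomic nervous system: shorter mean RR interval
and more low-frequency (LF) oscillation indicate sympathetic activation,
less high-frequency (HF) oscillation indicates vagal withdrawal. The package
implements the full measurement chain — ECG to RR intervals, RR to the eight
standard short-segment HRV indices, block-paradigm epoching, the associated
statistics, and a small prognosis classifier with exact Shapley feature
attribution — together with a cohort simulator, so the entire pipeline can
be exercised and validated without patient recordings.

# Measurement chain

## ECG to RR

ECG arrives as two-column delimited text with a JSON sidecar
(`sampling_rate`, `subject_id`). `powerline_notch()` removes mains
interference with a zero-phase spectral notch. `detect_r_peaks()` is a
Pan–Tompkins-style chain: 5–25 Hz zero-phase bandpass, second-order
difference, squaring, 150 ms moving-window integration, adaptive threshold
per 10 s chunk with a 250 ms refractory period, and refinement of each peak
to the raw-signal maximum within ±50 ms (the raw signal, so no filter delay
can bias beat times). All thresholds are relative, making detection
invariant to amplitude scaling. `clean_rr()` flags intervals deviating more
than 20% from the local median (up to 5 nearest neighbours) or outside
300–2000 ms, and replaces them by cubic-spline interpolation through the
neighbouring normal intervals; a segment with more than 5% corrections, or
any gap over 3 s (`segment_quality()`), is unusable and skipped downstream.
These thresholds are standard HRV-preprocessing conventions, not values
taken from any particular study, and all are configurable.

## RR to indices

Time-domain indices (mRRI, SDNN, both in ms, SDNN with the n−1 denominator)
are computed on the NN intervals before any resampling. The spectral chain
for a 3-minute segment is:

1. cubic-spline resampling onto a uniform 4 Hz grid (the conventional rate;
   "quadric spline" in parts of the literature is read as cubic, the
   standard choice),
2. smoothness-priors detrending, `x − (I + λ²D₂ᵀD₂)⁻¹x` with λ = 500 at
   4 Hz (cutoff ≈ 0.035 Hz, safely below the 0.04 Hz analysis floor; λ is
   the standard default since no value is universal),
3. Burg AR(19) fit (classic lattice recursion, reflection coefficients
   minimizing summed forward+backward prediction error),
4. one-sided AR spectrum
   `P(f) = 2σ²/(fs·|1 + Σ aₖe^{−i2πkf/fs}|²)` on a 1024-point grid —
   normalized so the integral over (0, fs/2] equals the process variance,
   which the tests verify against the detrended segment variance (≤5%),
5. trapezoidal band powers: LF 0.04–0.15 Hz, HF 0.15–0.4 Hz, TP their
   union 0.04–0.4 Hz, so TP = LF + HF exactly and the VLF range is excluded
   by construction (it is also what the detrending removed);
   nLF = 100·LF/(LF+HF), nHF its complement, LF/HF the ratio (missing, not
   infinite, when HF = 0).

## Paradigm epoching

`build_schedule()` produces the four-block day; `phase_windows()` places
Pre as the 3 minutes ending at stimulation onset, On as the *last* 3
minutes of the on-period (steady-state response; the placement inside the
30-minute window is not standardized, so it is configurable), and Post as
the 3 minutes from offset. `delta_features()` computes per-subject changes
(default Post − Pre; On − Pre available because the acute contrast is also
of interest) averaged over usable blocks, per frequency day or averaged
across days (8 features per subject).

## Statistics

`rm_anova_eta2()` is a one-way within-subject ANOVA with partial
η² = SS_cond/(SS_cond + SS_err); no sphericity correction by default.
`paired_t()`, `welch_t()` and `mann_whitney_exact()` (full enumeration for
n ≤ 12, mid-ranks for ties, normal approximation beyond) cover the group
contrasts; `holm_adjust()` exists but no correction is applied by default,
mirroring common practice in small exploratory cohorts. All tests are
verified against from-scratch oracles to 1e-8.

## Prognosis

Outcome is improvement of the CRS-R score by ≥3 points at follow-up.
`train_svm()` is an L2-regularized hinge-loss linear SVM solved by dual
coordinate descent (deterministic; bias via an augmented constant feature),
C = 1 by default — a linear kernel because a handful of subjects cannot
support kernel tuning. `cross_validated_auc()` uses stratified 5-fold
assignment (unstratified folds at 3 positives of 8 routinely produce
single-class training sets), standardization fit on training folds only,
and the rank (Mann–Whitney) AUC; folds with a single-class validation set
yield a missing AUC rather than 0.5. `shapley_attributions()` enumerates
all 2^d coalitions with background-mean masking, so efficiency, symmetry
and null-player hold exactly for d ≤ 15.

### Why the ranking fit is strongly regularized

`compare_feature_sets()` ranks features by mean |φ| of a fit whose cost
defaults to `C_rank = 0.2/n` rather than 1. Two facts force this. First,
TP = LF + HF *exactly* (shared grid), so the informative block is linearly
dependent and a soft-margin fit splits its weight arbitrarily — whenever
TP and HF carry equal functional weight, LF's weight is exactly zero.
Second, with n of order 10–40 a margin solution recruits independent noise
features because they always improve in-sample separability. As C → 0 the
linear SVM converges to the standardized class-mean-difference
(nearest-centroid) direction, whose Shapley ranking tracks each feature's
actual standardized group separation — which is what a feature-importance
ranking is meant to measure. The cross-validated classifiers keep C = 1.

# The synthetic cohort

## Generative model

RR series come from an integral pulse frequency modulation (IPFM) model:
beats are emitted when the integral of `(1 + m(t))/T₀` crosses successive
integers, with

`m(t) = a_LF·sin(2πf_LF t + φ_LF) + a_HF·sin(2πf_HF t + φ_HF) + noise + drift`

- oscillators at f_LF = 0.095 Hz and f_HF = 0.275 Hz (band centres),
  default amplitudes 0.06;
- broadband noise: Gaussian knots at 1 s, linearly interpolated,
  sd 0.02;
- VLF drift: Gaussian knots at 30 s, sd 0.06 in cohorts (0 elsewhere).
  The drift emulates the very-low-frequency component that dominates the
  variance of real RR series; it is excluded from the band powers by
  detrending but fully present in SDNN, which is what decouples SDNN from
  TP — without it, SDNN² ≈ band power and the two indices could never
  carry different information.

Validity requires `a_LF + a_HF + 3(noise_sd + drift_sd) < 1` so the
instantaneous rate stays positive. ECG synthesis places a Mexican-hat QRS
(80 ms wide, 1 mV) at each beat over Gaussian noise, at 500 Hz by default —
enough for ±10 ms RR precision at a fraction of a clinical 16 kHz record.

## The injected stimulation effect

Stated once, a priori, as the simulator's world — the source literature
reports directions and significance, not effect sizes:

| frequency | ΔmRRI (On) | LF amplitude gain | HF gain | drift gain |
|-----------|-----------|-------------------|---------|------------|
| 25 Hz     | −20 ms    | 1.3               | 0.85    | 1.3        |
| 50 Hz     | −40 ms    | 1.6               | 0.70    | 1.6        |
| 100 Hz    | −60 ms    | 2.0               | 0.55    | 2.0        |

Effects apply to the generative parameters during On (never post hoc to
the intervals) and persist after offset at carry-over 0.5 for 300 s —
Pre→Post deltas would otherwise be null, contradicting the reported
paradigm. Carry-over attenuates gains *geometrically* (`g^0.5`): additive
attenuation breaks the LF/HF-ratio neutrality of the outcome effect below
and leaks group information into the normalized indices. Improved subjects
receive an extra symmetric gain of 1.4 on both band amplitudes, which
raises their ΔTP/ΔLF/ΔHF while leaving nLF/nHF/LF-HF group-neutral (the
ratio is preserved) and mRRI untouched. Subject heterogeneity: T₀ ~
N(0.9, 0.05) s, band amplitudes lognormal (sd 0.10), HF amplitude
additionally lognormal per day (sd 0.15; vagal tone is the most labile
component), and drift reactivity as a stable per-subject trait, lognormal
across subjects (sd 0.5, truncated at ±2 sd, capped at 2.8). The
between-subject drift-reactivity spread is what makes ΔSDNN
outcome-uninformative, as reported for real cohorts; drawing it as a
subject trait (not per day) lets the paired dose contrasts cancel it, so
SDNN's dose ordering stays detectable.

## What a green test does and does not establish

The simulator produces stationary oscillators plus knotted noise; real RR
series have time-varying respiratory frequency, ectopy, arrhythmia and
nonstationary trends far richer than this. Green acceptance tests establish
that the *pipeline* measures what the generative model injects (spectral
fidelity, effect directions, dose ordering, attribution recovery) — they
say nothing about clinical validity in patients. The Shapley-ranking
recovery property is tested on 40-subject cohorts: at n = 8 with 3
responders, the chance standardized separation of an uninformative feature
has sd ≈ 0.73, so no stated world makes an 8-subject ranking reliably
identifiable; the published 8-patient ranking should be read with the same
caveat.

# Numerical choices and degenerate inputs

- IPFM integration on a 1/64 s grid (1/32 s inside the cohort simulator),
  crossings located by linear interpolation: beat-time error well under
  0.1 ms.
- The detrending operator is solved via a cached sparse Cholesky
  factorization keyed by (length, λ).
- Burg on a constant segment errors (zero variance); AR(19) on 720 samples
  satisfies the order < n/2 requirement with a wide margin.
- `clean_rr` is idempotent; flat ECG yields an empty peak series with a
  warning, not an exception; windows outside the recording are missing, not
  zero.
- Mann–Whitney with every observation tied returns p = 1; a paired t on
  zero-variance differences reports a missing p with a warning (0/0 is not
  a statistic).
- All randomness flows from explicit seeds; cohorts are bit-reproducible
  given the spec.

# Known limitations

- No VLF-band analysis, Lomb–Scargle, or nonlinear indices (Poincaré, DFA,
  multiscale entropy) — out of scope by design.
- Single-lead, single-template ECG synthesis; no arrhythmia simulation, so
  the ectopic-repair path is exercised with injected artifacts rather than
  physiological ectopy.
- The WFDB container format is not read or written; the delimited + sidecar
  interface is the supported exchange format.
- The exact Shapley enumeration is capped at 15 features; no sampling
  approximation is provided.
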