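# hrvdbs

Heart-rate-variability (HRV) analysis for block-design deep-brain-stimulation
(DBS) experiments, built for the central-thalamic stimulation paradigm used
in disorders-of-consciousness (DOC) cohorts: stimulation on for 30 min, off
for 90 min, four blocks per day, one day each at 25/50/100 Hz, with ECG
recorded throughout and consciousness (CRS-R) scored at baseline and
follow-up.

The package covers the whole measurement chain:

- **ECG → RR**: powerline notch, Pan–Tompkins-style R-peak detection
  (bandpass → second difference → squaring → integration → adaptive
  threshold, 250 ms refractory), ectopic-beat repair, segment quality
  control.
- **RR → indices**: the eight standard short-segment indices for 3-minute
  windows. Time domain on NN intervals: mRRI, SDNN. Frequency domain via
  cubic-spline resampling at 4 Hz, smoothness-priors detrending
  (x − (I + λ²D₂ᵀD₂)⁻¹x, λ = 500) and a Burg AR(19) spectrum
  P(f) = 2σ²/(fs·|1 + Σₖ aₖe^(−i2πkf/fs)|²), integrated over
  LF 0.04–0.15 Hz, HF 0.15–0.4 Hz, TP = LF ∪ HF;
  nLF = 100·LF/(LF+HF), nHF = 100·HF/(LF+HF), and LF/HF.
- **Paradigm**: schedules, Pre/On/Post 3-min windows per block, tidy index
  tables, per-subject Δ features (Post − Pre or On − Pre).
- **Statistics**: repeated-measures ANOVA with partial η², paired and Welch
  t, exact Mann–Whitney (full enumeration for n ≤ 12), Holm adjustment.
- **Prognosis**: responder labelling (ΔCRS-R ≥ 3), deterministic linear SVM
  (dual coordinate descent), stratified 5-fold cross-validated rank AUC,
  exact Shapley attribution over all 2^d coalitions, and full-vs-top-k
  feature-set comparison.
- **Synthetic cohorts**: an integral-pulse-frequency-modulation (IPFM)
  generator with LF/HF oscillators, broadband noise and VLF drift, plus
  injectable stimulation-locked effects (mRRI↓, SDNN↑, LF↑, HF↓ during On,
  dose-ordered with frequency, outcome-linked band-power gains), so every
  stage is testable end to end without patient data.

## Worked example

```r
library(hrvdbs)

spec   <- cohort_spec(n_subjects = 8, n_improved = 3, seed = 1)
cohort <- simulate_cohort(spec)          # 8 subjects x 3 days x 4 blocks
idx    <- phase_indices(cohort)          # 288 rows: subject/day/block/phase
head(idx[, c("subject","day","frequency","block","phase","mRRI","SDNN","LF","HF")], 3)
#>   subject day frequency block phase  mRRI   SDNN   LF   HF
#> 1     S01   1        25     1   Pre 882.0  69.18 2212 1655
#> 2     S01   1        25     1    On 889.9 112.96 7244 2770
#> 3     S01   1        25     1  Post 806.9  81.78 2966 1543

phase_contrasts(idx)[c(1, 2, 4, 3), c("index", "F", "p", "eta2")]
#>   index    F        p  eta2
#> 1  mRRI 10.8 1.43e-03 0.608
#> 2  SDNN 31.3 6.84e-06 0.817
#> 4    LF 18.5 1.16e-04 0.726
#> 3    TP 13.7 5.11e-04 0.661

feats <- delta_features(idx)                      # 8 Delta-features/subject
labs  <- label_outcomes(cohort$labels)
X <- as.matrix(feats[, c("mRRI","SDNN","TP","LF","HF","nLF","nHF","LF_HF")])
y <- labs$improved[match(feats$subject, labs$subject)]
cmp <- compare_feature_sets(X, y, top_k = 3, seed = 1)
cmp$ranking
#> [1] "TP" "LF" "HF" "nLF" "nHF" "SDNN" "LF_HF" "mRRI"
sprintf("AUC all: %.2f +/- %.2f | top-3: %.2f +/- %.2f",
        cmp$all$mean_auc, cmp$all$sd_auc, cmp$top$mean_auc, cmp$top$sd_auc)
#> [1] "AUC all: 1.00 +/- 0.00 | top-3: 1.00 +/- 0.00"
```

Reading the output: the per-phase F tests show the injected acute response
(mRRI drops during On, SDNN/LF/TP rise, with partial η² the share of
within-subject variance the phase explains). The attribution ranks the
three injected informative features TP, LF, HF on top for this draw — with
only 8 subjects the ranking has seed-to-seed variability (see the methods
vignette); at n = 40 the recovery is stable. AUC 1.0 reflects the strong
injected outcome effect in this synthetic world, not a clinical claim.

The one-command reproduction:

```r
run_all(run_config(seed = 1), out_dir = "hrvdbs_out")
# writes rr/, hrv_indices.csv, phase_stats.csv, freq_stats.csv,
# features.csv, labels.csv, prognosis.json, run.log
```

or from the shell: `inst/cli/hrvdbs all --out hrvdbs_out --seed 1`.

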