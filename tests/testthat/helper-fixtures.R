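# Shared fixtures: built in code at test time, never stored.

# A clean constant RR series (intervals in ms).
constant_rr <- function(n = 60, rr_ms = 1000, t0 = 0) {
  rri_series(t0 + seq(0, by = rr_ms / 1000, length.out = n + 1))
}

# Oracle match of detected peaks against generator beat times.
match_peaks <- function(detected, truth, tol = 0.010) {
  hit_truth <- vapply(truth, function(b) any(abs(detected - b) <= tol),
                      logical(1))
  hit_det <- vapply(detected, function(b) any(abs(truth - b) <= tol),
                    logical(1))
  list(recall = mean(hit_truth), precision = mean(hit_det))
}

# Periodogram band-power ratio oracle on a long RR realization -- kept
# independent of the package's Burg/AR spectral path.
periodogram_lf_hf <- function(rr, fs = 4, lambda = 500) {
  u <- resample_cubic_spline(rr, fs = fs)
  d <- detrend_smoothness_priors(u, lambda = lambda)
  sp <- stats::spec.pgram(stats::ts(d$values, frequency = fs), taper = 0,
                          plot = FALSE, detrend = FALSE)
  lf <- sum(sp$spec[sp$freq >= 0.04 & sp$freq < 0.15])
  hf <- sum(sp$spec[sp$freq >= 0.15 & sp$freq <= 0.4])
  lf / hf
}

# Small fast cohort spec for unit tests (short blocks, 1 day).
tiny_cohort_spec <- function(seed, n_subjects = 4, n_improved = 2,
                             frequencies = 100, n_blocks = 2,
                             effect = effect_model()) {
  cohort_spec(n_subjects = n_subjects, n_improved = n_improved,
              frequencies = frequencies, n_blocks = n_blocks,
              on_duration = 600, off_duration = 600, day_start = 300,
              effect = effect, seed = seed)
}

# Feature matrix + labels straight from a cohort.
cohort_features <- function(cohort, contrast = "post_minus_pre", ...) {
  idx <- phase_indices(cohort, ...)
  feats <- delta_features(idx, contrast = contrast)
  labs <- label_outcomes(cohort$labels)
  list(X = as.matrix(feats[, c("mRRI", "SDNN", "TP", "LF", "HF",
                               "nLF", "nHF", "LF_HF")]),
       y = labs$improved[match(feats$subject, labs$subject)],
       indices = idx, features = feats, labels = labs)
}
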