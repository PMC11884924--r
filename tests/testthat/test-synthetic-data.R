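test_that("unmodulated IPFM emits a metronome", {
  rr <- simulate_rr_ipfm(ipfm_params(T0 = 1, a_LF = 0, a_HF = 0,
                                     noise_sd = 0), 60)
  expect_true(all(abs(rr$intervals - 1000) < 0.5))
  expect_gte(length(rr$beat_times), 59)
  expect_lte(length(rr$beat_times), 60)
})

test_that("IPFM parameter invariants are enforced", {
  expect_error(ipfm_params(a_LF = 0.6), "amplitudes")
  expect_error(ipfm_params(a_LF = 0.45, a_HF = 0.45, noise_sd = 0.05),
               "rate would hit zero")
  expect_error(ipfm_params(f_LF = 0.2), "f_LF")
  expect_error(ipfm_params(f_HF = 0.1), "f_HF")
  expect_error(simulate_rr_ipfm(ipfm_params(), 5), "duration")
})

test_that("LF modulation produces the dominant spectral peak at f_LF", {
  set.seed(11)
  rr <- simulate_rr_ipfm(ipfm_params(T0 = 0.9, a_LF = 0.1, a_HF = 0,
                                     noise_sd = 0), 600)
  u <- resample_cubic_spline(rr, fs = 4)
  d <- detrend_smoothness_priors(u)
  sp <- stats::spec.pgram(stats::ts(d$values, frequency = 4), taper = 0,
                          plot = FALSE, detrend = FALSE)
  expect_lt(abs(sp$freq[which.max(sp$spec)] - 0.095), 0.01)
})

test_that("beat times are strictly increasing and effects respect timelines", {
  set.seed(12)
  tl <- effect_timeline(100, 200, delta_T0_ms = -100)
  rr <- simulate_rr_ipfm(ipfm_params(T0 = 1, a_LF = 0, a_HF = 0, noise_sd = 0),
                         300, effect_timeline = tl)
  expect_true(all(diff(rr$beat_times) > 0))
  inside <- rr$beat_times[-1] > 110 & rr$beat_times[-1] < 200
  outside <- rr$beat_times[-1] < 95 | rr$beat_times[-1] > 210
  expect_lt(mean(rr$intervals[inside]), 910)
  expect_gt(mean(rr$intervals[outside]), 990)
  expect_error(effect_timeline(c(0, 50), c(100, 150)), "overlap")
})

test_that("synthesized ECG round-trips through the detector", {
  set.seed(13)
  rr <- simulate_rr_ipfm(ipfm_params(T0 = 0.85), 60)
  ecg <- synthesize_ecg(rr, 500, noise_sd = 0)
  pk <- detect_r_peaks(ecg)
  m <- match_peaks(pk$peak_times, rr$beat_times)
  expect_gte(m$recall, 0.99)
  expect_gte(m$precision, 0.99)
  # empty series -> flat record
  empty <- rri_series(numeric(0), numeric(0), character(0))
  expect_length(synthesize_ecg(empty, 500)$samples, 0)
  # overlapping beats rejected
  fast <- rri_series(c(0, 0.05, 0.1), c(50, 50), c("normal", "normal"))
  expect_error(synthesize_ecg(fast, 500), "template longer")
})

test_that("cohort simulation is seed-deterministic", {
  a <- simulate_cohort(tiny_cohort_spec(seed = 42))
  b <- simulate_cohort(tiny_cohort_spec(seed = 42))
  expect_identical(a$subjects[[1]]$days[[1]]$rr$intervals,
                   b$subjects[[1]]$days[[1]]$rr$intervals)
  expect_identical(a$labels, b$labels)
  c <- simulate_cohort(tiny_cohort_spec(seed = 43))
  expect_false(identical(a$subjects[[1]]$days[[1]]$rr$intervals,
                         c$subjects[[1]]$days[[1]]$rr$intervals))
})

test_that("cohort labels contain exactly n_improved improved subjects", {
  coh <- simulate_cohort(cohort_spec(n_subjects = 8, n_improved = 3,
                                     frequencies = 100, n_blocks = 1,
                                     on_duration = 600, off_duration = 600,
                                     day_start = 300, seed = 5))
  labs <- label_outcomes(coh$labels)
  expect_identical(sum(labs$improved), 3L)
  expect_identical(labs$improved,
                   (labs$crs_r_followup - labs$crs_r_baseline) >= 3)
})

test_that("injected mRRI effect is recovered from generator intervals", {
  # oracle = direct mean of generator intervals inside On vs Pre windows
  deltas <- vapply(1:10, function(s) {
    em <- effect_model(frequencies = 100, delta_mRRI = -50, gain_LF = 1,
                       gain_HF = 1, gain_drift = 1, drift_subject_sd = 0,
                       outcome_effect = 1)
    coh <- simulate_cohort(tiny_cohort_spec(seed = s, effect = em))
    d <- unlist(lapply(coh$subjects, function(subj) {
      day <- subj$days[[1]]
      vapply(seq_len(nrow(day$schedule)), function(b) {
        w <- phase_windows(day$schedule$on_start[b], day$schedule$on_end[b])
        on <- rr_window(day$rr, w$start[2], w$end[2])
        pre <- rr_window(day$rr, w$start[1], w$end[1])
        mean(on$intervals) - mean(pre$intervals)
      }, numeric(1))
    }))
    mean(d)
  }, numeric(1))
  expect_lt(abs(mean(deltas) - (-50)), 10)
})

test_that("null cohorts give calibrated paired tests", {
  # zero-effect world; paired Pre/On t test on mRRI across subjects.
  # 200 simulated datasets, scaled down to short single-frequency sessions.
  null_em <- effect_model(delta_mRRI = c(0, 0, 0), gain_LF = c(1, 1, 1),
                          gain_HF = c(1, 1, 1), gain_drift = c(1, 1, 1),
                          drift_subject_sd = 0, outcome_effect = 1)
  p <- vapply(1:200, function(s) {
    coh <- simulate_cohort(tiny_cohort_spec(seed = 1000 + s, n_subjects = 8,
                                            n_improved = 0, n_blocks = 1,
                                            effect = null_em))
    d <- vapply(coh$subjects, function(subj) {
      day <- subj$days[[1]]
      w <- phase_windows(day$schedule$on_start[1], day$schedule$on_end[1])
      mean(rr_window(day$rr, w$start[2], w$end[2])$intervals) -
        mean(rr_window(day$rr, w$start[1], w$end[1])$intervals)
    }, numeric(1))
    paired_t(d, rep(0, length(d)))$p_value
  }, numeric(1))
  rej <- mean(p < 0.05)
  expect_gte(rej, 0.01)
  expect_lte(rej, 0.12)
})
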