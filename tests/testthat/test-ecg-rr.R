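test_that("read_ecg parses delimited records and validates metadata", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "toy.csv")
  writeLines(c("time_s,voltage_mV", "0.000,0.1", "0.002,0.2", "0.004,0.1"), p)
  jsonlite::write_json(list(sampling_rate = 500, subject_id = "S01"),
                       paste0(p, ".json"), auto_unbox = TRUE)
  rec <- read_ecg(p)
  expect_length(rec$samples, 3)
  expect_equal(rec$sampling_rate, 500)
  expect_equal(rec$subject_id, "S01")

  # missing sidecar -> error
  p2 <- file.path(dir, "orphan.csv")
  writeLines(c("time_s,voltage_mV", "0,0.1", "0.002,0.2"), p2)
  expect_error(read_ecg(p2), "sidecar")

  # non-monotone time column -> error
  p3 <- file.path(dir, "bad.csv")
  writeLines(c("time_s,voltage_mV", "0,0.1", "0.004,0.2", "0.002,0.1"), p3)
  jsonlite::write_json(list(sampling_rate = 500), paste0(p3, ".json"),
                       auto_unbox = TRUE)
  expect_error(read_ecg(p3), "increasing")
})

test_that("ECG write/read round-trips", {
  set.seed(20)
  rr <- simulate_rr_ipfm(ipfm_params(), 30)
  ecg <- synthesize_ecg(rr, 250, noise_sd = 0.05)
  ecg$subject_id <- "S07"
  p <- file.path(withr::local_tempdir(), "rt.csv")
  write_ecg(ecg, p)
  back <- read_ecg(p)
  expect_equal(back$samples, ecg$samples, tolerance = 1e-6)
  expect_equal(back$sampling_rate, 250)
  expect_equal(back$subject_id, "S07")
})

test_that("powerline notch kills mains and spares the passband", {
  fs <- 500
  tt <- (0:(20 * fs - 1)) / fs
  rms <- function(x) sqrt(mean(x^2))
  out50 <- powerline_notch(ecg_record(sin(2 * pi * 50 * tt), fs))
  expect_lte(rms(out50$samples), 0.10 * rms(sin(2 * pi * 50 * tt)))
  out10 <- powerline_notch(ecg_record(sin(2 * pi * 10 * tt), fs))
  expect_lt(abs(rms(out10$samples) / rms(sin(2 * pi * 10 * tt)) - 1), 0.12)
  zero <- powerline_notch(ecg_record(numeric(1000), fs))
  expect_true(all(abs(zero$samples) < 1e-12))
  expect_error(powerline_notch(ecg_record(numeric(10), 80), mains_freq = 50),
               "Nyquist")
})

test_that("R-peak detection handles degenerate and close-beat input", {
  expect_warning(pk <- detect_r_peaks(ecg_record(numeric(5000), 500)), "flat")
  expect_length(pk$peak_times, 0)
  # two template beats 100 ms apart -> one detection (refractory)
  fs <- 500
  x <- numeric(12 * fs)
  tpl <- qrs_mexican_hat(fs)
  put <- function(x, at) {
    i <- round(at * fs) + seq_along(tpl) - (length(tpl) - 1) / 2
    x[i] <- x[i] + tpl
    x
  }
  x <- put(x, 6); x <- put(x, 6.1)
  pk2 <- detect_r_peaks(ecg_record(x, fs))
  expect_length(pk2$peak_times, 1)
  expect_error(detect_r_peaks(ecg_record(numeric(100), 500)), "10 s")
})

test_that("detection is amplitude-scale invariant", {
  set.seed(21)
  rr <- simulate_rr_ipfm(ipfm_params(T0 = 0.8), 60)
  ecg <- synthesize_ecg(rr, 500, noise_sd = 0.05)
  p1 <- detect_r_peaks(ecg)$peak_times
  for (c in c(0.01, 7)) {
    scaled <- ecg_record(ecg$samples * c, 500, ecg$start_time)
    expect_equal(detect_r_peaks(scaled)$peak_times, p1)
  }
})

test_that("end-to-end RR fidelity on noiseless synthetic ECG", {
  set.seed(22)
  rr <- simulate_rr_ipfm(ipfm_params(T0 = 0.9, a_LF = 0.08, a_HF = 0.08), 120)
  ecg <- synthesize_ecg(rr, 500, noise_sd = 0)
  ext <- peaks_to_rr(detect_r_peaks(ecg))
  truth <- rr$intervals
  # align on beat times, compare matched intervals
  idx <- vapply(ext$beat_times, function(b) which.min(abs(rr$beat_times - b)),
                integer(1))
  err <- abs(ext$intervals - truth[pmin(idx[-length(idx)], length(truth))])
  expect_gte(mean(err <= 10), 0.99)
})

test_that("clean_rr flags, corrects and is idempotent", {
  rr <- constant_rr(60)
  out <- clean_rr(rr)
  expect_identical(out$intervals, rr$intervals)
  expect_identical(out$n_corrected, 0L)

  # single ectopic: one correction, plausible replacement
  iv <- rep(1000, 40); iv[20] <- 500
  bt <- c(0, cumsum(iv) / 1000)
  dirty <- rri_series(bt, iv)
  fixed <- clean_rr(dirty)
  expect_identical(fixed$n_corrected, 1L)
  expect_identical(fixed$flags[20], "corrected")
  expect_gt(fixed$intervals[20], 900)
  expect_lt(fixed$intervals[20], 1100)
  expect_true(fixed$usable)
  # idempotence
  again <- clean_rr(fixed)
  expect_equal(again$intervals, fixed$intervals)
  expect_identical(again$n_corrected, fixed$n_corrected)

  # 10% spikes -> unusable
  set.seed(23)
  iv2 <- rep(1000, 50); iv2[sample(50, 5)] <- 400
  spiky <- clean_rr(rri_series(c(0, cumsum(iv2) / 1000), iv2))
  expect_false(spiky$usable)

  expect_error(clean_rr(constant_rr(5)), "at least 10")
})

test_that("segment_quality applies the correction and gap rules", {
  rr <- clean_rr(constant_rr(120))
  expect_true(segment_quality(rr, 10, 100)$usable)

  # 5 s dropout inside the window -> unusable
  bt <- c(seq(0, 50, by = 1), seq(55, 100, by = 1))
  gap <- rri_series(bt, diff(bt) * 1000)
  expect_false(segment_quality(gap, 10, 90)$usable)

  # exactly 5% corrections -> usable (boundary inclusive)
  iv <- rep(1000, 40)
  flags <- rep("normal", 40); flags[1:2] <- "corrected"
  b5 <- rri_series(c(0, cumsum(iv) / 1000), iv, flags)
  q <- segment_quality(b5, 0, 40)
  expect_equal(q$correction_fraction, 0.05)
  expect_true(q$usable)
})

test_that("RR write/read round-trips with flags", {
  set.seed(24)
  rr <- clean_rr(simulate_rr_ipfm(ipfm_params(), 60))
  p <- file.path(withr::local_tempdir(), "rr.csv")
  write_rr(rr, p, header = "unit test")
  back <- read_rr(p)
  expect_equal(back$intervals, rr$intervals, tolerance = 1e-9)
  expect_identical(back$flags, rr$flags)
})
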