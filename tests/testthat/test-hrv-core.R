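test_that("time-domain indices match hand computations", {
  expect_equal(time_domain_indices(constant_rr(30)),
               list(mRRI = 1000, SDNN = 0))
  rr <- rri_series(c(0, 0.8, 1.8, 3.0), c(800, 1000, 1200))
  td <- time_domain_indices(rr)
  expect_equal(td$mRRI, 1000)
  expect_equal(td$SDNN, 200)   # n - 1 denominator
  # generator oracle: known mean interval
  set.seed(30)
  ipfm <- simulate_rr_ipfm(ipfm_params(T0 = 0.9), 300)
  expect_lt(abs(time_domain_indices(ipfm)$mRRI - 900) / 900, 0.02)
})

test_that("cubic-spline resampling reproduces polynomials and tones", {
  const <- resample_cubic_spline(constant_rr(60), fs = 4)
  expect_true(all(abs(const$values - 1000) < 1e-9))
  expect_equal(length(const$values), 4 * 59 + 1)

  # linear trend preserved (cubic spline reproduces degree-1 exactly)
  bt <- seq(0, 60, by = 1)
  iv <- seq(900, 1100, length.out = 60)
  lin <- resample_cubic_spline(rri_series(bt, iv), fs = 4)
  fit <- stats::lm(lin$values ~ seq_along(lin$values))
  expect_lt(max(abs(stats::resid(fit))), 1e-6)

  # 0.1 Hz modulation recovered
  bt2 <- seq(0, 120, by = 0.9)
  iv2 <- 900 + 100 * sin(2 * pi * 0.1 * bt2[-1])
  tone <- resample_cubic_spline(rri_series(bt2, iv2), fs = 4)
  sp <- stats::spec.pgram(stats::ts(tone$values - mean(tone$values),
                                    frequency = 4), taper = 0, plot = FALSE)
  expect_lt(abs(sp$freq[which.max(sp$spec)] - 0.1), 2 * sp$freq[1])

  expect_error(resample_cubic_spline(constant_rr(20), fs = 4), "30 s")
})

test_that("smoothness-priors detrending has the contracted transfer function", {
  expect_equal(detrend_smoothness_priors(numeric(100), 500), numeric(100))
  x <- stats::rnorm(50)
  expect_lt(max(abs(detrend_smoothness_priors(x, 0))), 1e-9)
  expect_error(detrend_smoothness_priors(x, -1), "non-negative")

  # tone attenuation at lambda = 500, fs = 4 (interior, away from edges)
  n <- 720; tt <- (0:(n - 1)) / 4
  atten <- vapply(c(0.01, 0.04, 0.10), function(f0) {
    out <- detrend_smoothness_priors(sin(2 * pi * f0 * tt), 500)
    core <- 150:570
    1 - stats::sd(out[core]) / stats::sd(sin(2 * pi * f0 * tt)[core])
  }, numeric(1))
  expect_gte(atten[1], 0.90)   # 0.01 Hz: >= 90% removed
  expect_lte(atten[3], 0.10)   # 0.10 Hz: <= 10% touched
  expect_lt(atten[2], atten[1])  # attenuation decreasing with frequency
})

test_that("Burg fit recovers AR coefficients and white-noise reflections", {
  # AR(2) oracle: Yule-Walker solved from the sample autocovariance
  set.seed(31)
  x <- as.numeric(stats::arima.sim(list(ar = c(1.0, -0.5)), 2000))
  fit <- burg_fit(x, order = 2)
  phi_hat <- -fit$coefficients
  acf0 <- stats::acf(x, lag.max = 2, plot = FALSE, demean = TRUE)$acf
  yw <- solve(matrix(c(1, acf0[2], acf0[2], 1), 2), acf0[2:3])
  expect_lt(max(abs(phi_hat - c(1.0, -0.5))), 0.05)
  expect_lt(max(abs(phi_hat - yw)), 0.02)     # agrees with the YW oracle

  # white noise: reflection coefficients small with high probability
  set.seed(32)
  refl <- replicate(100, burg_fit(stats::rnorm(720), order = 19)$reflection)
  expect_gte(mean(abs(refl) < 0.2), 0.95)

  expect_error(burg_fit(rep(1, 100), order = 5), "constant")
  expect_error(burg_fit(stats::rnorm(30), order = 19), "order")
})

test_that("AR PSD has the closed-form shapes and variance identity", {
  white <- structure(list(order = 0L, coefficients = numeric(0),
                          reflection = numeric(0), innovation_variance = 2.5,
                          sampling_rate = 4), class = "ar_model")
  psd <- ar_psd(white)
  expect_true(all(abs(psd$density - 2 * 2.5 / 4) < 1e-12))
  expect_equal(band_power(psd, c(0.04, 0.4)), 0.36 * 2 * 2.5 / 4,
               tolerance = 1e-9)

  ar1 <- structure(list(order = 1L, coefficients = -0.9,
                        reflection = -0.9, innovation_variance = 1,
                        sampling_rate = 4), class = "ar_model")
  d <- ar_psd(ar1)$density
  expect_true(all(diff(d) < 0))   # low-pass: monotone decreasing

  # variance identity against a long simulated realization of the model
  set.seed(33)
  x <- as.numeric(stats::arima.sim(list(ar = c(0.5, -0.3)), 1e5))
  fit <- burg_fit(x, order = 2)
  psd2 <- ar_psd(fit, fs = 4)
  integral <- band_power(psd2, c(psd2$frequencies[1], 2))
  expect_lt(abs(integral - stats::var(x)) / stats::var(x), 0.05)
})

test_that("band powers integrate and tile correctly", {
  set.seed(34)
  rr <- simulate_rr_ipfm(ipfm_params(), 300)
  fd <- frequency_domain_indices(rr)
  b <- hrv_bands()
  expect_equal(fd$LF + fd$HF, fd$TP, tolerance = 1e-9)   # exact tiling
  expect_error(band_power(fd$psd, c(0.4, 0.15)), "increasing")

  # narrowband HF tone: most of TP lands in HF
  set.seed(35)
  hf_only <- simulate_rr_ipfm(ipfm_params(a_LF = 0, a_HF = 0.1,
                                          noise_sd = 0.005), 300)
  fd2 <- frequency_domain_indices(hf_only)
  expect_gte(fd2$HF / fd2$TP, 0.8)
})

test_that("normalized indices satisfy their identities on every segment", {
  set.seed(36)
  for (i in 1:5) {
    rr <- simulate_rr_ipfm(ipfm_params(a_LF = stats::runif(1, 0.02, 0.12),
                                       a_HF = stats::runif(1, 0.02, 0.12)),
                           240)
    fd <- frequency_domain_indices(rr)
    expect_equal(fd$nLF + fd$nHF, 100)
    expect_equal(fd$LF_HF, fd$LF / fd$HF)
    expect_true(fd$TP >= max(fd$LF, fd$HF))
  }
})

test_that("indices are scale-equivariant", {
  set.seed(37)
  rr <- simulate_rr_ipfm(ipfm_params(), 240)
  c_scale <- 1.17
  scaled <- rri_series(rr$beat_times, rr$intervals * c_scale, rr$flags)
  a <- hrv_indices(rr); b <- hrv_indices(scaled)
  expect_equal(b$mRRI, a$mRRI * c_scale)
  expect_equal(b$SDNN, a$SDNN * c_scale)
  expect_equal(b$TP, a$TP * c_scale^2, tolerance = 1e-6)
  expect_equal(b$LF, a$LF * c_scale^2, tolerance = 1e-6)
  expect_equal(b$HF, a$HF * c_scale^2, tolerance = 1e-6)
  expect_equal(b$nLF, a$nLF, tolerance = 1e-6)
  expect_equal(b$LF_HF, a$LF_HF, tolerance = 1e-6)
})

test_that("IPFM tuned to LF/HF = 2 is recovered by 3-min segments", {
  # oracle: periodogram band ratio on a 60-min realization
  set.seed(38)
  p <- ipfm_params(T0 = 0.85, a_LF = 0.08 * sqrt(2), a_HF = 0.08,
                   noise_sd = 0.01)
  oracle <- periodogram_lf_hf(simulate_rr_ipfm(p, 3600))
  est <- vapply(1:20, function(s) {
    set.seed(300 + s)
    rr <- simulate_rr_ipfm(p, 220)
    seg <- rr_window(rr, 10, 190)
    frequency_domain_indices(seg)$LF_HF
  }, numeric(1))
  expect_lt(abs(mean(est) - oracle) / oracle, 0.2)
  expect_gt(oracle, 1.4); expect_lt(oracle, 2.8)  # params do sit near 2
})
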