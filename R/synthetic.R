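#' IPFM generator parameters
#'
#' Parameters of the integral pulse frequency modulation (IPFM) model of the
#' sinoatrial node: beats are emitted whenever the running integral of the
#' modulated rate `(1 + m(t)) / T0` crosses an integer, with
#' `m(t) = a_LF sin(2 pi f_LF t + phase_LF) + a_HF sin(2 pi f_HF t + phase_HF)
#' + broadband noise`. The two oscillators emulate the sympathetic/baroreflex
#' (LF, 0.04-0.15 Hz) and vagal/respiratory (HF, 0.15-0.4 Hz) drives.
#'
#' @param T0 mean beat interval in seconds.
#' @param a_LF,a_HF dimensionless modulation amplitudes, each in `[0, 0.5)`.
#' @param f_LF,f_HF oscillator frequencies (Hz); defaults sit at the centres
#'   of the LF and HF analysis bands.
#' @param phase_LF,phase_HF phases in radians.
#' @param noise_sd SD of the broadband (band-limited white) modulation noise.
#' @param drift_sd SD of a slow very-low-frequency (VLF) drift modulation
#'   (Gaussian knots every `drift_knot` seconds, linearly interpolated;
#'   energy well below the 0.04 Hz analysis floor). Default 0: the drift
#'   models the VLF-dominant variance of real RR series and is switched on
#'   by the cohort simulator.
#' @param drift_knot knot spacing of the drift process, seconds.
#' @param seed optional integer; when given, the generator seeds the RNG.
#' @return An object of class `ipfm_params`.
#' @export
ipfm_params <- function(T0 = 0.9, a_LF = 0.06, a_HF = 0.06,
                        f_LF = 0.095, f_HF = 0.275,
                        phase_LF = 0, phase_HF = 0,
                        noise_sd = 0.02, drift_sd = 0, drift_knot = 30,
                        seed = NULL) {
  p <- list(T0 = T0, a_LF = a_LF, a_HF = a_HF, f_LF = f_LF, f_HF = f_HF,
            phase_LF = phase_LF, phase_HF = phase_HF,
            noise_sd = noise_sd, drift_sd = drift_sd,
            drift_knot = drift_knot, seed = seed)
  validate_ipfm_params(p)
  structure(p, class = "ipfm_params")
}

validate_ipfm_params <- function(p) {
  if (p$T0 <= 0) stop("T0 must be positive")
  if (p$a_LF < 0 || p$a_LF >= 0.5 || p$a_HF < 0 || p$a_HF >= 0.5)
    stop("modulation amplitudes must lie in [0, 0.5)")
  if (p$noise_sd < 0 || p$drift_sd < 0) stop("noise SDs must be non-negative")
  if (p$a_LF + p$a_HF + 3 * (p$noise_sd + p$drift_sd) >= 1)
    stop("a_LF + a_HF + 3*(noise_sd + drift_sd) must be < 1 (rate would hit zero)")
  if (p$f_LF < 0.04 || p$f_LF >= 0.15)
    stop("f_LF must lie in [0.04, 0.15)")
  if (p$f_HF < 0.15 || p$f_HF >= 0.4)
    stop("f_HF must lie in [0.15, 0.4)")
  invisible(p)
}

#' Piecewise effect timeline for the IPFM generator
#'
#' Describes stimulation-locked modifications of the generator parameters:
#' within `[start, end)` the base interval is shifted by `delta_T0_ms` and the
#' band amplitudes multiplied by `gain_LF` / `gain_HF`. Intervals may not
#' overlap; effects are applied to the generative parameters, not post hoc to
#' the emitted intervals.
#'
#' @param start,end interval bounds in seconds.
#' @param delta_T0_ms additive change of the base interval, ms.
#' @param gain_LF,gain_HF,gain_drift multiplicative modulation gains (> 0).
#' @return A data frame of class `effect_timeline`.
#' @export
effect_timeline <- function(start, end, delta_T0_ms = 0,
                            gain_LF = 1, gain_HF = 1, gain_drift = 1) {
  n <- length(start)
  tl <- data.frame(start = as.numeric(start), end = as.numeric(end),
                   delta_T0_ms = rep_len(delta_T0_ms, n),
                   gain_LF = rep_len(gain_LF, n),
                   gain_HF = rep_len(gain_HF, n),
                   gain_drift = rep_len(gain_drift, n))
  if (any(tl$end <= tl$start)) stop("effect intervals must have end > start")
  if (any(tl$gain_LF <= 0) || any(tl$gain_HF <= 0) || any(tl$gain_drift <= 0))
    stop("gains must be > 0")
  o <- order(tl$start)
  tl <- tl[o, , drop = FALSE]
  if (n > 1L && any(tl$start[-1] < tl$end[-n] - 1e-9))
    stop("effect intervals must not overlap")
  class(tl) <- c("effect_timeline", "data.frame")
  tl
}

# Band-limited Gaussian modulation noise: white noise on a knot grid,
# linearly interpolated onto the integration grid. With 1 s knots this is the
# broadband noise term; with ~30 s knots it is the VLF drift.
ipfm_noise <- function(tt, noise_sd, knot = 1) {
  if (noise_sd <= 0) return(numeric(length(tt)))
  knots <- seq(floor(min(tt)) - knot, ceiling(max(tt)) + knot, by = knot)
  stats::approx(knots, stats::rnorm(length(knots), 0, noise_sd),
                xout = tt, rule = 2)$y
}

#' Simulate an RR series with the IPFM model
#'
#' Integrates the modulated rate on a fine grid and emits a beat at every
#' integer crossing of the integral (crossing times located by linear
#' interpolation, accurate to well under 1 ms at the default grid).
#'
#' @param params an [ipfm_params()] object.
#' @param duration recording length in seconds (must exceed `10 * T0`).
#' @param effect_timeline optional [effect_timeline()] of stimulation-locked
#'   parameter changes.
#' @param dt integration step in seconds.
#' @return An [rri_series()].
#' @examples
#' rr <- simulate_rr_ipfm(ipfm_params(T0 = 1, a_LF = 0, a_HF = 0,
#'                                    noise_sd = 0), 60)
#' range(rr$intervals)  # exactly 1000 ms
#' @export
simulate_rr_ipfm <- function(params, duration, effect_timeline = NULL,
                             dt = 1 / 64) {
  validate_ipfm_params(params)
  if (duration <= 10 * params$T0)
    stop("duration must exceed 10 * T0")
  if (!is.null(params$seed)) set.seed(params$seed)
  tt <- seq(0, duration, by = dt)
  n <- length(tt)
  a_lf <- rep(params$a_LF, n)
  a_hf <- rep(params$a_HF, n)
  g_drift <- rep(1, n)
  T0t <- rep(params$T0, n)
  if (!is.null(effect_timeline)) {
    for (i in seq_len(nrow(effect_timeline))) {
      idx <- tt >= effect_timeline$start[i] & tt < effect_timeline$end[i]
      a_lf[idx] <- a_lf[idx] * effect_timeline$gain_LF[i]
      a_hf[idx] <- a_hf[idx] * effect_timeline$gain_HF[i]
      if (!is.null(effect_timeline$gain_drift))
        g_drift[idx] <- g_drift[idx] * effect_timeline$gain_drift[i]
      T0t[idx] <- T0t[idx] + effect_timeline$delta_T0_ms[i] / 1000
    }
  }
  m <- a_lf * sin(2 * pi * params$f_LF * tt + params$phase_LF) +
    a_hf * sin(2 * pi * params$f_HF * tt + params$phase_HF) +
    ipfm_noise(tt, params$noise_sd) +
    g_drift * ipfm_noise(tt, params$drift_sd, params$drift_knot)
  rate <- (1 + m) / T0t
  if (any(rate <= 0)) stop("instantaneous rate fell to zero; effects too large")
  # trapezoidal cumulative integral of the rate
  integral <- c(0, cumsum((rate[-1] + rate[-n]) / 2) * dt)
  n_beats <- floor(integral[n])
  if (n_beats < 2L) stop("fewer than two beats generated")
  ks <- seq_len(n_beats)
  hi <- pmin(findInterval(ks, integral), n - 1L)  # integral[hi] <= k < integral[hi+1]
  frac <- (ks - integral[hi]) / (integral[hi + 1L] - integral[hi])
  beat_times <- tt[hi] + frac * dt
  rri_series(beat_times)
}

#' Mexican-hat QRS template
#'
#' Second derivative of a Gaussian, a standard stand-in for the QRS complex
#' in detector benchmarks. `width` is the total support of the template.
#'
#' @param sampling_rate Hz.
#' @param width total template width, seconds (default 80 ms).
#' @param amplitude peak amplitude, mV.
#' @return numeric vector (odd length, centred peak).
#' @export
qrs_mexican_hat <- function(sampling_rate, width = 0.08, amplitude = 1) {
  half <- floor(width / 2 * sampling_rate)
  t <- (-half:half) / sampling_rate
  s <- width / 8
  w <- (1 - (t / s)^2) * exp(-t^2 / (2 * s^2))
  amplitude * w / max(w)
}

#' Synthesize an ECG record from an RR series
#'
#' Places one QRS template at each beat time and adds white measurement
#' noise. Morphology is deliberately minimal (no P/T waves): the record
#' exists to exercise R-peak detection, not to look clinical.
#'
#' @param rr an [rri_series()].
#' @param sampling_rate Hz, at least 100.
#' @param qrs_template waveform vector; default [qrs_mexican_hat()].
#' @param noise_sd measurement noise SD in mV (default keeps QRS amplitude at
#'   least 5x the noise floor).
#' @param pad seconds of flat signal kept before the first and after the last
#'   beat.
#' @return An [ecg_record()].
#' @export
synthesize_ecg <- function(rr, sampling_rate = 500, qrs_template = NULL,
                           noise_sd = 0.1, pad = 0.5) {
  if (sampling_rate < 100) stop("sampling_rate must be at least 100 Hz")
  if (is.null(qrs_template)) qrs_template <- qrs_mexican_hat(sampling_rate)
  if (length(rr$beat_times) == 0L)
    return(ecg_record(numeric(0), sampling_rate))
  if (length(rr$intervals) &&
      length(qrs_template) / sampling_rate > min(rr$intervals) / 1000)
    stop("QRS template longer than the shortest RR interval (overlapping beats)")
  t0 <- rr$beat_times[1] - pad
  n <- ceiling((max(rr$beat_times) + pad - t0) * sampling_rate) + 1L
  x <- numeric(n)
  half <- (length(qrs_template) - 1L) %/% 2L
  centres <- round((rr$beat_times - t0) * sampling_rate) + 1L
  for (c in centres) {
    lo <- c - half; hi <- c + half
    src <- seq_along(qrs_template)
    keep <- lo:hi >= 1L & lo:hi <= n
    x[(lo:hi)[keep]] <- x[(lo:hi)[keep]] + qrs_template[src[keep]]
  }
  if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
  ecg_record(x, sampling_rate, start_time = t0)
}

#' Stimulation effect model
#'
#' Magnitude of the autonomic response injected during stimulation, per
#' stimulation frequency. The defaults encode the qualitative pattern of
#' central-thalamic stimulation reported in the literature this package
#' emulates: shorter mean RR, larger LF, smaller HF while the stimulator is
#' on, with magnitudes increasing from 25 to 50 to 100 Hz, plus an extra
#' multiplicative band-amplitude gain for subjects whose consciousness later
#' improves. `carry_over` is the fraction of the effect persisting for
#' `carry_duration` seconds after stimulation offset, so post-stimulation
#' windows retain an attenuated effect.
#'
#' @param frequencies stimulation frequencies (Hz).
#' @param delta_mRRI additive change of mean RR during On, ms (one per
#'   frequency).
#' @param gain_LF,gain_HF multiplicative gains on the LF / HF modulation
#'   amplitudes during On.
#' @param gain_drift multiplicative gain on the VLF drift amplitude during
#'   On; its subject-to-subject heterogeneity (`drift_subject_sd`, lognormal
#'   SD per subject-day) makes the SDNN response variable across subjects —
#'   VLF reactivity is the least reproducible HRV component — while the
#'   band powers, which exclude the drift by detrending, respond cleanly.
#' @param outcome_effect extra gain applied to both band amplitudes in
#'   improved subjects.
#' @param carry_over fraction of the On effect persisting post-offset.
#' @param carry_duration seconds of carry-over.
#' @return An object of class `effect_model`.
#' @export
effect_model <- function(frequencies = c(25, 50, 100),
                         delta_mRRI = c(-20, -40, -60),
                         gain_LF = c(1.3, 1.6, 2.0),
                         gain_HF = c(0.85, 0.70, 0.55),
                         gain_drift = c(1.3, 1.6, 2.0),
                         drift_subject_sd = 0.5,
                         outcome_effect = 1.4,
                         carry_over = 0.5,
                         carry_duration = 300) {
  stopifnot(length(delta_mRRI) == length(frequencies),
            length(gain_LF) == length(frequencies),
            length(gain_HF) == length(frequencies),
            length(gain_drift) == length(frequencies))
  if (any(gain_LF <= 0) || any(gain_HF <= 0) || any(gain_drift <= 0) ||
      outcome_effect <= 0)
    stop("gains must be > 0")
  structure(list(frequencies = frequencies, delta_mRRI = delta_mRRI,
                 gain_LF = gain_LF, gain_HF = gain_HF,
                 gain_drift = gain_drift, drift_subject_sd = drift_subject_sd,
                 outcome_effect = outcome_effect,
                 carry_over = carry_over, carry_duration = carry_duration),
            class = "effect_model")
}

#' Cohort specification
#'
#' @param n_subjects number of subjects.
#' @param n_improved number of subjects labelled improved (CRS-R gain >= 3).
#' @param frequencies stimulation frequency of each session day, Hz.
#' @param n_blocks stimulation blocks per day.
#' @param on_duration,off_duration block on / off durations, seconds.
#' @param day_start seconds between recording start and the first block onset
#'   (leaves room for the pre-stimulation window).
#' @param ipfm_defaults an [ipfm_params()] giving cohort-mean generator
#'   parameters; per-subject parameters are jittered around these.
#' @param effect an [effect_model()].
#' @param ecg_sampling_rate Hz, used when ECG synthesis is requested.
#' @param seed integer RNG seed; the cohort is a pure function of the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 8, n_improved = 3,
                        frequencies = c(25, 50, 100),
                        n_blocks = 4,
                        on_duration = 1800, off_duration = 5400,
                        day_start = 600,
                        ipfm_defaults = ipfm_params(drift_sd = 0.06),
                        effect = effect_model(),
                        ecg_sampling_rate = 500,
                        seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be at least 1")
  if (n_improved > n_subjects) stop("n_improved must be <= n_subjects")
  if (!all(frequencies %in% effect$frequencies))
    stop("every session frequency needs a row in the effect model")
  structure(list(n_subjects = n_subjects, n_improved = n_improved,
                 frequencies = frequencies, n_blocks = n_blocks,
                 on_duration = on_duration, off_duration = off_duration,
                 day_start = day_start, ipfm_defaults = ipfm_defaults,
                 effect = effect, ecg_sampling_rate = ecg_sampling_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a stimulation cohort
#'
#' For each subject and session day, draws subject-level IPFM parameters,
#' builds the block schedule, injects the frequency-specific effect during
#' the On periods (with attenuated carry-over after offset) and generates the
#' RR recording. Improved subjects additionally receive the outcome gain on
#' both band amplitudes, and CRS-R follow-up scores are drawn so that exactly
#' `n_improved` subjects gain at least 3 points.
#'
#' @param spec a [cohort_spec()].
#' @param with_ecg if `TRUE`, also synthesize an ECG record per subject-day
#'   (slow and memory-hungry at full session length; off by default).
#' @return A list with elements `subjects` (per subject: `days`, each holding
#'   `rr`, `schedule`, `frequency`, and optionally `ecg`), `labels` (data
#'   frame with CRS-R scores and the improved flag) and `spec`.
#' @export
simulate_cohort <- function(spec, with_ecg = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  em <- spec$effect
  improved <- rep(FALSE, spec$n_subjects)
  improved[sample.int(spec$n_subjects, spec$n_improved)] <- TRUE

  subjects <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    p0 <- spec$ipfm_defaults
    subj <- ipfm_params(
      T0 = max(0.6, stats::rnorm(1, p0$T0, 0.05)),
      a_LF = p0$a_LF * exp(stats::rnorm(1, 0, 0.10)),
      a_HF = p0$a_HF * exp(stats::rnorm(1, 0, 0.10)),
      f_LF = p0$f_LF, f_HF = p0$f_HF,
      phase_LF = stats::runif(1, 0, 2 * pi),
      phase_HF = stats::runif(1, 0, 2 * pi),
      noise_sd = p0$noise_sd,
      drift_sd = p0$drift_sd, drift_knot = p0$drift_knot)
    out_gain <- if (improved[s]) em$outcome_effect else 1
    # drift (VLF) reactivity is a stable subject trait: lognormal across
    # subjects (truncated +/- 2 SD), shared by all days, capped so the
    # modulation can never drive the instantaneous rate to zero
    z <- max(-2, min(2, stats::rnorm(1))) * em$drift_subject_sd
    drift_react <- exp(z)
    days <- vector("list", length(spec$frequencies))
    for (d in seq_along(spec$frequencies)) {
      freq <- spec$frequencies[d]
      fi <- match(freq, em$frequencies)
      # vagal (HF) tone is the most labile HRV component day to day
      day_p <- subj
      day_p$a_HF <- subj$a_HF * exp(stats::rnorm(1, 0, 0.15))
      # block count/frequency were validated with the spec; suppress the
      # interactive-use warnings of build_schedule here
      sched <- suppressWarnings(
        build_schedule(day_start = spec$day_start, frequency = freq,
                       n_blocks = spec$n_blocks,
                       on_duration = spec$on_duration,
                       off_duration = spec$off_duration))
      g_drift <- min(em$gain_drift[fi] * drift_react, 2.8)
      tl <- rbind(
        effect_timeline(sched$on_start, sched$on_end,
                        delta_T0_ms = em$delta_mRRI[fi],
                        gain_LF = em$gain_LF[fi] * out_gain,
                        gain_HF = em$gain_HF[fi] * out_gain,
                        gain_drift = g_drift),
        # carry-over attenuates gains geometrically (g^c), which keeps the
        # LF/HF ratio of a symmetric outcome gain intact post-stimulation
        effect_timeline(sched$on_end,
                        sched$on_end + em$carry_duration,
                        delta_T0_ms = em$delta_mRRI[fi] * em$carry_over,
                        gain_LF = (em$gain_LF[fi] * out_gain)^em$carry_over,
                        gain_HF = (em$gain_HF[fi] * out_gain)^em$carry_over,
                        gain_drift = g_drift^em$carry_over))
      tl <- tl[order(tl$start), ]
      class(tl) <- c("effect_timeline", "data.frame")
      duration <- max(sched$on_end) + em$carry_duration + 60
      # dt = 1/32 keeps beat times accurate to ~0.05 ms; halves session cost
      rr <- simulate_rr_ipfm(day_p, duration, effect_timeline = tl, dt = 1 / 32)
      days[[d]] <- list(rr = rr, schedule = sched, frequency = freq)
      if (with_ecg)
        days[[d]]$ecg <- synthesize_ecg(rr, spec$ecg_sampling_rate)
    }
    subjects[[s]] <- list(id = sprintf("S%02d", s), params = subj,
                          improved = improved[s], days = days)
  }
  baseline <- sample(5:10, spec$n_subjects, replace = TRUE)
  gain <- ifelse(improved, sample(3:6, spec$n_subjects, replace = TRUE),
                 sample(0:2, spec$n_subjects, replace = TRUE))
  labels <- data.frame(
    subject = vapply(subjects, `[[`, "", "id"),
    crs_r_baseline = baseline,
    crs_r_followup = pmin(baseline + gain, 23L),
    improved = improved)
  # the cap at 23 can never undo a >=3 gain here (baseline <= 10)
  list(subjects = subjects, labels = labels, spec = spec)
}
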