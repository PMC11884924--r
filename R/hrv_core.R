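#' Spectral band definitions
#'
#' The standard short-segment HRV bands: LF 0.04-0.15 Hz (sympathetic +
#' baroreflex), HF 0.15-0.4 Hz (vagal/respiratory), and total power defined
#' as their union 0.04-0.4 Hz, so TP = LF + HF by construction and the
#' ultra/very-low-frequency range is excluded (it is removed by detrending
#' anyway).
#'
#' @param TP,LF,HF two-element numeric ranges in Hz.
#' @return A named list of bands.
#' @export
hrv_bands <- function(TP = c(0.04, 0.4), LF = c(0.04, 0.15), HF = c(0.15, 0.4)) {
  for (b in list(TP, LF, HF))
    if (length(b) != 2L || b[1] >= b[2]) stop("bands must be increasing ranges")
  if (abs(LF[2] - HF[1]) > 1e-12 || abs(TP[1] - LF[1]) > 1e-12 ||
      abs(TP[2] - HF[2]) > 1e-12)
    stop("LF and HF must be adjacent and partition TP")
  list(TP = TP, LF = LF, HF = HF)
}

# Cholesky factors of the detrending operator, keyed by (length, lambda)
.detrend_cache <- new.env(parent = emptyenv())

nn_intervals <- function(rr) {
  rr$intervals[rr$flags != "rejected"]
}

#' Time-domain HRV indices
#'
#' Computed on the NN (normal-to-normal, after ectopic handling) intervals,
#' before any resampling: mRRI is the arithmetic mean and SDNN the sample
#' standard deviation (n - 1 denominator), both in ms.
#'
#' @param rr an [rri_series()].
#' @return A list with `mRRI` and `SDNN` (ms).
#' @export
time_domain_indices <- function(rr) {
  nn <- nn_intervals(rr)
  if (length(nn) < 2L) stop("need at least 2 normal intervals")
  list(mRRI = mean(nn), SDNN = stats::sd(nn))
}

#' Resample an RR series to a uniform grid by cubic spline
#'
#' Fits a cubic spline through the (beat time, interval) points — each
#' interval stamped at the beat that closes it — and evaluates it on a
#' uniform grid at `fs` Hz over the segment. The grid is clipped to the span
#' of the beats: no extrapolation.
#'
#' @param rr an [rri_series()] with at least 4 beats spanning >= 30 s.
#' @param fs target sampling rate, Hz (default 4).
#' @param start,end segment bounds; default the beat span.
#' @return A list of class `uniform_series` with `values` (ms),
#'   `sampling_rate` and `start_time`.
#' @export
resample_cubic_spline <- function(rr, fs = 4, start = NULL, end = NULL) {
  if (length(rr$beat_times) < 4L) stop("need at least 4 beats to resample")
  tmid <- rr$beat_times[-1]
  if (is.null(start)) start <- tmid[1]
  if (is.null(end)) end <- tmid[length(tmid)]
  if (end - start < 30) stop("segment must span at least 30 s")
  grid <- seq(start, end, by = 1 / fs)
  grid <- grid[grid >= tmid[1] & grid <= tmid[length(tmid)]]
  vals <- stats::spline(tmid, rr$intervals, xout = grid, method = "fmm")$y
  structure(list(values = vals, sampling_rate = fs, start_time = grid[1]),
            class = "uniform_series")
}

#' Smoothness-priors detrending
#'
#' Removes the slow (ultra-low-frequency) trend from a uniformly sampled
#' series with the regularized operator `x - (I + lambda^2 D2' D2)^{-1} x`,
#' where `D2` is the second-difference matrix. The smoothing parameter
#' `lambda` sets the cutoff (lambda = 500 at 4 Hz puts it near 0.035 Hz,
#' safely below the 0.04 Hz analysis floor). `lambda = 0` returns the zero
#' series, since the smoother then reproduces the input exactly.
#'
#' @param x a `uniform_series` (or numeric vector) of length >= 3.
#' @param lambda non-negative smoothing parameter.
#' @return A detrended object of the same shape as the input.
#' @export
detrend_smoothness_priors <- function(x, lambda = 500) {
  if (lambda < 0) stop("lambda must be non-negative")
  v <- if (inherits(x, "uniform_series")) x$values else as.numeric(x)
  n <- length(v)
  if (n < 3L) stop("need at least 3 samples")
  key <- sprintf("n%d_l%.6g", n, lambda)
  ch <- .detrend_cache[[key]]
  if (is.null(ch)) {
    D2 <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                             diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                              rep(1, n - 2L)))
    A <- Matrix::Diagonal(n) + lambda^2 * Matrix::crossprod(D2)
    ch <- Matrix::Cholesky(methods::as(A, "symmetricMatrix"), LDL = FALSE)
    if (length(.detrend_cache) < 64L) .detrend_cache[[key]] <- ch
  }
  trend <- as.numeric(Matrix::solve(ch, v))
  out <- v - trend
  if (inherits(x, "uniform_series")) {
    x$values <- out
    x
  } else out
}

#' Burg autoregressive model fit
#'
#' Classic Burg lattice recursion: at each stage the reflection coefficient
#' minimizes the summed forward + backward prediction-error power. The
#' returned coefficients follow the prediction-error-filter convention
#' `A(z) = 1 + a_1 z^-1 + ... + a_p z^-p` (so an AR process
#' `x_t = phi_1 x_{t-1} + ... + e_t` has `a_k = -phi_k`); the innovation
#' variance is the final prediction-error power.
#'
#' @param x a detrended `uniform_series` or numeric vector (mean is removed).
#' @param order AR order, default 19; must satisfy `length(x) > 2 * order`.
#' @return A list of class `ar_model` with `order`, `coefficients`,
#'   `reflection`, `innovation_variance` and `sampling_rate`.
#' @export
burg_fit <- function(x, order = 19) {
  fs <- if (inherits(x, "uniform_series")) x$sampling_rate else NA_real_
  v <- if (inherits(x, "uniform_series")) x$values else as.numeric(x)
  n <- length(v)
  if (n <= 2L * order) stop("need length(x) > 2 * order")
  v <- v - mean(v)
  if (stats::sd(v) == 0) stop("degenerate (constant) input: variance is zero")
  ef <- eb <- v
  a <- numeric(0)
  k_refl <- numeric(order)
  E <- sum(v^2) / n
  for (m in seq_len(order)) {
    fseg <- ef[(m + 1L):n]
    bseg <- eb[m:(n - 1L)]
    denom <- sum(fseg^2) + sum(bseg^2)
    k <- if (denom > 0) -2 * sum(fseg * bseg) / denom else 0
    k_refl[m] <- k
    a <- c(a + k * rev(a), k)
    ef_new <- ef
    ef_new[(m + 1L):n] <- fseg + k * bseg
    eb_new <- eb
    eb_new[(m + 1L):n] <- bseg + k * fseg
    ef <- ef_new; eb <- eb_new
    E <- E * (1 - k^2)
  }
  structure(list(order = order, coefficients = a, reflection = k_refl,
                 innovation_variance = E, sampling_rate = fs),
            class = "ar_model")
}

#' One-sided AR power spectral density
#'
#' Evaluates `P(f) = 2 sigma^2 / (fs |1 + sum_k a_k e^{-i 2 pi k f / fs}|^2)`
#' on a uniform grid over `(0, fs/2]`. With this normalization the integral
#' of the density over the half-axis equals the process variance.
#'
#' @param model an `ar_model` from [burg_fit()].
#' @param fs sampling rate, Hz (defaults to the one recorded in the model).
#' @param n_freqs grid size (default 4096; fine enough that the trapezoidal
#'   band integrals capture even near-unit-circle AR peaks, keeping the
#'   variance identity within tolerance).
#' @return A list of class `psd_estimate` with `frequencies` and `density`
#'   (ms^2/Hz).
#' @export
ar_psd <- function(model, fs = model$sampling_rate, n_freqs = 4096) {
  if (is.na(fs)) stop("sampling rate unknown; pass fs")
  freqs <- seq_len(n_freqs) * (fs / 2) / n_freqs
  a <- model$coefficients
  denom <- if (length(a)) {
    k <- seq_along(a)
    A <- 1 + exp(-2i * pi * outer(freqs / fs, k)) %*% a
    Mod(A)^2
  } else rep(1, n_freqs)
  dens <- as.numeric(2 * model$innovation_variance / (fs * denom))
  structure(list(frequencies = freqs, density = dens), class = "psd_estimate")
}

#' Band power by trapezoidal integration
#'
#' Integrates the PSD over `[f_lo, f_hi]`, interpolating the density at the
#' exact band edges so adjacent bands tile exactly (LF + HF = TP on a shared
#' grid).
#'
#' @param psd a `psd_estimate`.
#' @param band two-element increasing range, Hz.
#' @return Power in ms^2.
#' @export
band_power <- function(psd, band) {
  if (length(band) != 2L || band[1] >= band[2]) stop("band must be increasing")
  f <- psd$frequencies; d <- psd$density
  if (band[1] < 0 || band[2] > max(f) + 1e-9)
    stop("band outside the PSD frequency range")
  inside <- f > band[1] & f < band[2]
  fe <- c(band[1], f[inside], band[2])
  de <- c(stats::approx(f, d, xout = band[1], rule = 2)$y,
          d[inside],
          stats::approx(f, d, xout = band[2], rule = 2)$y)
  sum(diff(fe) * (de[-1] + de[-length(de)]) / 2)
}

#' Frequency-domain HRV indices for one segment
#'
#' Runs the full spectral chain — cubic-spline resampling at `fs`,
#' smoothness-priors detrending, Burg AR fit, one-sided PSD, trapezoidal band
#' powers — and derives the normalized indices: `nLF = 100 LF / (LF + HF)`,
#' `nHF = 100 HF / (LF + HF)` (so nLF + nHF = 100 exactly) and the ratio
#' `LF_HF = LF / HF` (reported as `NA` when HF is zero, never infinity).
#'
#' @param rr an [rri_series()] covering a usable segment (nominally 3 min).
#' @param fs resampling rate, Hz.
#' @param lambda detrending parameter.
#' @param order AR order.
#' @param bands band definitions from [hrv_bands()].
#' @param n_freqs PSD grid size.
#' @return A list with `TP`, `LF`, `HF` (ms^2), `nLF`, `nHF` (percent),
#'   `LF_HF`, and the intermediate `psd`.
#' @export
frequency_domain_indices <- function(rr, fs = 4, lambda = 500, order = 19,
                                     bands = hrv_bands(), n_freqs = 4096) {
  u <- resample_cubic_spline(rr, fs = fs)
  dtr <- detrend_smoothness_priors(u, lambda = lambda)
  model <- burg_fit(dtr, order = order)
  psd <- ar_psd(model, fs = fs, n_freqs = n_freqs)
  LF <- band_power(psd, bands$LF)
  HF <- band_power(psd, bands$HF)
  TP <- band_power(psd, bands$TP)
  tot <- LF + HF
  nLF <- if (tot > 0) 100 * LF / tot else NA_real_
  list(TP = TP, LF = LF, HF = HF,
       nLF = nLF,
       nHF = 100 - nLF,   # complement by construction: nLF + nHF = 100
       LF_HF = if (HF > 0) LF / HF else NA_real_,
       psd = psd)
}

#' All eight HRV indices for one segment
#'
#' @inheritParams frequency_domain_indices
#' @return A one-row data frame with columns mRRI, SDNN, TP, LF, HF, nLF,
#'   nHF, LF_HF.
#' @export
hrv_indices <- function(rr, fs = 4, lambda = 500, order = 19,
                        bands = hrv_bands(), n_freqs = 4096) {
  td <- time_domain_indices(rr)
  fd <- frequency_domain_indices(rr, fs = fs, lambda = lambda, order = order,
                                 bands = bands, n_freqs = n_freqs)
  data.frame(mRRI = td$mRRI, SDNN = td$SDNN, TP = fd$TP, LF = fd$LF,
             HF = fd$HF, nLF = fd$nLF, nHF = fd$nHF, LF_HF = fd$LF_HF)
}
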