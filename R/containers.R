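#' ECG record
#'
#' A uniformly sampled single-lead ECG trace. Voltages are in millivolts,
#' times in seconds from an arbitrary wall-clock origin (`start_time` offsets
#' sample 1 relative to that origin, so schedules and recordings can share a
#' clock).
#'
#' @param samples numeric vector of voltages (mV).
#' @param sampling_rate sampling frequency in Hz (> 0).
#' @param start_time wall-clock offset of the first sample, seconds.
#' @param subject_id optional subject identifier.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, sampling_rate, start_time = 0, subject_id = NA_character_) {
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0)
    stop("sampling_rate must be a single positive number")
  if (anyNA(samples)) stop("ECG samples contain NA values")
  structure(
    list(samples = as.numeric(samples),
         sampling_rate = as.numeric(sampling_rate),
         start_time = as.numeric(start_time),
         subject_id = subject_id),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  dur <- length(x$samples) / x$sampling_rate
  cat(sprintf("<ecg_record> %s: %d samples @ %g Hz (%.1f s), start %.1f s\n",
              if (is.na(x$subject_id)) "?" else x$subject_id,
              length(x$samples), x$sampling_rate, dur, x$start_time))
  invisible(x)
}

#' Sample times of an ECG record
#' @param ecg an `ecg_record`.
#' @return numeric vector of sample times (seconds, same clock as `start_time`).
#' @export
ecg_times <- function(ecg) {
  ecg$start_time + (seq_along(ecg$samples) - 1L) / ecg$sampling_rate
}

#' R-peak series
#'
#' @param peak_times strictly increasing peak times in seconds.
#' @param refractory minimum admissible peak spacing (seconds), recorded for
#'   validation.
#' @return An object of class `r_peaks`.
#' @export
r_peaks <- function(peak_times, refractory = 0.25) {
  peak_times <- as.numeric(peak_times)
  if (is.unsorted(peak_times, strictly = TRUE))
    stop("peak_times must be strictly increasing")
  if (length(peak_times) >= 2L && min(diff(peak_times)) < refractory - 1e-9)
    stop("successive peaks closer than the refractory period")
  structure(list(peak_times = peak_times, refractory = refractory),
            class = "r_peaks")
}

#' RR-interval series
#'
#' Beat-to-beat intervals with their beat times. Interval `i` spans beats `i`
#' and `i + 1`, so there is one fewer interval than beats. Quality flags track
#' preprocessing: `"normal"`, `"corrected"` (replaced by interpolation) or
#' `"rejected"`.
#'
#' @param beat_times strictly increasing beat times, seconds.
#' @param intervals intervals in ms; defaults to `diff(beat_times) * 1000`.
#' @param flags per-interval quality flags.
#' @param usable logical; `FALSE` marks a segment downstream stages must skip.
#' @param n_corrected number of intervals replaced by interpolation.
#' @return An object of class `rri_series`.
#' @export
rri_series <- function(beat_times, intervals = NULL, flags = NULL,
                       usable = TRUE, n_corrected = 0L) {
  beat_times <- as.numeric(beat_times)
  if (is.unsorted(beat_times, strictly = TRUE))
    stop("beat_times must be strictly increasing")
  if (is.null(intervals)) intervals <- diff(beat_times) * 1000
  intervals <- as.numeric(intervals)
  if (length(intervals) != max(length(beat_times) - 1L, 0L))
    stop("need length(intervals) == length(beat_times) - 1")
  if (length(intervals) && any(intervals <= 0))
    stop("intervals must be positive")
  if (is.null(flags)) flags <- rep("normal", length(intervals))
  if (!all(flags %in% c("normal", "corrected", "rejected")))
    stop("flags must be normal, corrected or rejected")
  if (length(flags) != length(intervals))
    stop("need one flag per interval")
  structure(list(beat_times = beat_times, intervals = intervals,
                 flags = flags, usable = usable,
                 n_corrected = as.integer(n_corrected)),
            class = "rri_series")
}

#' @export
print.rri_series <- function(x, ...) {
  cat(sprintf("<rri_series> %d beats, %d intervals (%d corrected), %s\n",
              length(x$beat_times), length(x$intervals), x$n_corrected,
              if (isTRUE(x$usable)) "usable" else "UNUSABLE"))
  if (length(x$intervals))
    cat(sprintf("  span %.1f-%.1f s, mean RR %.1f ms\n",
                min(x$beat_times), max(x$beat_times), mean(x$intervals)))
  invisible(x)
}

#' @export
length.rri_series <- function(x) length(x$intervals)

#' Restrict an RR series to a time window
#'
#' Keeps the beats falling inside `[start, end]` and the intervals between
#' them. Flags are carried along.
#'
#' @param rr an `rri_series`.
#' @param start,end window bounds in seconds (recording clock).
#' @return An `rri_series` covering the window (possibly empty).
#' @export
rr_window <- function(rr, start, end) {
  keep <- rr$beat_times >= start & rr$beat_times <= end
  idx <- which(keep)
  if (length(idx) < 2L)
    return(rri_series(rr$beat_times[idx], numeric(0), character(0),
                      usable = FALSE))
  iidx <- idx[-length(idx)]   # interval i sits between beats i and i+1
  rri_series(rr$beat_times[idx], rr$intervals[iidx], rr$flags[iidx],
             usable = rr$usable,
             n_corrected = sum(rr$flags[iidx] == "corrected"))
}
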