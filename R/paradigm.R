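#' Build a stimulation block schedule
#'
#' Standard block design: `n_blocks` stimulation-on periods of
#' `on_duration` seconds separated by `off_duration` seconds of rest (so
#' blocks sit at a `on + off` pitch starting at `day_start`). With the
#' defaults — four blocks of 30 min on / 90 min off — a day starting at
#' 10:00 stimulates at 10:00-10:30, 12:00-12:30, 14:00-14:30 and
#' 16:00-16:30.
#'
#' @param day_start onset of the first block. Either seconds on the
#'   recording clock, or a `"HH:MM"` string (converted to seconds from
#'   midnight).
#' @param frequency stimulation frequency, Hz. Values outside the usual
#'   `{25, 50, 100}` are allowed with a warning.
#' @param n_blocks number of blocks (a value other than 4 warns).
#' @param on_duration,off_duration block durations, seconds.
#' @return A data frame of class `stim_schedule` with columns `block`,
#'   `on_start`, `on_end` and attributes `frequency`, `day_start`.
#' @export
build_schedule <- function(day_start = "10:00", frequency = 100,
                           n_blocks = 4, on_duration = 1800,
                           off_duration = 5400) {
  if (is.character(day_start)) {
    hm <- as.numeric(strsplit(day_start, ":")[[1]])
    day_start <- hm[1] * 3600 + hm[2] * 60
  }
  if (!frequency %in% c(25, 50, 100))
    warning("unusual stimulation frequency: ", frequency, " Hz")
  if (n_blocks != 4) warning("non-standard block count: ", n_blocks)
  pitch <- on_duration + off_duration
  on_start <- day_start + (seq_len(n_blocks) - 1) * pitch
  sched <- data.frame(block = seq_len(n_blocks), on_start = on_start,
                      on_end = on_start + on_duration)
  validate_schedule(sched)
  attr(sched, "frequency") <- frequency
  attr(sched, "day_start") <- day_start
  class(sched) <- c("stim_schedule", "data.frame")
  sched
}

#' Assemble a schedule from explicit block times
#'
#' @param on_start,on_end vectors of block on/off switch times, seconds.
#' @param frequency stimulation frequency, Hz.
#' @return A `stim_schedule`.
#' @export
manual_schedule <- function(on_start, on_end, frequency = 100) {
  sched <- data.frame(block = seq_along(on_start),
                      on_start = as.numeric(on_start),
                      on_end = as.numeric(on_end))
  validate_schedule(sched)
  attr(sched, "frequency") <- frequency
  attr(sched, "day_start") <- sched$on_start[1]
  class(sched) <- c("stim_schedule", "data.frame")
  sched
}

validate_schedule <- function(sched) {
  if (any(sched$on_end <= sched$on_start))
    stop("blocks must have on_end > on_start")
  o <- order(sched$on_start)
  if (any(o != seq_len(nrow(sched))))
    stop("blocks must be chronological")
  if (nrow(sched) > 1L &&
      any(sched$on_start[-1] < sched$on_end[-nrow(sched)]))
    stop("blocks overlap")
  invisible(sched)
}

#' Phase windows of a block
#'
#' Pre ends at stimulation onset, On covers the last `duration` seconds of
#' the on-period (steady-state response), Post starts at stimulation offset.
#'
#' @param on_start,on_end block switch times, seconds.
#' @param duration window length, seconds (default 180).
#' @return A data frame with columns `phase`, `start`, `end`.
#' @export
phase_windows <- function(on_start, on_end, duration = 180) {
  data.frame(phase = c("Pre", "On", "Post"),
             start = c(on_start - duration, on_end - duration, on_end),
             end = c(on_start, on_end, on_end + duration))
}

#' Extract Pre/On/Post RR segments for every block
#'
#' Cuts the three 3-minute windows around each stimulation block out of the
#' recording and quality-controls each. Windows falling outside the
#' recording are marked missing rather than raising an error.
#'
#' @param rr an [rri_series()] covering (most of) the session.
#' @param schedule a `stim_schedule`.
#' @param duration window length, seconds.
#' @return A list with one element per block, each a list of `Pre`, `On`,
#'   `Post` entries holding `rr` (the segment or `NULL`), `usable`, `start`,
#'   `end`.
#' @export
extract_phase_segments <- function(rr, schedule, duration = 180) {
  rec_lo <- min(rr$beat_times); rec_hi <- max(rr$beat_times)
  lapply(seq_len(nrow(schedule)), function(b) {
    w <- phase_windows(schedule$on_start[b], schedule$on_end[b], duration)
    out <- lapply(seq_len(3L), function(i) {
      if (w$start[i] < rec_lo - 1 || w$end[i] > rec_hi + 1)
        return(list(rr = NULL, usable = FALSE,
                    start = w$start[i], end = w$end[i]))
      seg <- rr_window(rr, w$start[i], w$end[i])
      q <- segment_quality(rr, w$start[i], w$end[i])
      list(rr = seg, usable = q$usable && length(seg$intervals) >= 30L,
           start = w$start[i], end = w$end[i])
    })
    names(out) <- w$phase
    out
  })
}

#' Tidy HRV index table for a cohort
#'
#' Applies the full HRV chain to every usable Pre/On/Post segment of every
#' block, subject and day of a simulated (or assembled) cohort. Unusable or
#' missing segments contribute no row: missingness propagates as absence,
#' never as zeros.
#'
#' @param cohort a cohort as returned by [simulate_cohort()].
#' @param duration phase-window length, seconds.
#' @param ... passed to [hrv_indices()].
#' @return A data frame with columns `subject`, `day`, `frequency`, `block`,
#'   `phase` and the eight index columns.
#' @export
phase_indices <- function(cohort, duration = 180, ...) {
  rows <- list()
  for (subj in cohort$subjects) {
    for (d in seq_along(subj$days)) {
      day <- subj$days[[d]]
      segs <- extract_phase_segments(day$rr, day$schedule, duration)
      for (b in seq_along(segs)) {
        for (ph in names(segs[[b]])) {
          seg <- segs[[b]][[ph]]
          if (!isTRUE(seg$usable)) next
          idx <- hrv_indices(seg$rr, ...)
          rows[[length(rows) + 1L]] <- cbind(
            data.frame(subject = subj$id, day = d,
                       frequency = day$frequency, block = b, phase = ph),
            idx)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(subject = character(), day = integer(),
                      frequency = numeric(), block = integer(),
                      phase = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

hrv_index_names <- function() c("mRRI", "SDNN", "TP", "LF", "HF", "nLF", "nHF", "LF_HF")

#' Per-subject Delta-index feature matrix
#'
#' For each subject (and optionally each stimulation frequency) computes the
#' change of every HRV index under stimulation, averaged over that day's
#' usable blocks. The default contrast is Post - Pre; On - Pre captures the
#' acute effect instead. With `aggregate = "mean_over_frequencies"` the
#' per-frequency deltas are averaged into 8 features per subject (the layout
#' used for attribution); `"per_frequency"` keeps 24.
#'
#' @param table a tidy table from [phase_indices()].
#' @param contrast `"post_minus_pre"` or `"on_minus_pre"`.
#' @param aggregate `"mean_over_frequencies"` or `"per_frequency"`.
#' @return A data frame, one row per subject, with a `subject` column and
#'   one column per feature. Subjects with no usable block pair are dropped
#'   with a warning.
#' @export
delta_features <- function(table,
                           contrast = c("post_minus_pre", "on_minus_pre"),
                           aggregate = c("mean_over_frequencies", "per_frequency")) {
  contrast <- match.arg(contrast)
  aggregate <- match.arg(aggregate)
  hi <- if (contrast == "post_minus_pre") "Post" else "On"
  idx_names <- hrv_index_names()
  key <- interaction(table$subject, table$day, table$block, drop = TRUE)
  deltas <- list()
  for (k in levels(key)) {
    blk <- table[key == k, , drop = FALSE]
    a <- blk[blk$phase == hi, idx_names, drop = FALSE]
    b <- blk[blk$phase == "Pre", idx_names, drop = FALSE]
    if (nrow(a) != 1L || nrow(b) != 1L) next   # missing phase: block excluded
    deltas[[length(deltas) + 1L]] <- cbind(
      blk[1, c("subject", "day", "frequency"), drop = FALSE],
      a - b)
  }
  if (!length(deltas)) stop("no block with both phases usable")
  dd <- do.call(rbind, deltas)
  agg_day <- stats::aggregate(dd[idx_names],
                              by = list(subject = dd$subject,
                                        frequency = dd$frequency),
                              FUN = mean)
  if (aggregate == "per_frequency") {
    wide <- stats::reshape(agg_day, direction = "wide",
                           idvar = "subject", timevar = "frequency")
    names(wide) <- sub("^(.*)\\.(\\d+)$", "\\1_\\2Hz", names(wide))
    out <- wide
  } else {
    out <- stats::aggregate(agg_day[idx_names],
                            by = list(subject = agg_day$subject), FUN = mean)
  }
  all_subj <- unique(table$subject)
  dropped <- setdiff(all_subj, out$subject)
  if (length(dropped))
    warning("subjects dropped (no usable block pair): ",
            paste(dropped, collapse = ", "))
  rownames(out) <- NULL
  out
}
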