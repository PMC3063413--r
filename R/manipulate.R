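## Appending, chunking and clock alignment of recordings.

channels_compatible <- function(a, b) {
  identical(a$channels$name, b$channels$name) &&
    identical(a$channels$kind, b$channels$kind) &&
    isTRUE(all.equal(a$sampling_rate, b$sampling_rate))
}

#' Append two recordings
#'
#' When both recordings carry a real-world start time the file order is
#' determined automatically from the clock and any gap between the end
#' of the earlier file and the start of the later one is filled with
#' zeros (rounded to the nearest sample; sub-sample disagreement gives a
#' zero-length gap). Without clocks the recordings are concatenated in
#' argument order. Events and scores of the later file are shifted by
#' the earlier file's length plus the gap. Overlapping clock ranges are
#' an error.
#'
#' @param rec_a,rec_b recordings with identical channel lists and rates
#' @return appended recording; start clock = the earlier start when known
#' @export
append_recordings <- function(rec_a, rec_b) {
  if (!channels_compatible(rec_a, rec_b))
    fk_stop("fk_compatibility_error",
            "recordings differ in channels or sampling rate")
  fs <- rec_a$sampling_rate
  gap <- 0
  if (!is.null(rec_a$start_clock_time) && !is.null(rec_b$start_clock_time)) {
    if (rec_b$start_clock_time < rec_a$start_clock_time) {
      tmp <- rec_a; rec_a <- rec_b; rec_b <- tmp
    }
    gap_s <- rec_b$start_clock_time - end_clock_time(rec_a)
    gap <- round(gap_s * fs)
    if (gap < 0)
      fk_stop("fk_overlap_error",
              "recordings overlap in clock time by %.3f s", -gap_s)
  }
  a <- read_window(rec_a)
  b <- read_window(rec_b)
  nch <- nrow(rec_a$channels)
  data <- cbind(a, matrix(0, nch, gap), b)
  shift <- rec_a$n_samples + gap
  ev_b <- rec_b$events
  if (nrow(ev_b)) ev_b$onset <- ev_b$onset + shift
  events <- rbind(rec_a$events, ev_b)

  out <- recording(data, fs, rec_a$channels, events = events,
                   start_clock_time = rec_a$start_clock_time,
                   history = c(rec_a$history, rec_b$history))
  # merge scores: the later file's windows land at an offset in windows
  for (ss in rec_a$scores) {
    ext <- scoreset(ss$scorer_id, ss$window_length_s, duration_s(out),
                    fpl_sample = ss$fpl_sample, opl_sample = ss$opl_sample,
                    sampling_rate = fs)
    ext$stages[seq_along(ss$stages)] <- ss$stages
    ext$artefact_flags[seq_along(ss$stages)] <- ss$artefact_flags
    out <- add_scoreset(out, ext)
  }
  for (ss in rec_b$scores) {
    woff <- round(shift / (ss$window_length_s * fs))
    ids <- vapply(out$scores, function(s) s$scorer_id, "")
    ext <- if (ss$scorer_id %in% ids) get_scoreset(out, ss$scorer_id)
           else scoreset(ss$scorer_id, ss$window_length_s, duration_s(out),
                         sampling_rate = fs)
    idx <- seq_along(ss$stages) + woff
    idx <- idx[idx <= length(ext$stages)]
    ext$stages[idx] <- ss$stages[seq_along(idx)]
    ext$artefact_flags[idx] <- ss$artefact_flags[seq_along(idx)]
    if (!is.null(ss$fpl_sample)) ext$fpl_sample <- ss$fpl_sample + shift
    if (!is.null(ss$opl_sample)) ext$opl_sample <- ss$opl_sample + shift
    out <- add_scoreset(out, ext)
  }
  add_history(out, sprintf("append (gap = %d samples)", gap))
}

#' Cut an episode out of a recording
#'
#' The interval may be given in samples, seconds from the beginning,
#' real-world clock time, or by a pair of marker labels. The half-open
#' sample interval `[t0, t1)` is extracted: events with onsets inside it
#' are kept and shifted, an event at exactly `t1` is excluded, the start
#' clock advances, and scoring windows whose start lies inside the
#' interval are re-indexed.
#'
#' @param rec recording
#' @param t0_s,t1_s interval in seconds from the recording start
#' @param clock0,clock1 interval as real-world POSIX seconds (requires a
#'   start clock)
#' @param marker_start,marker_end event labels bounding the interval
#'   (onset of first match each)
#' @return chunked recording
#' @export
chunk <- function(rec, t0_s = NULL, t1_s = NULL,
                  clock0 = NULL, clock1 = NULL,
                  marker_start = NULL, marker_end = NULL) {
  fs <- rec$sampling_rate
  if (!is.null(marker_start) || !is.null(marker_end)) {
    find <- function(lbl) {
      hit <- which(rec$events$label == lbl)
      if (!length(hit))
        fk_stop("fk_lookup_error", "marker label '%s' not found", lbl)
      rec$events$onset[hit[1]]
    }
    s0 <- find(marker_start)
    s1 <- find(marker_end)
  } else if (!is.null(clock0)) {
    if (is.null(rec$start_clock_time))
      fk_stop("fk_parameter_error", "recording has no start clock")
    s0 <- round((clock0 - rec$start_clock_time) * fs)
    s1 <- round((clock1 - rec$start_clock_time) * fs)
  } else {
    if (is.null(t0_s) || is.null(t1_s))
      fk_stop("fk_parameter_error", "no interval specification given")
    s0 <- round(t0_s * fs)
    s1 <- round(t1_s * fs)
  }
  if (s1 <= s0)
    fk_stop("fk_parameter_error", "empty interval: t1 <= t0")
  if (s0 < 0 || s1 > rec$n_samples)
    fk_stop("fk_bounds_error", "interval outside recording")

  data <- read_window(rec, rec$channels$name, s0, s1 - s0)
  ev <- rec$events[rec$events$onset >= s0 & rec$events$onset < s1, ,
                   drop = FALSE]
  if (nrow(ev)) {
    ev$onset <- ev$onset - s0
    ev$duration <- pmin(ev$duration, (s1 - s0) - ev$onset)
  }
  clock <- if (!is.null(rec$start_clock_time))
    rec$start_clock_time + s0 / fs else NULL
  out <- recording(data, fs, rec$channels, events = ev,
                   start_clock_time = clock, history = rec$history)
  for (ss in rec$scores) {
    wl_samp <- ss$window_length_s * fs
    w_start <- (seq_along(ss$stages) - 1) * wl_samp
    keep <- which(w_start >= s0 & w_start < s1)
    new <- scoreset(ss$scorer_id, ss$window_length_s, duration_s(out),
                    sampling_rate = fs)
    if (length(keep)) {
      dst <- seq_along(keep)
      dst <- dst[dst <= length(new$stages)]
      new$stages[dst] <- ss$stages[keep[seq_along(dst)]]
      new$artefact_flags[dst] <- ss$artefact_flags[keep[seq_along(dst)]]
    }
    if (!is.null(ss$fpl_sample) && ss$fpl_sample >= s0 && ss$fpl_sample < s1)
      new$fpl_sample <- ss$fpl_sample - s0
    if (!is.null(ss$opl_sample) && ss$opl_sample >= s0 && ss$opl_sample <= s1)
      new$opl_sample <- ss$opl_sample - s0
    out <- add_scoreset(out, new)
  }
  add_history(out, sprintf("chunk [%g, %g) samples", s0, s1))
}

#' Align recordings on a common real-world timeline
#'
#' Computes per-recording sample offsets so that identical clock
#' instants coincide on a shared time axis (offset 0 = earliest start).
#' When any recording lacks a start clock, all files are assumed to
#' begin at the same time and every offset is 0.
#'
#' @param recs list of recordings
#' @return integer vector of sample offsets, one per recording
#' @export
align_for_comparison <- function(recs) {
  if (length(recs) < 2)
    fk_stop("fk_parameter_error", "need at least two recordings")
  clocks <- lapply(recs, function(r) r$start_clock_time)
  if (any(vapply(clocks, is.null, TRUE)))
    return(rep(0L, length(recs)))
  t0 <- min(unlist(clocks))
  vapply(seq_along(recs), function(i)
    as.integer(round((clocks[[i]] - t0) * recs[[i]]$sampling_rate)),
    integer(1))
}
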