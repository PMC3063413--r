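#' Channel description table
#'
#' Builds the per-channel metadata table of a [recording()]. Channel kind
#' drives downstream defaults: EEG channels take part in mean-EEG
#' rereferencing and ROI averaging, ECG channels are used for heartbeat
#' detection, EOG/EMG channels may be displayed bipolar.
#'
#' @param name character vector of unique, nonempty channel labels
#' @param kind channel type, one of `"EEG"`, `"EOG"`, `"EMG"`, `"ECG"`,
#'   `"OTHER"` (recycled)
#' @param unit physical unit string (canonical unit is microvolt)
#' @param scale_group display-scaling group id
#' @param x,y optional 2-D scalp-plane coordinates
#' @return a data.frame with one row per channel
#' @export
channel_info <- function(name, kind = "EEG", unit = "uV",
                         scale_group = kind, x = NA_real_, y = NA_real_) {
  name <- as.character(name)
  if (length(name) == 0 || any(!nzchar(name)))
    fk_stop("fk_name_error", "channel names must be nonempty")
  if (anyDuplicated(name))
    fk_stop("fk_name_error", "duplicate channel name: %s",
            name[duplicated(name)][1])
  kind <- match.arg(toupper(kind), c("EEG", "EOG", "EMG", "ECG", "OTHER"),
                    several.ok = TRUE)
  data.frame(
    name = name,
    kind = rep_len(kind, length(name)),
    unit = rep_len(unit, length(name)),
    scale_group = rep_len(as.character(scale_group), length(name)),
    x = rep_len(as.numeric(x), length(name)),
    y = rep_len(as.numeric(y), length(name)),
    stringsAsFactors = FALSE
  )
}

#' Typed event markers
#'
#' Events carry a label (e.g. `fmri_volume_trigger`, `artefact`, `arousal`,
#' `FPL`, `OPL`, `event_of_interest`, `new_segment`), a 0-based sample
#' onset, a duration in samples, and an optional free-form payload.
#'
#' @param label character vector of event labels
#' @param onset 0-based sample onsets
#' @param duration durations in samples (>= 0)
#' @param payload optional character payloads
#' @return a data.frame with one row per event, ordered as given
#' @export
events_table <- function(label = character(), onset = integer(),
                         duration = 0L, payload = NA_character_) {
  n <- length(label)
  data.frame(
    label = as.character(label),
    onset = as.numeric(onset),
    duration = rep_len(as.numeric(duration), n),
    payload = rep_len(as.character(payload), n),
    stringsAsFactors = FALSE
  )
}

empty_events <- function() events_table()

validate_events <- function(events, n_samples) {
  if (nrow(events) == 0) return(invisible(events))
  if (any(events$onset < 0) || any(events$onset >= pmax(n_samples, 1)))
    fk_stop("fk_bounds_error", "event onset outside [0, n_samples)")
  if (any(events$duration < 0) ||
      any(events$onset + events$duration > n_samples))
    fk_stop("fk_bounds_error", "event extends past end of recording")
  invisible(events)
}

#' Continuous multichannel recording
#'
#' The central container: a continuous multichannel signal with header
#' metadata, a windowed data-access contract, events, sleep scores, an
#' optional real-world start time, and a provenance history. Sample data
#' live either in memory (a channels x samples matrix) or on disk in a
#' binary file that is read window by window — the whole signal is never
#' materialized for file-backed recordings.
#'
#' Sample indexing is 0-based; all intervals are half-open
#' `[start, start + length)`.
#'
#' @param data channels x samples numeric matrix (microvolts), or a source
#'   list describing a file-backed binary (internal use)
#' @param sampling_rate sampling rate in Hz (> 0)
#' @param channels channel table from [channel_info()]
#' @param events event table from [events_table()]
#' @param start_clock_time optional real-world start time: numeric POSIX
#'   seconds (microsecond resolution) or an ISO-8601 string
#' @param scores list of score sets ([scoreset()])
#' @param history character vector of provenance strings
#' @return an object of class `fk_recording`
#' @export
recording <- function(data, sampling_rate, channels,
                      events = empty_events(), start_clock_time = NULL,
                      scores = list(), history = character()) {
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    fk_stop("fk_parameter_error", "sampling_rate must be > 0")
  if (is.matrix(data)) {
    if (nrow(data) != nrow(channels))
      fk_stop("fk_parameter_error",
              "data has %d rows but %d channels declared",
              nrow(data), nrow(channels))
    source <- list(type = "memory", data = data)
    n_samples <- ncol(data)
  } else if (is.list(data) && identical(data$type, "file")) {
    source <- data
    n_samples <- data$n_samples
  } else {
    fk_stop("fk_parameter_error", "data must be a matrix or a file source")
  }
  if (is.character(start_clock_time))
    start_clock_time <- parse_clock_iso(start_clock_time)
  rec <- structure(
    list(
      sampling_rate = as.numeric(sampling_rate),
      channels = channels,
      n_samples = as.numeric(n_samples),
      start_clock_time = start_clock_time,
      events = events,
      scores = scores,
      history = history,
      source = source
    ),
    class = "fk_recording"
  )
  validate_events(events, rec$n_samples)
  rec
}

#' @export
print.fk_recording <- function(x, ...) {
  cat(sprintf("<fk_recording> %d channel(s) x %s samples @ %g Hz (%.1f s)\n",
              nrow(x$channels), format(x$n_samples, big.mark = ","),
              x$sampling_rate, x$n_samples / x$sampling_rate))
  cat(sprintf("  channels: %s\n",
              paste(utils::head(x$channels$name, 8), collapse = ", ")))
  if (!is.null(x$start_clock_time))
    cat(sprintf("  starts:   %s\n", format_clock_iso(x$start_clock_time)))
  cat(sprintf("  events: %d | scores: %d | source: %s\n",
              nrow(x$events), length(x$scores), x$source$type))
  if (length(x$history))
    cat("  history:", paste(x$history, collapse = " ; "), "\n")
  invisible(x)
}

#' @export
duration_s <- function(rec) UseMethod("duration_s")

#' @export
duration_s.fk_recording <- function(rec) rec$n_samples / rec$sampling_rate

#' Real-world end time of a recording
#' @param rec a recording
#' @return numeric POSIX seconds, or NULL when no start clock is set
#' @export
end_clock_time <- function(rec) {
  if (is.null(rec$start_clock_time)) return(NULL)
  rec$start_clock_time + rec$n_samples / rec$sampling_rate
}

channel_indices <- function(rec, channel_names) {
  idx <- match(channel_names, rec$channels$name)
  if (anyNA(idx))
    fk_stop("fk_name_error", "unknown channel(s): %s",
            paste(channel_names[is.na(idx)], collapse = ", "))
  idx
}

#' Read a window of sample data
#'
#' The fundamental data accessor. Returns exactly a
#' `length(channel_names) x length` block of microvolt values; for
#' file-backed recordings only the requested window (all stored channels x
#' `length` samples at most) is read from disk, so arbitrarily long
#' recordings can be processed piecewise. Pure: never mutates the
#' recording.
#'
#' @param rec a [recording()]
#' @param channel_names channels to read (default all, in stored order)
#' @param start 0-based first sample
#' @param length number of samples; `[start, start + length)` must lie
#'   inside the recording
#' @return numeric matrix, channels x samples, rownames = channel names
#' @export
read_window <- function(rec, channel_names = rec$channels$name,
                        start = 0, length = rec$n_samples - start) {
  if (start < 0 || length < 0 || start + length > rec$n_samples)
    fk_stop("fk_bounds_error",
            "window [%g, %g) outside recording of %g samples",
            start, start + length, rec$n_samples)
  idx <- channel_indices(rec, channel_names)
  out <- if (rec$source$type == "memory") {
    rec$source$data[idx, seq_len(length) + start, drop = FALSE]
  } else {
    read_file_window(rec$source, idx, start, length)
  }
  rownames(out) <- channel_names
  out
}

## Window read from a binary file source. Multiplexed layout reads one
## contiguous span of frames; vectorized layout seeks once per channel.
read_file_window <- function(src, idx, start, length) {
  nch <- src$n_channels
  bps <- if (src$dtype == "int16") 2L else 4L
  what <- if (src$dtype == "int16") integer() else numeric()
  size <- if (src$dtype == "int16") 2L else 4L
  con <- file(src$path, "rb")
  on.exit(close(con))
  if (length == 0) {
    out <- matrix(numeric(0), nrow = length(idx), ncol = 0)
    return(out)
  }
  if (identical(src$orientation, "VECTORIZED")) {
    out <- matrix(0, nrow = length(idx), ncol = length)
    for (k in seq_along(idx)) {
      ch <- idx[k]
      seek(con, ((ch - 1) * src$n_samples + start) * bps)
      v <- readBin(con, what, n = length, size = size, endian = "little",
                   signed = TRUE)
      if (base::length(v) < length)
        fk_stop("fk_integrity_error", "binary file shorter than header claims")
      out[k, ] <- as.numeric(v)
    }
  } else {
    seek(con, start * nch * bps)
    v <- readBin(con, what, n = length * nch, size = size, endian = "little",
                 signed = TRUE)
    if (base::length(v) < length * nch)
      fk_stop("fk_integrity_error", "binary file shorter than header claims")
    out <- matrix(as.numeric(v), nrow = nch, ncol = length)[idx, , drop = FALSE]
  }
  if (!is.null(src$resolution))
    out <- out * src$resolution[idx]
  out
}

#' Replace the sample data of a recording (in memory)
#'
#' Returns a new recording whose samples are `data`; header metadata,
#' events and scores are carried over. Used by correction methods, which
#' never modify their input.
#' @param rec template recording
#' @param data channels x samples matrix
#' @param note optional history entry to append
#' @return new recording
#' @export
with_data <- function(rec, data, note = NULL) {
  out <- recording(data, rec$sampling_rate, rec$channels,
                   events = rec$events, start_clock_time = rec$start_clock_time,
                   scores = rec$scores, history = rec$history)
  if (!is.null(note)) out <- add_history(out, note)
  out
}

#' @export
add_history <- function(rec, note) {
  rec$history <- c(rec$history, sprintf("[%s] %s",
                                        format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                                        note))
  rec
}

#' Append events to a recording
#' @param rec recording
#' @param events event table
#' @return recording with events appended (validated)
#' @export
add_events <- function(rec, events) {
  rec$events <- rbind(rec$events, events)
  validate_events(rec$events, rec$n_samples)
  rec
}
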