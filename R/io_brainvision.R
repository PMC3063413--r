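## BrainVision (.vhdr / .vmrk / .eeg) import by header translation only:
## the original binary is linked in place, never copied. INT16 samples are
## scaled to microvolts on read via the per-channel resolution.

parse_bv_ini <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub(";.*$", "", lines)
  section <- NULL
  out <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- character()
    } else if (grepl("=", ln) && !is.null(section)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- sub("^[^=]*=", "", ln)
      out[[section]][[key]] <- val
    }
  }
  out
}

guess_kind <- function(name) {
  up <- toupper(name)
  ifelse(grepl("ECG|EKG", up), "ECG",
  ifelse(grepl("EOG", up), "EOG",
  ifelse(grepl("EMG", up), "EMG", "EEG")))
}

#' Import a BrainVision recording by header translation
#'
#' Reads the `.vhdr` and `.vmrk` text headers and links the original
#' `.eeg` binary in place — the sample payload is never read, converted
#' or copied, so importing a multi-gigabyte EEG-fMRI file takes a
#' fraction of a second and no extra disk space. INT16 data are scaled
#' to microvolts on access using each channel's resolution. All markers
#' become events (1-based BrainVision positions converted to 0-based
#' onsets); a New Segment marker timestamp, when present and parseable,
#' sets the real-world start time.
#'
#' @param vhdr_path path to the `.vhdr` header
#' @return a file-backed [recording()]
#' @export
import_brainvision <- function(vhdr_path) {
  if (!file.exists(vhdr_path))
    fk_stop("fk_parameter_error", "no such file: %s", vhdr_path)
  ini <- parse_bv_ini(vhdr_path)
  ci <- ini[["Common Infos"]]
  bi <- ini[["Binary Infos"]]
  chi <- ini[["Channel Infos"]]
  if (is.null(ci) || is.null(chi))
    fk_stop("fk_parameter_error", "malformed .vhdr: missing sections")
  dir <- dirname(vhdr_path)

  n_channels <- as.integer(ci[["NumberOfChannels"]])
  samp_int_us <- as.numeric(ci[["SamplingInterval"]])
  if (is.na(samp_int_us) || samp_int_us <= 0)
    fk_stop("fk_parameter_error", "invalid SamplingInterval")
  fs <- 1e6 / samp_int_us
  orientation <- toupper(ci[["DataOrientation"]] %||% "MULTIPLEXED")
  fmt <- toupper(bi[["BinaryFormat"]] %||% "INT_16")
  dtype <- if (grepl("FLOAT", fmt)) "float32" else "int16"
  if (dtype == "int16" && orientation == "VECTORIZED")
    fk_warn("VECTORIZED INT16 layout: window reads use the slower per-channel path")

  # Ch<N>=<name>,<ref>,<resolution>,<unit>
  nm <- res <- unit <- character(n_channels)
  for (k in seq_len(n_channels)) {
    entry <- chi[[paste0("Ch", k)]]
    if (is.null(entry))
      fk_stop("fk_parameter_error", "missing Ch%d in .vhdr", k)
    parts <- strsplit(entry, ",")[[1]]
    nm[k] <- trimws(parts[1])
    res[k] <- if (length(parts) >= 3 && nzchar(trimws(parts[3])))
      trimws(parts[3]) else "1"
    unit[k] <- if (length(parts) >= 4) trimws(parts[4]) else ""
  }
  resolution <- as.numeric(res)
  resolution[is.na(resolution) | resolution <= 0] <- 1
  # normalize recognized units to uV; unknown units default to uV, logged
  for (k in seq_len(n_channels)) {
    # strip any non-ASCII micro-sign byte sequence (file encodings vary)
    u <- gsub("[^A-Za-z]", "", unit[k])
    if (u %in% c("", "V", "uV")) {
      if (identical(u, "V") && !grepl("[^A-Za-z]", unit[k]))
        resolution[k] <- resolution[k] * 1e6       # plain volts
      next
    }
    if (toupper(u) == "MV") resolution[k] <- resolution[k] * 1000
    else fk_warn("channel %s: unknown unit '%s', assuming uV", nm[k], unit[k])
  }
  if (dtype == "float32") resolution_eff <- resolution  # floats also carry resolution
  else resolution_eff <- resolution

  eeg_path <- file.path(dir, ci[["DataFile"]])
  if (!file.exists(eeg_path))
    fk_stop("fk_parameter_error", "data file not found: %s", eeg_path)
  bps <- if (dtype == "int16") 2 else 4
  n_samples <- floor(file.size(eeg_path) / (bps * n_channels))

  events <- empty_events()
  start_clock <- NULL
  mrk_file <- ci[["MarkerFile"]]
  if (!is.null(mrk_file) && nzchar(mrk_file)) {
    mrk_path <- file.path(dir, mrk_file)
    if (!file.exists(mrk_path)) {
      fk_warn("marker file %s missing; importing without events", mrk_file)
    } else {
      mk <- parse_bv_ini(mrk_path)[["Marker Infos"]]
      for (key in names(mk)) {
        if (!grepl("^Mk[0-9]+$", key)) next
        parts <- strsplit(mk[[key]], ",")[[1]]
        type <- trimws(parts[1])
        descr <- if (length(parts) >= 2) trimws(parts[2]) else ""
        pos <- as.numeric(parts[3])          # 1-based -> 0-based
        pts <- if (length(parts) >= 4) as.numeric(parts[4]) else 0
        label <- if (nzchar(descr)) descr else type
        events <- rbind(events, events_table(label, pos - 1, max(pts, 0), type))
        if (toupper(type) == "NEW SEGMENT" && length(parts) >= 6) {
          ts <- parse_bv_timestamp(parts[6])
          if (is.null(ts)) fk_warn("malformed New Segment timestamp '%s'",
                                   parts[6])
          else if (is.null(start_clock))
            start_clock <- ts - (pos - 1) / fs   # clock refers to the marker sample
        }
      }
    }
  }

  channels <- channel_info(nm, guess_kind(nm))
  src <- list(type = "file", path = eeg_path, dtype = dtype,
              orientation = orientation, n_channels = n_channels,
              n_samples = n_samples, resolution = resolution_eff)
  rec <- recording(src, fs, channels, events = events,
                   start_clock_time = start_clock)
  add_history(rec, sprintf("import_brainvision %s", basename(vhdr_path)))
}
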