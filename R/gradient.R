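## Gradient-artefact rejection: averaged artefact subtraction (AAS).
##
## The MR gradient artefact is locked to the repetition time (TR) and
## orders of magnitude larger than EEG. For every fMRI volume epoch the
## artefact template is the mean of the epochs in a moving window of
## n_average_volumes contiguous volumes; subtracting it cancels the
## (stationary) artefact while attenuating the underlying EEG by only
## 1/n_average_volumes. The corrected signal is then anti-alias filtered
## and downsampled.

#' Gradient-artefact correction settings
#'
#' @param tr_s fMRI repetition time, seconds
#' @param n_average_volumes volumes averaged into each template (default
#'   30)
#' @param trigger_label event label of the scanner volume/slice triggers;
#'   NULL enables TR-based epoching over a detected or given episode
#' @param auto_detect detect the scanning episode automatically when no
#'   triggers are available
#' @param detect_window_s episode-detector tile length, seconds (default
#'   1)
#' @param detect_channel channel used by the detector (default: first
#'   channel)
#' @param detect_threshold_uv mean-absolute-amplitude threshold in
#'   microvolts (default 350); a tile is artefacted when its mean
#'   absolute amplitude strictly exceeds this
#' @param target_rate_hz output sampling rate after correction (default
#'   500)
#' @return list of class `fk_ga_config`
#' @export
ga_config <- function(tr_s, n_average_volumes = 30, trigger_label = NULL,
                      auto_detect = is.null(trigger_label),
                      detect_window_s = 1, detect_channel = NULL,
                      detect_threshold_uv = 350, target_rate_hz = 500) {
  if (!is.null(tr_s) && tr_s <= 0)
    fk_stop("fk_parameter_error", "tr_s must be > 0")
  if (n_average_volumes < 1)
    fk_stop("fk_parameter_error", "n_average_volumes must be >= 1")
  structure(list(tr_s = tr_s, n_average_volumes = as.integer(n_average_volumes),
                 trigger_label = trigger_label, auto_detect = auto_detect,
                 detect_window_s = detect_window_s,
                 detect_channel = detect_channel,
                 detect_threshold_uv = detect_threshold_uv,
                 target_rate_hz = target_rate_hz),
            class = "fk_ga_config")
}

#' Automatic scanning-episode detection
#'
#' Tiles the detection channel into non-overlapping windows (1 s by
#' default) and flags every tile whose mean absolute amplitude strictly
#' exceeds the threshold (350 uV by default, first channel). Contiguous
#' flagged tiles are merged; episode boundaries are snapped outward to
#' whole tiles.
#'
#' @param rec recording
#' @param cfg [ga_config()]
#' @return list of c(start_sample, end_sample) half-open episodes (may be
#'   empty)
#' @export
detect_scan_episode <- function(rec, cfg) {
  ch <- cfg$detect_channel %||% rec$channels$name[1]
  fs <- rec$sampling_rate
  wlen <- round(cfg$detect_window_s * fs)
  n_tiles <- floor(rec$n_samples / wlen)
  if (n_tiles == 0) return(list())
  hot <- logical(n_tiles)
  for (i in seq_len(n_tiles)) {
    x <- read_window(rec, ch, (i - 1) * wlen, wlen)[1, ]
    hot[i] <- mean(abs(x)) > cfg$detect_threshold_uv
  }
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  eps <- which(r$values)
  lapply(eps, function(k)
    c((starts[k] - 1) * wlen, ends[k] * wlen))
}

#' Volume epoch onsets
#'
#' Trigger mode (the safest option): onsets are the scanner trigger
#' events' sample onsets; irregular spacing beyond one sample of jitter
#' raises a warning, since it indicates the EEG and MR clocks were not
#' synchronized and AAS will likely be inaccurate. TR mode: onsets are
#' laid out every `round(tr_s * fs)` samples from the episode start.
#'
#' @param rec recording
#' @param cfg [ga_config()]
#' @param episode optional c(start, end) sample interval (TR mode); when
#'   missing and `auto_detect` is set, the first detected episode is used
#' @return increasing integer vector of 0-based onset samples
#' @export
epoch_onsets <- function(rec, cfg, episode = NULL) {
  fs <- rec$sampling_rate
  if (!is.null(cfg$trigger_label)) {
    on <- rec$events$onset[rec$events$label == cfg$trigger_label]
    if (length(on) == 0)
      fk_stop("fk_parameter_error", "no events labelled '%s'",
              cfg$trigger_label)
    on <- sort(on)
    if (length(on) > 2) {
      d <- diff(on)
      if (max(d) - min(d) > 1)
        fk_warn("trigger spacing jitter of %d samples: EEG/MR clocks were probably not synchronized",
                max(d) - min(d))
    }
    return(on)
  }
  if (is.null(episode)) {
    eps <- if (cfg$auto_detect) detect_scan_episode(rec, cfg) else list()
    if (length(eps) == 0)
      fk_stop("fk_parameter_error",
              "no triggers and no scanning episode found")
    episode <- eps[[1]]
  }
  tr_samp <- round(cfg$tr_s * fs)
  n_vol <- floor((episode[2] - episode[1]) / tr_samp)
  if (n_vol < 1)
    fk_stop("fk_parameter_error", "episode shorter than one TR")
  episode[1] + (seq_len(n_vol) - 1) * tr_samp
}

## Moving-average template window: exactly min(n_avg, n_epochs) epochs,
## nearest-centered on epoch i and clamped (shifted, not shrunk) at the
## episode edges.
template_window <- function(i, n_epochs, n_avg) {
  k <- min(n_avg, n_epochs)
  before <- floor((k - 1) / 2)
  start <- i - before
  start <- max(1L, min(start, n_epochs - k + 1L))
  seq(start, start + k - 1L)
}

#' Averaged artefact subtraction with downsampling
#'
#' Removes the gradient artefact and downsamples the corrected
#' recording. For each channel and each volume epoch the template is
#' the mean of the epochs in a moving window of `n_average_volumes`
#' volumes (the current epoch included); the template is subtracted
#' from the epoch. Samples outside the scanning episode are untouched.
#' The whole signal is then low-pass filtered at `0.4 * target_rate_hz`
#' and decimated; events are re-indexed to the new rate.
#'
#' @param rec recording
#' @param cfg [ga_config()]
#' @param episode optional c(start, end) sample interval for TR mode
#' @return corrected, downsampled recording
#' @export
aas_correct <- function(rec, cfg, episode = NULL) {
  fs <- rec$sampling_rate
  onsets <- epoch_onsets(rec, cfg, episode)
  n_ep <- length(onsets)
  # epoch length: modal inter-onset interval (last epoch may be shorter)
  ep_len <- if (n_ep > 1) {
    d <- diff(onsets)
    as.integer(names(sort(table(d), decreasing = TRUE))[1])
  } else {
    round(cfg$tr_s * fs)
  }
  data <- read_window(rec)
  nch <- nrow(data)
  for (ch in seq_len(nch)) {
    x <- data[ch, ]
    # epoch matrix on the common grid; short tail epochs padded with NA
    ep <- matrix(NA_real_, n_ep, ep_len)
    for (i in seq_len(n_ep)) {
      s <- onsets[i] + 1
      len <- min(ep_len, length(x) - s + 1)
      if (len > 0) ep[i, seq_len(len)] <- x[s:(s + len - 1)]
    }
    for (i in seq_len(n_ep)) {
      win <- template_window(i, n_ep, cfg$n_average_volumes)
      tmpl <- colMeans(ep[win, , drop = FALSE], na.rm = TRUE)
      s <- onsets[i] + 1
      len <- min(ep_len, length(x) - s + 1)
      if (len > 0) {
        tl <- tmpl[seq_len(len)]
        tl[is.na(tl)] <- 0
        x[s:(s + len - 1)] <- x[s:(s + len - 1)] - tl
      }
    }
    data[ch, ] <- x
  }
  dec <- decimate(data, fs, cfg$target_rate_hz)
  ev <- rec$events
  if (nrow(ev)) {
    ev$onset <- round(ev$onset * cfg$target_rate_hz / fs)
    ev$duration <- round(ev$duration * cfg$target_rate_hz / fs)
    ev <- ev[ev$onset < ncol(dec$data), , drop = FALSE]
  }
  out <- recording(dec$data, dec$rate, rec$channels, events = ev,
                   start_clock_time = rec$start_clock_time,
                   scores = rec$scores, history = rec$history)
  add_history(out, sprintf(
    "aas_correct (n_avg = %d, %d epochs, fs %g -> %g Hz)",
    cfg$n_average_volumes, n_ep, fs, dec$rate))
}
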