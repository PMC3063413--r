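## Whole-recording Welch spectrograms with score-aware exclusion and
## absolute / relative / deep-sleep-normalized ("Mongrain") band power.

#' Whole-recording spectrogram
#'
#' The recording is bandpass filtered, cut into outer windows (defaults:
#' the scoring window length when scores are given, else 30 s), and each
#' outer window's PSD is estimated by Welch averaging of overlapping
#' Hamming-tapered subwindows. When a score set is supplied, outer
#' windows overlapping movement-time (stage 6) windows, artefact-flagged
#' windows, or artefact/arousal events are excluded: their power is set
#' to zero and recorded in a mask, and all downstream statistics use the
#' mask.
#'
#' @param rec recording
#' @param channels channels to include (default: all EEG)
#' @param band_hz bandpass applied before estimation (default c(0.5,
#'   Nyquist))
#' @param window_s outer window length, seconds
#' @param subwindow_s Welch subwindow, seconds (default 4)
#' @param overlap_frac Welch overlap (default 0.5)
#' @param scores optional [scoreset()] for exclusion
#' @return object of class `fk_spectrogram`: `power` is channels x
#'   windows x frequencies in uV^2/Hz, `excluded` a per-window logical
#'   mask with a `reason` attribute
#' @export
spectrogram <- function(rec, channels = NULL, band_hz = NULL,
                        window_s = NULL, subwindow_s = 4,
                        overlap_frac = 0.5, scores = NULL) {
  if (is.null(channels))
    channels <- rec$channels$name[rec$channels$kind == "EEG"]
  fs <- rec$sampling_rate
  if (is.null(window_s))
    window_s <- if (!is.null(scores)) scores$window_length_s else 30
  if (window_s < subwindow_s)
    fk_stop("fk_parameter_error", "window_s must be >= subwindow_s")
  wlen <- round(window_s * fs)
  n_win <- floor(rec$n_samples / wlen)
  if (n_win < 1)
    fk_stop("fk_parameter_error", "recording shorter than one window")
  nper <- round(subwindow_s * fs)
  nfreq <- floor(nper / 2) + 1
  freqs <- seq(0, nfreq - 1) * fs / nper
  power <- array(0, dim = c(length(channels), n_win, nfreq))
  excluded <- rep(FALSE, n_win)
  reason <- rep(NA_character_, n_win)

  if (!is.null(scores)) {
    swl <- round(scores$window_length_s * fs)
    bad_start <- (which(scores$stages == 6L | scores$artefact_flags) - 1) * swl
    art_ev <- rec$events[rec$events$label %in% c("artefact", "arousal"), ,
                         drop = FALSE]
    for (w in seq_len(n_win)) {
      w0 <- (w - 1) * wlen; w1 <- w0 + wlen
      if (length(bad_start) &&
          any(bad_start < w1 & (bad_start + swl) > w0)) {
        excluded[w] <- TRUE; reason[w] <- "movement"
      } else if (nrow(art_ev) &&
                 any(art_ev$onset < w1 &
                     (art_ev$onset + pmax(art_ev$duration, 1)) > w0)) {
        excluded[w] <- TRUE; reason[w] <- "artefact"
      }
    }
  }
  if (length(channels)) {
    for (ci in seq_along(channels)) {
      x <- read_window(rec, channels[ci], 0, n_win * wlen)[1, ]
      if (!is.null(band_hz)) x <- bandpass(x, fs, band_hz[1], band_hz[2])
      for (w in seq_len(n_win)) {
        if (excluded[w]) next                       # power stays zero
        seg <- x[((w - 1) * wlen + 1):(w * wlen)]
        power[ci, w, ] <- welch_psd(seg, fs, subwindow_s, overlap_frac)$psd
      }
    }
  }
  structure(list(channel_names = channels,
                 window_centers_s = (seq_len(n_win) - 0.5) * window_s,
                 frequencies_hz = freqs, power = power,
                 window_length_s = window_s, subwindow_s = subwindow_s,
                 overlap_frac = overlap_frac,
                 excluded = excluded, exclusion_reason = reason),
            class = "fk_spectrogram")
}

#' @export
print.fk_spectrogram <- function(x, ...) {
  cat(sprintf("<fk_spectrogram> %d channel(s) x %d window(s) x %d freqs (0-%g Hz), %d excluded\n",
              dim(x$power)[1], dim(x$power)[2], dim(x$power)[3],
              max(x$frequencies_hz), sum(x$excluded)))
  invisible(x)
}

spec_channel_index <- function(spec, channel) {
  i <- match(channel, spec$channel_names)
  if (is.na(i))
    fk_stop("fk_name_error", "channel '%s' not in spectrogram", channel)
  i
}

#' Band power per spectrogram window
#'
#' Three scalings: `absolute` integrates the PSD over the band;
#' `relative` divides by the full-spectrum integral of the same window;
#' `mongrain` divides the band power by its mean over windows scored as
#' deep sleep (stages 3-4) across the night. Excluded windows yield NA,
#' never 0/0.
#'
#' @param spec [spectrogram()] result
#' @param band_hz c(low, high) band in Hz
#' @param mode `"absolute"`, `"relative"` or `"mongrain"`
#' @param channel channel name (default first)
#' @param hypnogram_scores score set (required for mongrain)
#' @param deep_stages stage codes counting as deep sleep (default 3, 4)
#' @return numeric vector, one value per window (NA where excluded)
#' @export
band_power <- function(spec, band_hz,
                       mode = c("absolute", "relative", "mongrain"),
                       channel = spec$channel_names[1],
                       hypnogram_scores = NULL, deep_stages = c(3, 4)) {
  mode <- match.arg(mode)
  ci <- spec_channel_index(spec, channel)
  df <- spec$frequencies_hz[2] - spec$frequencies_hz[1]
  sel <- spec$frequencies_hz >= band_hz[1] & spec$frequencies_hz <= band_hz[2]
  if (!any(sel))
    fk_stop("fk_parameter_error", "band outside computed frequencies")
  p <- spec$power[ci, , , drop = TRUE]
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  absolute <- rowSums(p[, sel, drop = FALSE]) * df
  absolute[spec$excluded] <- NA_real_
  if (mode == "absolute") return(absolute)
  if (mode == "relative") {
    total <- rowSums(p) * df
    out <- absolute / total
    out[spec$excluded | total == 0] <- NA_real_
    return(out)
  }
  # mongrain
  if (is.null(hypnogram_scores))
    fk_stop("fk_parameter_error", "mongrain scaling requires a score set")
  st <- stage_of_windows(spec, hypnogram_scores)
  deep <- which(st %in% deep_stages & !spec$excluded)
  if (!length(deep))
    fk_stop("fk_parameter_error", "no deep-sleep windows for mongrain scaling")
  absolute / mean(absolute[deep])
}

## Stage code of each spectrogram window (stage of the scoring window
## containing the spectrogram window's start).
stage_of_windows <- function(spec, scores) {
  w0 <- spec$window_centers_s - spec$window_length_s / 2
  idx <- floor(w0 / scores$window_length_s) + 1
  idx[idx < 1 | idx > length(scores$stages)] <- NA
  out <- rep(NA_integer_, length(idx))
  ok <- !is.na(idx)
  out[ok] <- scores$stages[idx[ok]]
  out
}

#' Mean power spectrum during one sleep stage
#'
#' Unweighted mean PSD of one channel across the non-excluded
#' spectrogram windows scored as the requested stage.
#'
#' @param spec [spectrogram()] result
#' @param scores score set
#' @param stage_code stage code (0-6)
#' @param channel channel name
#' @return list(freq, psd)
#' @export
stage_mean_spectrum <- function(spec, scores, stage_code, channel) {
  ci <- spec_channel_index(spec, channel)
  st <- stage_of_windows(spec, scores)
  sel <- which(st == stage_code & !spec$excluded)
  if (!length(sel)) {
    avail <- sort(unique(st[!spec$excluded & !is.na(st)]))
    fk_stop("fk_parameter_error",
            "no valid windows in stage %s (available stages: %s)",
            stage_code, paste(avail, collapse = ", "))
  }
  p <- spec$power[ci, sel, , drop = FALSE]
  list(freq = spec$frequencies_hz, psd = apply(p, 3, mean))
}
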