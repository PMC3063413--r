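## Pulse-artefact (ballistocardiogram) rejection.
##
## The cardiac pulse artefact is beat-locked but nonstationary (it varies
## from heartbeat to heartbeat), a few tens of microvolts with main
## frequency around 1-2 Hz. Three corrections are provided: Gaussian-mean
## averaging (a beat-locked AAS with Gaussian weights), OBS-PCA (fit and
## subtract an optimal basis set of beat-epoch principal components), and
## a combined method that applies Gaussian-mean to the low-pass (<= 4 Hz)
## part and OBS-PCA to the high-pass (>= 4 Hz) part before recombining.

#' Pulse-artefact correction settings
#'
#' @param method `"gaussian_mean"`, `"obs_pca"` or `"combined"`
#' @param n_obs_components number of principal components in the OBS
#'   basis (default 4)
#' @param gm_window_beats Gaussian-mean window size in beats (odd,
#'   default 21)
#' @param gm_sigma_beats Gaussian weight spread in beats (default 5)
#' @param epoch_pre_frac,epoch_post_frac epoch extent before/after the R
#'   peak as fractions of the median RR interval (defaults 0.25 / 0.75)
#' @param split_hz combined-method crossover frequency (default 4)
#' @return list of class `fk_pa_config`
#' @export
pa_config <- function(method = c("combined", "gaussian_mean", "obs_pca"),
                      n_obs_components = 4, gm_window_beats = 21,
                      gm_sigma_beats = 5, epoch_pre_frac = 0.25,
                      epoch_post_frac = 0.75, split_hz = 4) {
  method <- match.arg(method)
  if (n_obs_components < 1)
    fk_stop("fk_parameter_error", "n_obs_components must be >= 1")
  if (gm_window_beats %% 2 == 0)
    fk_stop("fk_parameter_error", "gm_window_beats must be odd")
  structure(list(method = method, n_obs_components = as.integer(n_obs_components),
                 gm_window_beats = as.integer(gm_window_beats),
                 gm_sigma_beats = gm_sigma_beats,
                 epoch_pre_frac = epoch_pre_frac,
                 epoch_post_frac = epoch_post_frac, split_hz = split_hz),
            class = "fk_pa_config")
}

#' Detect heartbeats on an ECG channel
#'
#' Polarity-invariant QRS detection: the ECG is band-passed to 7-40 Hz,
#' passed through the Teager energy operator, smoothed, and thresholded
#' adaptively; an RR-interval plausibility pass recovers beats missed in
#' long gaps and prunes implausibly close detections. R-peak times are
#' refined to the local absolute maximum of the band-passed ECG.
#'
#' @param rec recording (>= 10 s)
#' @param ecg_channel ECG channel name (default: first channel of kind
#'   ECG)
#' @return object of class `fk_heartbeats`: `r_peaks` (0-based samples,
#'   strictly increasing) and `median_rr` (samples)
#' @export
detect_qrs <- function(rec, ecg_channel = NULL) {
  if (is.null(ecg_channel)) {
    hit <- which(rec$channels$kind == "ECG")
    if (!length(hit))
      fk_stop("fk_name_error", "no ECG channel in recording")
    ecg_channel <- rec$channels$name[hit[1]]
  }
  fs <- rec$sampling_rate
  if (rec$n_samples < 10 * fs)
    fk_stop("fk_parameter_error", "need at least 10 s of ECG")
  x <- read_window(rec, ecg_channel)[1, ]
  bp <- bandpass(x, fs, 7, min(40, fs / 2 - 1e-9))
  n <- length(bp)
  e <- bp^2
  e[2:(n - 1)] <- bp[2:(n - 1)]^2 - bp[1:(n - 2)] * bp[3:n]
  e[e < 0] <- 0
  k <- max(3, round(0.08 * fs))
  e <- as.numeric(stats::filter(e, rep(1 / k, k), sides = 2))
  e[is.na(e)] <- 0

  top <- quantile(e, 0.99)
  if (top <= 0)
    fk_stop("fk_detection_error", "no plausible heartbeats on %s", ecg_channel)
  thr <- 0.2 * top
  refract <- round(0.35 * fs)
  peaks <- find_energy_peaks(e, thr, refract)
  if (length(peaks) < 3)
    fk_stop("fk_detection_error", "no plausible heartbeats on %s", ecg_channel)
  med_rr <- median(diff(peaks))
  # recover beats missed in long gaps with a halved threshold
  repeat {
    gaps <- which(diff(peaks) > 1.6 * med_rr)
    added <- FALSE
    for (g in gaps) {
      lo <- peaks[g] + refract
      hi <- peaks[g + 1] - refract
      if (hi <= lo) next
      seg <- e[lo:hi]
      if (max(seg) > thr / 2) {
        peaks <- sort(c(peaks, lo + which.max(seg) - 1))
        added <- TRUE
      }
    }
    if (!added) break
    med_rr <- median(diff(peaks))
  }
  # prune implausibly close pairs, keeping the stronger
  repeat {
    d <- diff(peaks)
    bad <- which(d < 0.4 * med_rr)
    if (!length(bad)) break
    b <- bad[1]
    drop <- if (e[peaks[b]] < e[peaks[b + 1]]) b else b + 1
    peaks <- peaks[-drop]
  }
  # refine to the absolute band-passed extremum (polarity-invariant)
  half <- round(0.05 * fs)
  r <- vapply(peaks, function(p) {
    lo <- max(1, p - half); hi <- min(n, p + half)
    lo + which.max(abs(bp[lo:hi])) - 1
  }, numeric(1))
  r <- sort(unique(r))
  bpm <- 60 * (length(r) - 1) / ((r[length(r)] - r[1]) / fs)
  if (is.na(bpm) || bpm < 30 || bpm > 180)
    fk_stop("fk_detection_error",
            "estimated heart rate %.0f bpm outside 30-180", bpm)
  structure(list(r_peaks = r - 1, median_rr = median(diff(r))),
            class = "fk_heartbeats")
}

find_energy_peaks <- function(e, thr, refract) {
  n <- length(e)
  cand <- which(e > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[e[cand] >= e[cand - 1] & e[cand] >= e[cand + 1]]
  if (!length(cand)) return(integer())
  cand <- cand[order(e[cand], decreasing = TRUE)]
  taken <- integer()
  for (p in cand)
    if (!length(taken) || all(abs(taken - p) >= refract))
      taken <- c(taken, p)
  sort(taken)
}

#' @export
print.fk_heartbeats <- function(x, ...) {
  cat(sprintf("<fk_heartbeats> %d beats, median RR = %g samples\n",
              length(x$r_peaks), x$median_rr))
  invisible(x)
}

corrected_channel_idx <- function(rec, channels) {
  if (is.null(channels))
    which(rec$channels$kind %in% c("EEG", "EOG", "EMG"))
  else
    channel_indices(rec, channels)
}

## Per-beat epoch boundaries on the raw grid, truncated at the midpoints
## between neighbouring beats so overlapping epochs never double-correct.
beat_ranges <- function(r_peaks, pre_len, post_len, n) {
  nb <- length(r_peaks)
  lo <- hi <- numeric(nb)
  for (i in seq_len(nb)) {
    l <- r_peaks[i] - pre_len
    h <- r_peaks[i] + post_len          # half-open [l, h)
    # truncate at the midpoint only when neighbouring epochs overlap
    if (i > 1 && r_peaks[i - 1] + post_len > l)
      l <- max(l, floor((r_peaks[i - 1] + r_peaks[i]) / 2) + 1)
    if (i < nb && r_peaks[i + 1] - pre_len < h)
      h <- min(h, floor((r_peaks[i] + r_peaks[i + 1]) / 2) + 1)
    lo[i] <- max(l, 0)
    hi[i] <- min(h, n)
  }
  cbind(lo, hi)
}

#' Gaussian-mean pulse-artefact correction
#'
#' Beat-locked averaged artefact subtraction with Gaussian weights: for
#' each channel and each beat, the template is the Gaussian-weighted
#' mean (sigma = `gm_sigma_beats` beats, weights normalized to 1) of the
#' `gm_window_beats` surrounding epochs, aligned on the R peak; the
#' template is subtracted over the beat's epoch. Epochs span
#' `[R - 0.25 RR, R + 0.75 RR)` of the median RR by default and are
#' truncated at the midpoint between beats when they would overlap.
#' Samples outside all epochs, and channels outside the corrected set,
#' are untouched.
#'
#' @param rec recording
#' @param beats [detect_qrs()] result
#' @param cfg [pa_config()]
#' @param channels channels to correct (default: all EEG/EOG/EMG)
#' @return corrected recording
#' @export
correct_gaussian_mean <- function(rec, beats, cfg = pa_config("gaussian_mean"),
                                  channels = NULL) {
  idx <- corrected_channel_idx(rec, channels)
  pre_len <- round(cfg$epoch_pre_frac * beats$median_rr)
  post_len <- round(cfg$epoch_post_frac * beats$median_rr)
  L <- pre_len + post_len
  nb <- length(beats$r_peaks)
  rng <- beat_ranges(beats$r_peaks, pre_len, post_len, rec$n_samples)
  half <- (cfg$gm_window_beats - 1) %/% 2
  data <- read_window(rec)
  for (ch in idx) {
    x <- data[ch, ]
    ep <- matrix(NA_real_, nb, L)
    for (i in seq_len(nb)) {
      off0 <- rng[i, 1] - (beats$r_peaks[i] - pre_len)   # offset into grid
      len <- rng[i, 2] - rng[i, 1]
      if (len > 0)
        ep[i, seq_len(len) + off0] <- x[(rng[i, 1] + 1):rng[i, 2]]
    }
    for (i in seq_len(nb)) {
      win <- max(1, i - half):min(nb, i + half)
      w <- exp(-((win - i)^2) / (2 * cfg$gm_sigma_beats^2))
      sub <- ep[win, , drop = FALSE]
      wm <- matrix(w, nrow = length(win), ncol = L)
      wm[is.na(sub)] <- 0
      sub[is.na(sub)] <- 0
      denom <- colSums(wm)
      tmpl <- colSums(sub * wm) / ifelse(denom > 0, denom, 1)
      off0 <- rng[i, 1] - (beats$r_peaks[i] - pre_len)
      len <- rng[i, 2] - rng[i, 1]
      if (len > 0)
        x[(rng[i, 1] + 1):rng[i, 2]] <-
          x[(rng[i, 1] + 1):rng[i, 2]] - tmpl[seq_len(len) + off0]
    }
    data[ch, ] <- x
  }
  with_data(rec, data, sprintf("correct_gaussian_mean (%d beats)", nb))
}

#' OBS-PCA pulse-artefact correction
#'
#' Per channel: beat epochs (aligned on the R peak, linearly
#' time-normalized to the median-RR grid) are stacked into a beats x
#' time matrix; the optimal basis set is the mean epoch plus the first
#' `n_obs_components` principal components of the epoch matrix. The
#' basis (with an intercept) is fitted to every epoch by least squares
#' and the fit subtracted over the beat's (midpoint-truncated) extent.
#' Component signs are fixed so each component's largest-magnitude
#' coefficient is positive, making the correction deterministic.
#'
#' @inheritParams correct_gaussian_mean
#' @return corrected recording
#' @export
correct_obs_pca <- function(rec, beats, cfg = pa_config("obs_pca"),
                            channels = NULL) {
  idx <- corrected_channel_idx(rec, channels)
  nb <- length(beats$r_peaks)
  if (nb < cfg$n_obs_components + 2)
    fk_stop("fk_parameter_error", "need at least %d beats for %d components",
            cfg$n_obs_components + 2, cfg$n_obs_components)
  pre_len <- round(cfg$epoch_pre_frac * beats$median_rr)
  post_len <- round(cfg$epoch_post_frac * beats$median_rr)
  L <- pre_len + post_len
  grid <- seq_len(L) - 1 - pre_len                # offsets from R peak
  rng <- beat_ranges(beats$r_peaks, pre_len, post_len, rec$n_samples)
  n <- rec$n_samples
  # local RR per beat for time normalization
  rr_loc <- rep(beats$median_rr, nb)
  if (nb > 2) {
    d <- diff(beats$r_peaks)
    rr_loc <- c(d[1], (d[-length(d)] + d[-1]) / 2, d[length(d)])
  }
  data <- read_window(rec)
  for (ch in idx) {
    x <- data[ch, ]
    ep <- matrix(0, nb, L)
    for (i in seq_len(nb)) {
      # sample the beat's own RR-scaled epoch onto the median grid
      t_src <- beats$r_peaks[i] + grid * (rr_loc[i] / beats$median_rr)
      t_src <- pmin(pmax(t_src, 0), n - 1)
      ep[i, ] <- approx(seq_len(n) - 1, x, xout = t_src, rule = 2)$y
    }
    # demean each epoch; the PCA runs on the uncentered matrix so the
    # mean artefact waveform is captured by the leading component
    dev <- ep - rowMeans(ep)
    k <- min(cfg$n_obs_components, nb, L)
    pc <- prcomp(dev, center = FALSE, rank. = k)
    rot <- pc$rotation
    nz <- which(pc$sdev[seq_len(ncol(rot))] > 1e-12 * pc$sdev[1])
    rot <- rot[, nz, drop = FALSE]
    if (ncol(rot) < cfg$n_obs_components)
      fk_warn("epoch matrix rank %d < %d requested components",
              ncol(rot), cfg$n_obs_components)
    for (j in seq_len(ncol(rot)))
      if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
    # least-squares fit of the orthonormal basis = projection
    fit <- (dev %*% rot) %*% t(rot)               # artefact estimate per beat
    for (i in seq_len(nb)) {
      len <- rng[i, 2] - rng[i, 1]
      if (len <= 0) next
      # map the fit back to the beat's own time grid
      t_norm <- (((rng[i, 1]:(rng[i, 2] - 1)) - beats$r_peaks[i]) *
                   (beats$median_rr / rr_loc[i])) + pre_len + 1
      vals <- approx(seq_len(L), fit[i, ], xout = t_norm, rule = 2)$y
      x[(rng[i, 1] + 1):rng[i, 2]] <- x[(rng[i, 1] + 1):rng[i, 2]] - vals
    }
    data[ch, ] <- x
  }
  with_data(rec, data, sprintf("correct_obs_pca (k = %d, %d beats)",
                               cfg$n_obs_components, nb))
}

#' Combined low/high-band pulse-artefact correction
#'
#' Gaussian-mean correction is applied to the low-pass (<= `split_hz`)
#' part of the signal and OBS-PCA to the high-pass (>= `split_hz`) part;
#' the two corrected parts are summed. The branch filters are exactly
#' amplitude-complementary, so with no correction applied the two
#' branches reconstruct the input.
#'
#' @inheritParams correct_gaussian_mean
#' @return corrected recording
#' @export
correct_combined <- function(rec, beats, cfg = pa_config("combined"),
                             channels = NULL) {
  idx <- corrected_channel_idx(rec, channels)
  data <- read_window(rec)
  lo <- data; hi <- data
  for (ch in idx) {
    lo[ch, ] <- lowpass(data[ch, ], rec$sampling_rate, cfg$split_hz)
    hi[ch, ] <- data[ch, ] - lo[ch, ]   # exact complement
  }
  rec_lo <- correct_gaussian_mean(with_data(rec, lo), beats, cfg,
                                  rec$channels$name[idx])
  rec_hi <- correct_obs_pca(with_data(rec, hi), beats, cfg,
                            rec$channels$name[idx])
  out <- read_window(rec_lo) + read_window(rec_hi)
  out[-idx, ] <- data[-idx, , drop = FALSE]
  with_data(rec, out, sprintf("correct_combined (split %g Hz)", cfg$split_hz))
}

#' Dispatch on the configured pulse-artefact method
#' @inheritParams correct_gaussian_mean
#' @export
correct_pulse <- function(rec, beats, cfg = pa_config(), channels = NULL) {
  switch(cfg$method,
         gaussian_mean = correct_gaussian_mean(rec, beats, cfg, channels),
         obs_pca = correct_obs_pca(rec, beats, cfg, channels),
         combined = correct_combined(rec, beats, cfg, channels))
}
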