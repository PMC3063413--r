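## Synthetic-data generators with known ground truth. Every generator is
## a pure function of its parameters and seed (the global RNG state is
## saved and restored), and returns the injected truth alongside the
## recording so tests never need external data.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

DEFAULT_MONTAGE <- c("Fp1", "Fp2", "AF3", "AF4", "F3", "Fz", "F4",
                     "FC3", "C3", "CP3", "FC4", "C4", "CP4",
                     "P3", "Pz", "P4", "POz", "O1", "O2", "M1", "M2",
                     "T7", "T8", "F7", "F8", "Cz", "Oz", "FCz")

#' Synthetic multichannel EEG background
#'
#' 1/f-shaped Gaussian noise per channel (log-log PSD slope about -1
#' over 1-40 Hz, flattened below 0.5 Hz), scaled to a target RMS of
#' 15 uV — a realistic amplitude for scalp EEG background. Channels are
#' named after the extended 10-20 montage so ROI maps apply directly.
#'
#' @param n_channels number of channels
#' @param fs sampling rate, Hz
#' @param duration_s duration, seconds
#' @param seed RNG seed
#' @param rms_uv target per-channel RMS (default 15)
#' @return a [recording()]
#' @export
gen_background <- function(n_channels, fs, duration_s, seed = 1,
                           rms_uv = 15) {
  n <- round(fs * duration_s)
  data <- with_seed(seed, {
    m <- matrix(0, n_channels, n)
    f <- seq(0, n - 1) / n * fs
    f <- pmin(f, fs - f)
    shape <- 1 / sqrt(pmax(f, 0.5))
    for (ch in seq_len(n_channels)) {
      w <- rnorm(n)
      x <- Re(fft(fft(w) * shape, inverse = TRUE)) / n
      m[ch, ] <- x * (rms_uv / sqrt(mean(x^2)))
    }
    m
  })
  nm <- DEFAULT_MONTAGE[seq_len(n_channels)]
  nm[is.na(nm)] <- paste0("X", which(is.na(nm)))
  rec <- recording(data, fs, channel_info(nm, "EEG"))
  add_history(rec, sprintf("gen_background(seed = %d)", seed))
}

#' Inject a strictly TR-periodic gradient artefact
#'
#' Adds the same seeded random-spline waveform once per TR inside the
#' episode — the idealized, perfectly stationary gradient artefact that
#' averaged artefact subtraction assumes — and writes one volume-trigger
#' event per repetition. At the default 5000 uV amplitude the artefact
#' exceeds a 15 uV EEG background by more than 40 dB.
#'
#' @param rec recording
#' @param tr_s repetition time, seconds
#' @param amplitude_uv peak artefact amplitude (default 5000)
#' @param episode_s c(start, end) of the scanning episode, seconds
#'   (default: whole recording)
#' @param seed seed for the waveform shape
#' @param trigger_label event label for the volume triggers
#' @return list(recording, onsets = 0-based volume onset samples,
#'   template = one-TR waveform)
#' @export
inject_gradient_artefact <- function(rec, tr_s, amplitude_uv = 5000,
                                     episode_s = c(0, duration_s(rec)),
                                     seed = 1,
                                     trigger_label = "fmri_volume_trigger") {
  fs <- rec$sampling_rate
  tr_len <- round(tr_s * fs)
  template <- with_seed(seed, {
    k <- 24
    ctrl <- rnorm(k)
    sp <- spline(seq_len(k), ctrl, n = tr_len)$y
    if (amplitude_uv == 0) rep(0, tr_len)
    else sp / max(abs(sp)) * amplitude_uv
  })
  s0 <- round(episode_s[1] * fs)
  s1 <- min(round(episode_s[2] * fs), rec$n_samples)
  n_vol <- floor((s1 - s0) / tr_len)
  onsets <- s0 + (seq_len(n_vol) - 1) * tr_len
  data <- read_window(rec)
  for (on in onsets)
    data[, (on + 1):(on + tr_len)] <-
      sweep(data[, (on + 1):(on + tr_len), drop = FALSE], 2, template, "+")
  out <- with_data(rec, data, sprintf("inject_gradient_artefact(tr = %g)", tr_s))
  if (amplitude_uv != 0 && n_vol > 0)
    out <- add_events(out, events_table(trigger_label, onsets))
  list(recording = out, onsets = onsets, template = template)
}

## One cardiac cycle of synthetic ECG, phase in [0, 1) around the R peak.
ecg_cycle <- function(phase) {
  g <- function(mu, sigma, amp) amp * exp(-((phase - mu)^2) / (2 * sigma^2))
  g(-0.20, 0.030, 120) +          # P
    g(-0.025, 0.012, -150) +      # Q
    g(0, 0.012, 800) +            # R
    g(0.030, 0.015, -250) +       # S
    g(0.25, 0.045, 250)           # T
}

#' Synthetic ECG trace with known beat times
#'
#' @param fs sampling rate, Hz
#' @param duration_s duration, seconds
#' @param bpm heart rate (default 60)
#' @param noise_rms_uv additive white noise RMS (default 0)
#' @param seed RNG seed (noise)
#' @param polarity +1 or -1
#' @return list(x = uV trace, beats = 0-based R-peak samples)
#' @export
synth_ecg <- function(fs, duration_s, bpm = 60, noise_rms_uv = 0, seed = 1,
                      polarity = 1) {
  n <- round(fs * duration_s)
  rr <- 60 / bpm
  r_times <- seq(0.5, duration_s - 0.5, by = rr)
  beats <- round(r_times * fs)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  for (rt in beats / fs) {
    ph <- (t - rt) / rr
    sel <- which(ph > -0.45 & ph < 0.55)
    x[sel] <- x[sel] + ecg_cycle(ph[sel])
  }
  x <- x * polarity
  if (noise_rms_uv > 0)
    x <- x + with_seed(seed, rnorm(n, sd = noise_rms_uv))
  list(x = x, beats = beats)
}

#' Inject a heartbeat-locked pulse artefact and an ECG channel
#'
#' Adds a synthetic ECG channel plus, on every EEG channel, a
#' beat-locked artefact built from 2-3 Gaussian bumps over the cardiac
#' cycle — a few tens of microvolts with main power around 1-2 Hz, like
#' the ballistocardiogram in a 3T scanner. Beat-to-beat variability is
#' multiplicative lognormal amplitude jitter.
#'
#' @param rec recording (EEG channels receive the artefact)
#' @param bpm heart rate (default 60)
#' @param variability lognormal sigma of the per-beat amplitude jitter
#'   (0 = identical artefact every beat)
#' @param amplitude_uv typical artefact amplitude per channel (default
#'   40)
#' @param seed RNG seed
#' @return list(recording, beats = 0-based R-peak samples,
#'   beat_scales = beats x channels jitter matrix, templates = channels
#'   x cycle-length artefact templates)
#' @export
inject_pulse_artefact <- function(rec, bpm = 60, variability = 0.1,
                                  amplitude_uv = 40, seed = 1) {
  fs <- rec$sampling_rate
  n <- rec$n_samples
  ecg <- synth_ecg(fs, n / fs, bpm)
  rr_samp <- round(60 / bpm * fs)
  eeg_idx <- which(rec$channels$kind == "EEG")
  cyc <- seq(0, rr_samp - 1) / rr_samp            # phase 0..1 from R peak
  gens <- with_seed(seed, {
    tm <- matrix(0, length(eeg_idx), rr_samp)
    for (k in seq_along(eeg_idx)) {
      nb <- sample(2:3, 1)
      mu <- runif(nb, 0.05, 0.8)
      sg <- runif(nb, 0.06, 0.15)
      am <- runif(nb, 0.4, 1) * amplitude_uv * sample(c(-1, 1), nb, TRUE)
      for (b in seq_len(nb))
        tm[k, ] <- tm[k, ] + am[b] * exp(-((cyc - mu[b])^2) / (2 * sg[b]^2))
    }
    scales <- matrix(
      exp(rnorm(length(ecg$beats) * length(eeg_idx), 0, variability)),
      length(ecg$beats), length(eeg_idx))
    if (variability == 0) scales[] <- 1
    list(templates = tm, scales = scales)
  })
  data <- read_window(rec)
  for (bi in seq_along(ecg$beats)) {
    s <- ecg$beats[bi] + 1
    len <- min(rr_samp, n - s + 1)
    if (len <= 0) next
    for (k in seq_along(eeg_idx))
      data[eeg_idx[k], s:(s + len - 1)] <-
        data[eeg_idx[k], s:(s + len - 1)] +
        gens$templates[k, seq_len(len)] * gens$scales[bi, k]
  }
  data <- rbind(data, ecg$x)
  channels <- rbind(rec$channels, channel_info("ECG", "ECG"))
  out <- recording(data, fs, channels, events = rec$events,
                   start_clock_time = rec$start_clock_time,
                   scores = rec$scores, history = rec$history)
  out <- add_history(out, sprintf("inject_pulse_artefact(bpm = %g)", bpm))
  list(recording = out, beats = ecg$beats, beat_scales = gens$scales,
       templates = gens$templates)
}

#' Canonical biphasic slow-wave pulse
#'
#' A smooth negative-then-positive waveform whose criterion-relevant
#' measurements are exact by construction: a small positive lead-in
#' bump, a negative half-sine of duration `sep_s` (the down-to-up
#' zero-crossing separation) reaching `neg_uv` at its center, and a
#' positive half-sine whose peak of `pos_uv` occurs `pos_lag_s` after
#' the up crossing. Zero crossings land exactly on sample instants when
#' the durations are whole numbers of samples.
#'
#' @param fs sampling rate, Hz
#' @param sep_s down-to-up zero-crossing separation, seconds
#' @param neg_uv negative-peak voltage (negative), uV
#' @param pos_uv positive-peak voltage, uV
#' @param pos_lag_s up-crossing-to-positive-peak lag, seconds
#' @param lead_s lead-in bump duration, seconds
#' @param lead_uv lead-in bump amplitude, uV
#' @return list(x = waveform, down_i = 0-based sample of the down
#'   crossing within x)
#' @export
sw_pulse <- function(fs, sep_s = 0.5, neg_uv = -100, pos_uv = 60,
                     pos_lag_s = 0.4, lead_s = 0.15,
                     lead_uv = abs(neg_uv) / 20) {
  n_lead <- round(lead_s * fs)
  n_neg <- round(sep_s * fs)
  n_pos <- round(2 * pos_lag_s * fs)
  k <- 0:(n_lead + n_neg + n_pos)
  x <- numeric(length(k))
  lead <- k <= n_lead
  x[lead] <- lead_uv * sin(pi * k[lead] / n_lead)
  negp <- k >= n_lead & k <= n_lead + n_neg
  x[negp] <- neg_uv * sin(pi * (k[negp] - n_lead) / n_neg)
  posp <- k >= n_lead + n_neg
  x[posp] <- pos_uv * sin(pi * (k[posp] - n_lead - n_neg) / n_pos)
  list(x = x, down_i = n_lead)
}

#' Inject slow waves with known per-electrode delays
#'
#' Each wave spec places an [sw_pulse()] at a given time; per-electrode
#' delays (seconds) shift the waveform on each named electrode, so the
#' injected propagation pattern is exactly recoverable.
#'
#' @param rec recording
#' @param wave_specs list of specs: list(time_s, sep_s, neg_uv, pos_uv,
#'   pos_lag_s, delays = named vector of per-electrode delays in
#'   seconds; NULL = all EEG electrodes at delay 0)
#' @return list(recording, truth = data.frame of injected parameters)
#' @export
inject_slow_waves <- function(rec, wave_specs) {
  fs <- rec$sampling_rate
  data <- read_window(rec)
  truth <- list()
  for (ws in wave_specs) {
    ws <- modifyList(list(sep_s = 0.5, neg_uv = -100, pos_uv = 60,
                          pos_lag_s = 0.4, delays = NULL), ws)
    delays <- ws$delays
    if (is.null(delays)) {
      nm <- rec$channels$name[rec$channels$kind == "EEG"]
      delays <- setNames(rep(0, length(nm)), nm)
    }
    missing <- setdiff(names(delays), rec$channels$name)
    if (length(missing))
      fk_stop("fk_name_error", "unknown electrode(s) in wave spec: %s",
              paste(missing, collapse = ", "))
    pulse <- sw_pulse(fs, ws$sep_s, ws$neg_uv, ws$pos_uv, ws$pos_lag_s)
    for (e in names(delays)) {
      s <- round((ws$time_s + delays[[e]]) * fs) - pulse$down_i + 1
      idx <- seq_along(pulse$x) + s - 1
      ok <- idx >= 1 & idx <= ncol(data)
      ch <- match(e, rec$channels$name)
      data[ch, idx[ok]] <- data[ch, idx[ok]] + pulse$x[ok]
    }
    truth[[length(truth) + 1]] <- data.frame(
      time_s = ws$time_s, sep_s = ws$sep_s, neg_uv = ws$neg_uv,
      pos_uv = ws$pos_uv, pos_lag_s = ws$pos_lag_s,
      n_electrodes = length(delays))
  }
  list(recording = with_data(rec, data, "inject_slow_waves"),
       truth = do.call(rbind, truth))
}

#' Synthetic stage-structured sleep recording
#'
#' EEG background plus stage-dependent oscillations (delta in deep
#' sleep, spindle-band activity in stage 2, alpha in wake), with the
#' generating hypnogram attached as a score set — ground truth for
#' score-aware spectral analysis.
#'
#' @param n_channels channels
#' @param fs sampling rate, Hz
#' @param stage_pattern integer stage codes, one per scoring window
#' @param window_s scoring window length, seconds (default 30)
#' @param seed RNG seed
#' @param scorer_id scorer id of the truth score set
#' @return list(recording, scores)
#' @export
gen_sleep_recording <- function(n_channels = 4, fs = 100,
                                stage_pattern = c(0, 0, 1, 2, 2, 3, 3, 4, 4, 5, 5, 0),
                                window_s = 30, seed = 1,
                                scorer_id = "truth") {
  dur <- length(stage_pattern) * window_s
  rec <- gen_background(n_channels, fs, dur, seed)
  data <- read_window(rec)
  t <- (seq_len(rec$n_samples) - 1) / fs
  osc_freq <- c(`0` = 10, `1` = 6, `2` = 13, `3` = 1, `4` = 0.8, `5` = 5,
                `6` = 0)
  osc_amp <- c(`0` = 15, `1` = 10, `2` = 12, `3` = 60, `4` = 70, `5` = 10,
               `6` = 0)
  for (w in seq_along(stage_pattern)) {
    st <- as.character(stage_pattern[w])
    if (!st %in% names(osc_freq) || osc_amp[st] == 0) next
    sel <- t >= (w - 1) * window_s & t < w * window_s
    osc <- osc_amp[st] * sin(2 * pi * osc_freq[st] * t[sel])
    data[, sel] <- sweep(data[, sel, drop = FALSE], 2, osc, "+")
  }
  rec <- with_data(rec, data, "gen_sleep_recording")
  ss <- scoreset(scorer_id, window_s, dur, fpl_sample = 0,
                 opl_sample = rec$n_samples, sampling_rate = fs)
  ss$stages <- as.integer(stage_pattern)
  rec <- add_scoreset(rec, ss)
  list(recording = rec, scores = ss)
}
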