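# Shared fixtures and independent oracles. Everything is generated in
# code at test time; nothing is read from disk except files the tests
# themselves write to tempdir().

# Deterministic fill pattern sample(c, t) = 1000*c + t (t 0-based).
pattern_recording <- function(n_channels = 3, n_samples = 10, fs = 100) {
  data <- outer(seq_len(n_channels) * 1000,
                seq_len(n_samples) - 1, `+`)
  recording(data, fs, channel_info(paste0("ch", seq_len(n_channels))))
}

# Write a BrainVision triple (.vhdr/.vmrk/.eeg) fixture. `data` is an
# integer channels x samples matrix of raw INT16 values.
write_bv_fixture <- function(dir, name = "fix", data, fs = 500,
                             resolution = 0.5, markers = list(),
                             orientation = "MULTIPLEXED",
                             marker_file = TRUE) {
  nch <- nrow(data)
  vhdr <- file.path(dir, paste0(name, ".vhdr"))
  vmrk <- file.path(dir, paste0(name, ".vmrk"))
  eeg <- file.path(dir, paste0(name, ".eeg"))
  ch_lines <- vapply(seq_len(nch), function(k)
    sprintf("Ch%d=CH%d,,%g,µV", k, k, resolution), "")
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    sprintf("DataFile=%s.eeg", name),
    if (marker_file) sprintf("MarkerFile=%s.vmrk", name),
    "DataFormat=BINARY",
    sprintf("DataOrientation=%s", orientation),
    sprintf("NumberOfChannels=%d", nch),
    sprintf("SamplingInterval=%g", 1e6 / fs),
    "[Binary Infos]",
    "BinaryFormat=INT_16",
    "[Channel Infos]",
    ch_lines
  ), vhdr)
  mk_lines <- character()
  for (i in seq_along(markers)) {
    m <- markers[[i]]
    mk_lines <- c(mk_lines, sprintf(
      "Mk%d=%s,%s,%d,%d,0%s", i, m$type, m$descr %||% "", m$position,
      m$points %||% 1, if (!is.null(m$date)) paste0(",", m$date) else ""))
  }
  writeLines(c("Brain Vision Data Exchange Marker File, Version 1.0",
               "[Marker Infos]", mk_lines), vmrk)
  con <- file(eeg, "wb")
  vals <- if (orientation == "VECTORIZED") as.integer(t(data))
          else as.integer(data)
  writeBin(vals, con, size = 2L, endian = "little")
  close(con)
  vhdr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- independent brute-force slow-wave criteria validator -------------
# Re-implements the five criteria with plain loops; shares no code with
# detect_sw(). Used as the soundness/completeness oracle.
bruteforce_sw <- function(x, fs, sep_range = c(0.25, 1.25),
                          neg_thr = -80, p2p_thr = 140, slope_frac = 0.9,
                          pos_lag_max = 2) {
  n <- length(x)
  downs <- c(); ups <- c()
  for (i in 1:(n - 1)) {
    if (x[i] > 0 && x[i + 1] < 0)
      downs <- c(downs, i - 1 + x[i] / (x[i] - x[i + 1]))
    if (x[i] == 0 && x[i + 1] < 0 && i > 1 && x[i - 1] > 0)
      downs <- c(downs, i - 1)
    if (x[i] < 0 && x[i + 1] > 0)
      ups <- c(ups, i - 1 + (-x[i]) / (x[i + 1] - x[i]))
    if (x[i + 1] == 0 && x[i] < 0 && i + 2 <= n && x[i + 2] >= 0)
      ups <- c(ups, i)
  }
  cand <- list()
  for (d in downs) {
    u_after <- ups[ups > d]
    if (!length(u_after)) next
    u <- min(u_after)
    sep <- (u - d) / fs
    i0 <- ceiling(d) + 1; i1 <- floor(u) + 1
    neg_v <- min(x[i0:i1]); neg_i <- i0 + which.min(x[i0:i1]) - 1
    d_after <- downs[downs > u]
    j1 <- if (length(d_after)) floor(min(d_after)) + 1 else n
    j0 <- ceiling(u) + 1
    if (j1 <= j0) next
    pos_v <- max(x[j0:j1]); pos_i <- j0 + which.max(x[j0:j1]) - 1
    slope <- 0
    for (k in neg_i:(pos_i - 1))
      slope <- max(slope, (x[k + 1] - x[k]) * fs)
    cand[[length(cand) + 1]] <- list(
      sep = sep, neg = neg_v, p2p = pos_v - neg_v,
      neg_t = (neg_i - 1) / fs, pos_lag = (pos_i - 1) / fs - u / fs,
      slope = slope,
      c123 = sep >= sep_range[1] - 1e-6 && sep <= sep_range[2] + 1e-6 &&
        neg_v < neg_thr && (pos_v - neg_v) > p2p_thr)
  }
  if (!length(cand)) return(data.frame())
  passing123 <- Filter(function(w) w$c123, cand)
  if (!length(passing123)) return(data.frame())
  smax <- max(vapply(passing123, `[[`, 0, "slope"))
  ok <- Filter(function(w)
    w$c123 && w$slope > slope_frac * smax && w$pos_lag <= pos_lag_max + 1e-6,
    cand)
  do.call(rbind, lapply(ok, function(w)
    data.frame(neg_t = w$neg_t, neg = w$neg, p2p = w$p2p, sep = w$sep,
               slope = w$slope)))
}

# A recording holding a single canonical slow wave on every EEG channel.
single_wave_recording <- function(fs = 500, sep_s = 0.5, neg_uv = -100,
                                  pos_uv = 60, pos_lag_s = 0.4,
                                  duration_s = 10, time_s = 4,
                                  channels = c("Fz", "Cz")) {
  rec <- recording(matrix(0, length(channels), fs * duration_s), fs,
                   channel_info(channels, "EEG"))
  inject_slow_waves(rec, list(list(
    time_s = time_s, sep_s = sep_s, neg_uv = neg_uv, pos_uv = pos_uv,
    pos_lag_s = pos_lag_s)))$recording
}

expect_exit <- function(code, expected) expect_identical(code, expected)

hb <- function(beats) {
  structure(list(r_peaks = beats, median_rr = median(diff(beats))),
            class = "fk_heartbeats")
}

match_rate <- function(found, truth, tol) {
  hits <- vapply(truth, function(b) any(abs(found - b) <= tol), TRUE)
  false_pos <- vapply(found, function(f) all(abs(truth - f) > tol), TRUE)
  c(sens = mean(hits), fpr = sum(false_pos) / length(truth))
}

# Rank-3 beat-locked artefact: zero-mean orthonormal waveforms b_j with
# exactly orthogonal coefficient columns, so the OBS decomposition is
# analytically known.
rank3_fixture <- function(fs = 250, n_beats = 30, seed = 3) {
  set.seed(seed)
  rr <- fs
  L <- rr                                       # pre 0.25 + post 0.75
  n <- (n_beats + 2) * rr
  raw <- matrix(rnorm(L * 3), L, 3)
  raw <- apply(raw, 2, function(v) {
    f <- fft(v); f[20:(L - 19)] <- 0            # smooth
    Re(fft(f, inverse = TRUE)) / L
  })
  raw <- sweep(raw, 2, colMeans(raw))           # zero-mean waveforms
  B <- qr.Q(qr(raw))                            # orthonormal
  C <- matrix(rnorm(n_beats * 3), n_beats, 3)
  C <- sweep(C, 2, colMeans(C))
  C <- qr.Q(qr(C)) %*% diag(c(40, 20, 8))       # orthogonal, ordered scale
  beats <- (seq_len(n_beats)) * rr              # R peaks, 0-based
  x <- numeric(n)
  E <- C %*% t(B)                               # beats x L epochs
  pre <- round(0.25 * rr)                       # same grid as the method
  for (i in seq_len(n_beats))
    x[(beats[i] - pre) + seq_len(L)] <- E[i, ]
  list(rec = recording(matrix(x, 1), fs, channel_info("C3", "EEG")),
       beats = hb(beats), E = E, C = C, B = B, rr = rr)
}

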