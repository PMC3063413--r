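ecg_rec <- function(fs = 250, dur = 60, bpm = 60, noise = 0, seed = 1,
                    polarity = 1) {
  e <- synth_ecg(fs, dur, bpm, noise_rms_uv = noise, seed = seed,
                 polarity = polarity)
  rec <- recording(matrix(e$x, 1), fs, channel_info("ECG", "ECG"))
  list(rec = rec, beats = e$beats)
}

test_that("QRS detection recovers clean and inverted synthetic ECG", {
  fs <- 250
  for (pol in c(1, -1)) {
    e <- ecg_rec(fs, 60, 60, polarity = pol)
    beats <- detect_qrs(e$rec, "ECG")
    expect_equal(length(beats$r_peaks), length(e$beats))
    expect_true(all(abs(beats$r_peaks - e$beats) <= 1))
    expect_equal(beats$median_rr, fs)
  }
  # flat channel -> detection failure
  flat <- recording(matrix(0, 1, fs * 20), fs, channel_info("ECG", "ECG"))
  expect_error(detect_qrs(flat, "ECG"), class = "fk_detection_error")
  expect_error(detect_qrs(ecg_rec(fs, 5)$rec, "ECG"),
               class = "fk_parameter_error")   # < 10 s
})

test_that("QRS detection tolerates 10 dB additive noise", {
  fs <- 250
  clean <- synth_ecg(fs, 120, 72)
  sig_rms <- sqrt(mean(clean$x^2))
  noise_rms <- sig_rms / sqrt(10)              # SNR = 10 dB
  e <- ecg_rec(fs, 120, 72, noise = noise_rms, seed = 2)
  beats <- detect_qrs(e$rec, "ECG")
  m <- match_rate(beats$r_peaks, e$beats, tol = 0.02 * fs)  # +/- 20 ms
  expect_gte(m["sens"], 0.99)
  expect_lte(m["fpr"], 0.01)
})

pa_fixture <- function(fs = 250, dur = 40, variability = 0, n_ch = 2,
                       background = 0, seed = 1) {
  data <- if (background > 0) {
    read_window(gen_background(n_ch, fs, dur, seed, rms_uv = background))
  } else matrix(0, n_ch, fs * dur)
  rec <- recording(data, fs, channel_info(c("C3", "C4", "O1", "O2")[1:n_ch],
                                          "EEG"))
  inject_pulse_artefact(rec, bpm = 60, variability = variability,
                        seed = seed)
}

test_that("Gaussian mean removes an identical per-beat artefact exactly", {
  fs <- 250
  fx <- pa_fixture(fs)
  beats <- hb(fx$beats)
  out <- correct_gaussian_mean(fx$recording, beats)
  # interior epochs, whose whole Gaussian window consists of complete
  # artefact epochs, cancel exactly (edge beats see truncated neighbours)
  sel <- seq(fx$beats[12], fx$beats[length(fx$beats) - 11])
  expect_lt(max(abs(read_window(out, "C3")[1, sel])), 1e-6)
  expect_true(all(is.finite(read_window(out))))
  # ECG channel untouched
  expect_equal(read_window(out, "ECG"), read_window(fx$recording, "ECG"))
})

test_that("Gaussian weighting beats a flat mean under amplitude drift", {
  fs <- 250
  rr <- fs
  n <- 40 * fs
  beats <- seq(fs, n - fs, by = rr)
  tmpl <- 50 * exp(-((seq_len(rr) / rr - 0.4)^2) / (2 * 0.1^2))
  x <- numeric(n)
  for (i in seq_along(beats))
    x[beats[i] + seq_len(rr)] <- tmpl * (1 + 0.03 * i)   # linear drift
  rec <- recording(matrix(x, 1), fs, channel_info("C3", "EEG"))
  b <- hb(beats)
  res_gauss <- read_window(correct_gaussian_mean(rec, b, pa_config(
    "gaussian_mean")))[1, ]
  res_flat <- read_window(correct_gaussian_mean(rec, b, pa_config(
    "gaussian_mean", gm_sigma_beats = 1e6)))[1, ]
  expect_lt(sqrt(mean(res_gauss^2)), sqrt(mean(res_flat^2)))
})

test_that("OBS with k = 4 removes a rank-3 artefact exactly", {
  fx <- rank3_fixture()
  # rank 3 < 4 requested components: used rank is reported
  expect_warning(out <- correct_obs_pca(fx$rec, fx$beats,
                                        pa_config("obs_pca")), "rank")
  sel <- seq(fx$beats$r_peaks[2], fx$beats$r_peaks[28])
  expect_lt(max(abs(read_window(out)[1, sel])), 1e-6)
  # determinism: identical rerun
  out2 <- suppressWarnings(correct_obs_pca(fx$rec, fx$beats,
                                           pa_config("obs_pca")))
  expect_identical(read_window(out), read_window(out2))
})

test_that("OBS with k = 2 leaves exactly the third component", {
  fx <- rank3_fixture()
  out <- correct_obs_pca(fx$rec, fx$beats,
                         pa_config("obs_pca", n_obs_components = 2))
  x <- read_window(out)[1, ]
  # oracle: residual of epoch i is its projection on the excluded third
  # axis, c_i3 * b3 — computed directly from the construction
  rr <- fx$rr
  for (i in c(5, 15, 25)) {
    s <- fx$beats$r_peaks[i] - round(0.25 * rr)
    got <- x[s + seq_len(rr)]
    want <- fx$C[i, 3] * fx$B[, 3]
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("OBS does not gut artefact-free EEG (8-12 Hz band)", {
  fs <- 250
  rec <- gen_background(1, fs, 180, seed = 4)
  beats <- hb(seq(fs, 179 * fs, by = fs))
  out <- correct_obs_pca(rec, beats, pa_config("obs_pca"))
  bpow <- function(r) {
    w <- welch_psd(read_window(r)[1, ], fs)
    band_integral(w$freq, w$psd, c(8, 12))
  }
  band_integral <- fastkit:::band_integral
  expect_lt(abs(bpow(out) - bpow(rec)) / bpow(rec), 0.1)
})

test_that("branch filters are complementary and split at 4 Hz", {
  fs <- 250
  set.seed(5)
  x <- rnorm(fs * 30)
  lo <- lowpass(x, fs, 4)
  hi <- highpass(x, fs, 4)
  expect_lt(sqrt(mean((lo + hi - x)^2)) / sqrt(mean(x^2)), 0.01)
  # magnitude responses cross where the gains are equal: 4 Hz
  glo <- fastkit:::butter_gain(seq(0.25, 10, 0.25), 4, "low")
  ghi <- fastkit:::butter_gain(seq(0.25, 10, 0.25), 4, "high")
  expect_equal(seq(0.25, 10, 0.25)[which.min(abs(glo - ghi))], 4)
})

test_that("combined method preserves high-band EEG, removes low-band artefact", {
  fs <- 500
  dur <- 240
  set.seed(10)
  # band-separated generator: EEG strictly above 4 Hz (5-30 Hz noise)
  clean <- bandpass(rnorm(fs * dur), fs, 5, 30)
  clean <- clean * (10 / sd(clean))
  # artefact confined below 4 Hz: one slow bump per beat
  rr <- fs
  beats <- seq(fs, (dur - 1) * fs, by = rr)
  x <- clean
  bump <- 60 * exp(-((seq_len(rr) / rr - 0.45)^2) / (2 * 0.16^2))
  for (b in beats) x[b + seq_len(rr)] <- x[b + seq_len(rr)] + bump
  recpa <- recording(matrix(x, 1), fs, channel_info("C3", "EEG"))
  out <- correct_combined(recpa, hb(beats), pa_config("combined"))
  sel <- seq(5 * fs, (dur - 5) * fs)
  y <- read_window(out)[1, ]
  # per-epoch least-squares OBS necessarily projects out ~k/L_eff of a
  # band-limited EEG's variance (L_eff = 2 x bandwidth x RR ~ 50 here),
  # bounding attainable fidelity near r ~ 0.91; see the methods vignette
  expect_gt(cor(highpass(y, fs, 4)[sel], clean[sel]), 0.90)
  lp_pow <- function(v) mean(lowpass(v, fs, 4)[sel]^2)
  expect_gt(10 * log10(lp_pow(x) / lp_pow(y)), 20)
})

test_that("every method reduces the beat-locked artefact by >= 70%", {
  fx <- pa_fixture(fs = 250, dur = 300, variability = 0.1, n_ch = 2,
                   background = 15, seed = 6)
  beats <- detect_qrs(fx$recording, "ECG")
  bla <- fastkit:::beat_locked_amplitude
  before <- bla(read_window(fx$recording, "C3")[1, ], beats)
  clean <- gen_background(2, 250, 300, 6, rms_uv = 15)
  wc <- welch_psd(read_window(clean)[1, ], 250)
  dev_from_clean <- function(r) {
    w <- welch_psd(read_window(r, "C3")[1, ], 250)
    sel <- w$freq >= 0.5 & w$freq <= 25
    sqrt(mean((log10(w$psd[sel]) - log10(wc$psd[sel]))^2))
  }
  devs <- c()
  for (m in c("gaussian_mean", "obs_pca", "combined")) {
    out <- correct_pulse(fx$recording, beats, pa_config(m))
    after <- bla(read_window(out, "C3")[1, ], beats)
    expect_lt(after, 0.3 * before)
    devs[m] <- dev_from_clean(out)
    # untouched: ECG channel identical
    expect_equal(read_window(out, "ECG"), read_window(fx$recording, "ECG"))
  }
  # the combined method's spectrum is closer to the clean spectrum than
  # no correction; plain OBS is NOT (it guts genuine 0.5-2 Hz activity,
  # the documented weakness that motivates the combined method) — so the
  # ordering is asserted for combined only, and OBS is checked to at
  # least suppress the artefact's own 1-2.5 Hz band
  expect_lt(devs["combined"], dev_from_clean(fx$recording))
  art_band <- function(r) {
    w <- welch_psd(read_window(r, "C3")[1, ], 250)
    sum(w$psd[w$freq >= 1 & w$freq <= 2.5])
  }
  expect_lt(art_band(correct_pulse(fx$recording, beats,
                                   pa_config("obs_pca"))),
            art_band(fx$recording))
})
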