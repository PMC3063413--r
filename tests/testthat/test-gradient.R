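square_artefact_rec <- function(amp, fs = 200, dur = 60, on = c(20, 40)) {
  x <- numeric(fs * dur)
  sel <- seq(on[1] * fs + 1, on[2] * fs)
  x[sel] <- amp * rep(c(1, -1), length.out = length(sel))
  recording(rbind(x, 0), fs, channel_info(c("Fz", "Cz")))
}

test_that("scanning-episode detection thresholds mean absolute amplitude", {
  cfg <- ga_config(tr_s = 2)
  # 400 uV square artefact in [20, 40) s -> exactly that episode
  rec <- square_artefact_rec(400)
  eps <- detect_scan_episode(rec, cfg)
  expect_length(eps, 1)
  expect_equal(eps[[1]], c(20 * 200, 40 * 200))
  # all-quiet recording -> nothing
  expect_length(detect_scan_episode(square_artefact_rec(0), cfg), 0)
  # exactly at the 350 uV threshold -> NOT detected (strict inequality)
  expect_length(detect_scan_episode(square_artefact_rec(350), cfg), 0)
  expect_length(detect_scan_episode(square_artefact_rec(351), cfg), 1)
})

test_that("epoch onsets come from triggers or TR within an episode", {
  fs <- 5000
  rec <- recording(matrix(0, 1, 20 * fs), fs, channel_info("Fz"))
  rec <- add_events(rec, events_table("R128", seq(0, 9) * 2 * fs))
  cfg <- ga_config(tr_s = 2, trigger_label = "R128")
  expect_equal(epoch_onsets(rec, cfg), seq(0, 9) * 10000)
  # TR mode over an explicit [20, 40) s episode, TR 2 s -> 10 onsets
  rec2 <- recording(matrix(0, 1, 60 * 200), 200, channel_info("Fz"))
  cfg2 <- ga_config(tr_s = 2, auto_detect = FALSE)
  on <- epoch_onsets(rec2, cfg2, episode = c(20 * 200, 40 * 200))
  expect_length(on, 10)
  expect_equal(diff(on), rep(400, 9))
  # no triggers and no episode -> error
  expect_error(epoch_onsets(rec2, ga_config(tr_s = 2)),
               class = "fk_parameter_error")
  # jittered triggers warn about unsynchronized clocks
  rec3 <- add_events(recording(matrix(0, 1, 20 * fs), fs, channel_info("Fz")),
                     events_table("R128", c(0, 10000, 20007, 30000)))
  expect_warning(epoch_onsets(rec3, cfg), "synchronized")
})

test_that("AAS cancels a strictly periodic artefact exactly", {
  fs <- 500
  rec <- recording(matrix(0, 2, 50 * fs), fs, channel_info(c("Fz", "Cz")))
  inj <- inject_gradient_artefact(rec, tr_s = 2, episode_s = c(5, 45),
                                  seed = 3)
  cfg <- ga_config(tr_s = 2, trigger_label = "fmri_volume_trigger",
                   target_rate_hz = fs)
  out <- aas_correct(inj$recording, cfg)
  ep <- read_window(out, "Fz", 5 * fs, 40 * fs)
  expect_lt(max(abs(ep)), 1e-6)
  # samples outside the episode untouched
  expect_equal(read_window(out, "Fz", 0, 5 * fs),
               read_window(inj$recording, "Fz", 0, 5 * fs))
})

test_that("AAS recovers EEG under a large artefact (injection-recovery)", {
  fs <- 500
  t <- (seq_len(50 * fs) - 1) / fs
  clean <- 2 * sin(2 * pi * 10.13 * t)     # incommensurate with TR = 2 s
  rec <- recording(rbind(clean, clean), fs, channel_info(c("Fz", "Cz")))
  inj <- inject_gradient_artefact(rec, 2, episode_s = c(5, 45), seed = 4)
  out <- aas_correct(inj$recording,
                     ga_config(2, trigger_label = "fmri_volume_trigger",
                               target_rate_hz = fs))
  sel <- seq(6 * fs, 44 * fs)
  expect_gt(cor(read_window(out, "Fz")[1, sel], clean[sel]), 0.99)
})

test_that("defaults downsample 5 kHz input to 500 Hz and re-index events", {
  fs <- 5000
  rec <- gen_background(2, fs, 10, seed = 5)
  inj <- inject_gradient_artefact(rec, 0.5, episode_s = c(1, 9), seed = 5)
  cfg <- ga_config(0.5, trigger_label = "fmri_volume_trigger")
  out <- aas_correct(inj$recording, cfg)
  expect_equal(out$sampling_rate, 500)
  expect_equal(out$n_samples, 5000)
  trig <- out$events[out$events$label == "fmri_volume_trigger", ]
  expect_equal(trig$onset, inj$onsets / 10)
})

test_that("template averages exactly min(n_avg, n_epochs) epochs", {
  # probe with unique per-epoch delta patterns: the recovered template's
  # support counts the epochs given nonzero weight
  fs <- 500
  tr_len <- 250
  n_ep <- 100
  x <- numeric(n_ep * tr_len + fs)
  for (i in seq_len(n_ep)) x[(i - 1) * tr_len + i] <- 1
  rec <- recording(matrix(x, 1), fs, channel_info("Fz"))
  rec <- add_events(rec, events_table("trig", (seq_len(n_ep) - 1) * tr_len))
  cfg <- ga_config(0.5, trigger_label = "trig", target_rate_hz = fs)
  out <- aas_correct(rec, cfg)
  j <- 50
  epoch_before <- x[((j - 1) * tr_len + 1):(j * tr_len)]
  epoch_after <- read_window(out, "Fz", (j - 1) * tr_len, tr_len)[1, ]
  template <- epoch_before - epoch_after
  expect_equal(sum(abs(template) > 1e-9), 30)
  # edge epoch still uses exactly 30 (window clamped, not shrunk)
  e1_after <- read_window(out, "Fz", 0, tr_len)[1, ]
  t1 <- x[1:tr_len] - e1_after
  expect_equal(sum(abs(t1) > 1e-9), 30)
  # fewer epochs than the window: all of them
  rec6 <- recording(matrix(x[1:(6 * tr_len)], 1), fs, channel_info("Fz"))
  rec6 <- add_events(rec6, events_table("trig", (0:5) * tr_len))
  out6 <- aas_correct(rec6, cfg)
  t6 <- x[1:tr_len] - read_window(out6, "Fz", 0, tr_len)[1, ]
  expect_equal(sum(abs(t6) > 1e-9), 6)
})

test_that("correction is per-channel independent (permutation invariance)", {
  fs <- 250
  set.seed(9)
  base <- matrix(rnorm(3 * 20 * fs, sd = 10), 3)
  chans <- c("Fz", "Cz", "Pz")
  mk <- function(data, names) {
    r <- recording(data, fs, channel_info(names))
    inject_gradient_artefact(r, 1, episode_s = c(2, 18), seed = 6)$recording
  }
  cfg <- ga_config(1, trigger_label = "fmri_volume_trigger",
                   target_rate_hz = fs)
  out1 <- aas_correct(mk(base, chans), cfg)
  perm <- c(3, 1, 2)
  out2 <- aas_correct(mk(base[perm, ], chans[perm]), cfg)
  expect_equal(read_window(out2, chans), read_window(out1, chans))
})

test_that("artefact power at the scanner fundamental drops >= 30 dB", {
  fs <- 500
  rec <- gen_background(1, fs, 66, seed = 8)
  inj <- inject_gradient_artefact(rec, 2, episode_s = c(2, 62), seed = 8)
  out <- aas_correct(inj$recording,
                     ga_config(2, trigger_label = "fmri_volume_trigger",
                               target_rate_hz = fs))
  sel_psd <- function(r) {
    x <- read_window(r, "Fp1", 2 * fs, 60 * fs)[1, ]
    w <- welch_psd(x, fs, subwindow_s = 8)
    w$psd[which.min(abs(w$freq - 0.5))]
  }
  expect_gt(10 * log10(sel_psd(inj$recording) / sel_psd(out)), 30)
})
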