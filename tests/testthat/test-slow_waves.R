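test_that("episode extraction resolves whole / time / stage specs", {
  rec <- pattern_recording(2, 150 * 100, fs = 100)
  expect_equal(extract_episode(rec), list(c(0, 150 * 100)))
  expect_equal(extract_episode(rec, t0_s = 2, t1_s = 5),
               list(c(200, 500)))
  expect_error(extract_episode(rec, t0_s = 5, t1_s = 5),
               class = "fk_parameter_error")
  # hypnogram [2,3,3,2,4] at 30 s, stages {3,4} -> [30,90) and [120,150)
  ss <- scoreset("s", 30, 150, sampling_rate = 100)
  for (i in seq_along(c(2, 3, 3, 2, 4)))
    ss <- set_stage(ss, i - 1, c(2, 3, 3, 2, 4)[i])
  eps <- extract_episode(rec, ss, stages = c(3, 4))
  expect_equal(eps, list(c(30 * 100, 90 * 100), c(120 * 100, 150 * 100)))
  # no matching stage: empty list, not an error
  expect_equal(extract_episode(rec, ss, stages = 5), list())
})

test_that("ROI averages match a brute-force per-sample loop", {
  set.seed(20)
  chans <- c("Fz", "F3", "C3", "FC3", "Pz", "XX")
  rec <- recording(matrix(rnorm(6 * 200), 6), 100, channel_info(chans))
  roi_map <- list(front = c("Fz", "F3", "Missing1"), left = c("C3", "FC3"),
                  par = "Pz", other = "XX")
  avg <- roi_average(rec, roi_map)
  d <- read_window(rec)
  front_loop <- left_loop <- numeric(200)
  for (s in 1:200) {
    front_loop[s] <- mean(d[c("Fz", "F3"), s])
    left_loop[s] <- mean(d[c("C3", "FC3"), s])
  }
  expect_equal(unname(avg["front", ]), front_loop)
  expect_equal(unname(avg["left", ]), left_loop)
  # single-electrode ROI is that electrode
  expect_equal(unname(avg["par", ]), unname(d["Pz", ]))
  # opposite signs cancel
  rec2 <- recording(rbind(rep(10, 5), rep(-10, 5)), 100,
                    channel_info(c("C3", "C4")))
  expect_equal(unname(roi_average(rec2, list(c = c("C3", "C4")))["c", ]),
               rep(0, 5))
  expect_error(roi_average(rec, list(bad = "NotThere")),
               class = "fk_configuration_error")
})

canon <- function(fs = 500, sep = 0.5, neg = -100, pos = 60, lag = 0.4,
                  pad = 4) {
  p <- sw_pulse(fs, sep, neg, pos, lag)
  c(numeric(pad * fs), p$x, numeric(pad * fs))
}

test_that("detector accepts the canonical wave and measures it exactly", {
  fs <- 500
  w <- detect_sw(canon(fs), fs)
  expect_length(w, 1)
  w <- w[[1]]
  expect_equal(w$up_zx_s - w$down_zx_s, 0.5)
  expect_equal(w$neg_peak_uv, -100)
  expect_equal(w$p2p_uv, 160)
  expect_equal(w$pos_peak_s - w$up_zx_s, 0.4)
})

test_that("each criterion rejects boundary and sub-threshold waves", {
  fs <- 500
  # p2p exactly 140 (neg -100, pos 40): strict > rejects
  expect_length(detect_sw(canon(fs, pos = 40), fs), 0)
  expect_length(detect_sw(canon(fs, pos = 41), fs), 1)
  # separation 0.20 s below the 0.25 minimum
  expect_length(detect_sw(canon(fs, sep = 0.20), fs), 0)
  expect_length(detect_sw(canon(fs, sep = 0.25), fs), 1)
  expect_length(detect_sw(canon(fs, sep = 1.25), fs), 1)
  expect_length(detect_sw(canon(fs, sep = 1.30), fs), 0)
  # negative peak exactly -80 rejected (pos adjusted to keep p2p > 140)
  expect_length(detect_sw(canon(fs, neg = -80, pos = 160), fs), 0)
  expect_length(detect_sw(canon(fs, neg = -81, pos = 160), fs), 1)
  # positive peak beyond 2 s after the up crossing
  expect_length(detect_sw(canon(fs, lag = 2.0, pad = 6), fs), 1)
  expect_length(detect_sw(canon(fs, lag = 2.1, pad = 6), fs), 0)
})

test_that("slope criterion is relative to the episode's candidates", {
  fs <- 500
  mk <- function(scale) {
    p <- sw_pulse(fs, 0.5, -100, 100, 0.4)
    p$x * scale
  }
  episode <- function(r)
    c(numeric(2 * fs), mk(1), numeric(4 * fs), mk(r), numeric(2 * fs))
  # test wave at 85% of the reference slope: rejected; at 95%: accepted
  expect_length(detect_sw(episode(0.85), fs), 1)
  w <- detect_sw(episode(0.95), fs)
  expect_length(w, 2)
  # exactly 90% is rejected (strict >)
  expect_length(detect_sw(episode(0.90), fs), 1)
  expect_length(detect_sw(episode(0.91), fs), 2)
})

test_that("detector is sound and complete against the brute-force oracle", {
  fs <- 250
  set.seed(30)
  # low-amplitude background: the waves must clear each criterion by a
  # clean margin after the noise's own contribution to the measurements
  rec <- gen_background(1, fs, 120, seed = 30, rms_uv = 2)
  x <- bandpass(read_window(rec)[1, ], fs, 0.25, 4)
  # inject waves with >= 10% margins on every criterion, plus one clear
  # violator; analytic slopes pi*|neg|/sep are equalized across the
  # passing waves so the relative slope criterion holds for all of them
  specs <- list(
    list(time_s = 10, sep_s = 0.5, neg_uv = -120, pos_uv = 80, pos_lag_s = 0.4),
    list(time_s = 40, sep_s = 0.8, neg_uv = -192, pos_uv = 60, pos_lag_s = 0.5),
    list(time_s = 70, sep_s = 0.4, neg_uv = -96, pos_uv = 100, pos_lag_s = 0.3),
    list(time_s = 100, sep_s = 0.15, neg_uv = -120, pos_uv = 80, pos_lag_s = 0.3))
  for (s in specs) {
    p <- sw_pulse(fs, s$sep_s, s$neg_uv, s$pos_uv, s$pos_lag_s)
    i0 <- round(s$time_s * fs) - p$down_i
    x[i0 + seq_along(p$x)] <- x[i0 + seq_along(p$x)] + p$x
  }
  got <- detect_sw(x, fs)
  oracle <- bruteforce_sw(x, fs)
  # soundness: every emitted wave is in the oracle set
  for (w in got)
    expect_true(any(abs(oracle$neg_t - w$neg_peak_s) < 2 / fs))
  # completeness near the injected margin-passing waves
  for (s in specs[1:3])
    expect_true(any(vapply(got, function(w)
      abs(w$neg_peak_s - s$time_s) < 1.5, TRUE)))
  # the separation violator is absent
  expect_false(any(vapply(got, function(w)
    abs(w$neg_peak_s - 100) < 1.5, TRUE)))
})

test_that("trajectories recover injected per-electrode delays exactly", {
  fs <- 250
  chans <- c("Fz", "F3", "C3", "C4", "Pz")
  rec <- recording(matrix(0, 5, fs * 20), fs, channel_info(chans, "EEG"))
  delays <- setNames(c(0, 0.010, 0.020, 0.030, 0.040) + 0, chans)
  # delays as exact sample multiples at 250 Hz: 0.012, 0.024 ... use 4 ms grid
  delays <- setNames(c(0, 0.012, 0.020, 0.028, 0.040), chans)
  inj <- inject_slow_waves(rec, list(list(time_s = 10, delays = delays)))
  roi <- list(all = chans)
  sig <- roi_average(inj$recording, roi)["all", ]
  w <- detect_sw(sig, fs, sw_config(roi_map = roi))
  expect_length(w, 1)
  tr <- sw_trajectory(inj$recording, w[[1]], sw_config(roi_map = roi),
                      electrodes = chans)
  expect_equal(tr$origin_electrode, "Fz")
  expect_equal(tr$electrode_delays[chans], delays, tolerance = 1.01 / fs)
  # single-electrode participation gives a one-entry zero map
  rec1 <- recording(matrix(0, 1, fs * 20), fs, channel_info("Cz", "EEG"))
  inj1 <- inject_slow_waves(rec1, list(list(time_s = 10,
                                            delays = c(Cz = 0))))
  w1 <- detect_sw(read_window(inj1$recording)[1, ], fs)
  tr1 <- sw_trajectory(inj1$recording, w1[[1]], electrodes = "Cz")
  expect_equal(unname(tr1$electrode_delays), 0)
  expect_equal(names(tr1$electrode_delays), "Cz")
})

test_that("electrodes without a matching peak are excluded from the map", {
  fs <- 250
  chans <- c("Fz", "Cz", "Pz")
  rec <- recording(matrix(0, 3, fs * 20), fs, channel_info(chans, "EEG"))
  # Pz's wave arrives 0.5 s later: outside the +/-0.3 s match window
  inj <- inject_slow_waves(rec, list(
    list(time_s = 10, delays = c(Fz = 0, Cz = 0.02, Pz = 0.5))))
  roi <- list(front = c("Fz", "Cz"))
  sig <- roi_average(inj$recording, roi)["front", ]
  w <- detect_sw(sig, fs, sw_config(roi_map = roi))[[1]]
  tr <- sw_trajectory(inj$recording, w, electrodes = chans)
  expect_setequal(names(tr$electrode_delays), c("Fz", "Cz"))
})

test_that("cross-ROI duplicates merge into one wave", {
  mkwave <- function(t, neg, delays = NULL, origin = NULL) {
    w <- list(roi = "r", down_zx_s = t - 0.3, up_zx_s = t + 0.3,
              neg_peak_s = t, neg_peak_uv = neg, pos_peak_s = t + 0.6,
              pos_peak_uv = 60, p2p_uv = 60 - neg, max_slope_uv_per_s = 500)
    if (!is.null(delays)) {
      w$electrode_delays <- delays
      w$origin_time_s <- origin
      w$origin_electrode <- names(delays)[1]
    }
    structure(w, class = "fk_slow_wave")
  }
  # same physical wave seen by 2 ROIs 0.1 s apart -> one survivor
  a <- mkwave(10.0, -120, c(Fz = 0, Cz = 0.02), 10.0)
  b <- mkwave(10.1, -100, c(Pz = 0), 9.98)
  out <- dedupe_across_rois(list(a, b))
  expect_length(out, 1)
  expect_equal(out[[1]]$neg_peak_uv, -120)
  # unioned delays re-zeroed to the earliest electrode (Pz at 9.98)
  expect_equal(out[[1]]$origin_electrode, "Pz")
  expect_equal(unname(out[[1]]$electrode_delays["Fz"]), 0.02)
  # distant waves survive; empty input tolerated
  expect_length(dedupe_across_rois(list(mkwave(1, -90), mkwave(4, -90))), 2)
  expect_length(dedupe_across_rois(list()), 0)
})

test_that("full pipeline finds injected waves and writes events", {
  fs <- 250
  chans <- c("Fz", "F3", "C3", "FC3", "FC4", "C4", "Pz", "P3")
  rec <- gen_background(8, fs, 120, seed = 31, rms_uv = 5)
  rec <- recording(read_window(rec), fs, channel_info(chans, "EEG"))
  inj <- inject_slow_waves(rec, list(list(time_s = 20), list(time_s = 60),
                                     list(time_s = 90)))
  res <- find_slow_waves(inj$recording)
  expect_length(res$waves, 3)
  expect_equal(sum(res$recording$events$label == "slow_wave"), 3)
  times <- sort(vapply(res$waves, `[[`, 0, "neg_peak_s"))
  expect_equal(times, c(20, 60, 90) + 0.25, tolerance = 0.2)
  # export writes one row per wave plus a delay table
  out <- file.path(tempdir(), "waves.tsv")
  export_sw_table(res$waves, out, paste0(out, ".d"))
  expect_equal(nrow(utils::read.table(out, header = TRUE, sep = "\t")), 3)
})
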