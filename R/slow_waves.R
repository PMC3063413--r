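## Slow-wave detection and scalp trajectory extraction.
##
## Detection runs on signals averaged over four scalp regions of
## interest and applies five criteria to every candidate biphasic wave:
## (1) a negative (down) zero crossing followed by a positive (up) zero
## crossing separated by 0.25-1.25 s, (2) a negative peak below -80 uV
## between them, (3) negative-to-positive peak-to-peak amplitude above
## 140 uV, (4) maximum positive slope above 90% of the maximum slope
## among candidates in the episode, and (5) the positive peak at most
## 2 s after the up crossing. The wave's scalp trajectory is the map of
## per-electrode negative-peak delays relative to the first detecting
## electrode.

#' Slow-wave detection settings
#'
#' Amplitude criteria are strict inequalities exactly as printed
#' (< -80 uV, > 140 uV, > 90% of the maximum slope); range criteria are
#' inclusive. Comparisons carry a 1e-9 relative guard so waves sitting
#' exactly on a boundary behave as the printed inequality dictates under
#' floating-point arithmetic.
#'
#' @param roi_map named list of 4 electrode vectors (defaults: frontal,
#'   central left, central right, parietal neighbourhoods)
#' @param band_hz detection bandpass, Hz (default 0.25-4)
#' @param zx_separation_s accepted down-to-up zero-crossing separation
#'   range, seconds (default c(0.25, 1.25), inclusive)
#' @param neg_peak_uv negative-peak criterion, uV (default -80, strict <)
#' @param p2p_uv peak-to-peak criterion, uV (default 140, strict >)
#' @param slope_frac slope criterion as a fraction of the episode's
#'   maximum candidate slope (default 0.90, strict >)
#' @param pos_peak_max_lag_s maximum up-crossing-to-positive-peak lag,
#'   seconds (default 2, inclusive)
#' @param electrode_match_window_s half-width of the per-electrode
#'   negative-peak search window around the ROI peak (default 0.3 s)
#' @return list of class `fk_sw_config`
#' @export
sw_config <- function(roi_map = fastkit_defaults()$roi_map,
                      band_hz = c(0.25, 4.0),
                      zx_separation_s = c(0.25, 1.25),
                      neg_peak_uv = -80, p2p_uv = 140, slope_frac = 0.90,
                      pos_peak_max_lag_s = 2.0,
                      electrode_match_window_s = 0.3) {
  if (length(roi_map) < 1 || any(!vapply(roi_map, length, 1L)))
    fk_stop("fk_configuration_error", "roi_map entries must be nonempty")
  structure(list(roi_map = roi_map, band_hz = band_hz,
                 zx_separation_s = zx_separation_s, neg_peak_uv = neg_peak_uv,
                 p2p_uv = p2p_uv, slope_frac = slope_frac,
                 pos_peak_max_lag_s = pos_peak_max_lag_s,
                 electrode_match_window_s = electrode_match_window_s),
            class = "fk_sw_config")
}

EPS_REL <- 1e-9
EPS_T <- 1e-6   # seconds; absorbs sub-sample interpolation round-off

#' Resolve the episode(s) to analyze
#'
#' Either the whole recording, an explicit time window, or the maximal
#' runs of requested sleep stages from a score set.
#'
#' @param rec recording
#' @param scores optional score set (stage mode)
#' @param stages stage codes defining the episode (default deep sleep,
#'   3-4)
#' @param t0_s,t1_s explicit window, seconds
#' @return list of half-open c(start_sample, end_sample) intervals
#'   (possibly empty)
#' @export
extract_episode <- function(rec, scores = NULL, stages = c(3, 4),
                            t0_s = NULL, t1_s = NULL) {
  fs <- rec$sampling_rate
  if (!is.null(t0_s) || !is.null(t1_s)) {
    if (is.null(t0_s) || is.null(t1_s) || t1_s <= t0_s)
      fk_stop("fk_parameter_error", "need t1_s > t0_s")
    return(list(c(round(t0_s * fs), min(round(t1_s * fs), rec$n_samples))))
  }
  if (is.null(scores))
    return(list(c(0, rec$n_samples)))
  wl <- round(scores$window_length_s * fs)
  in_stage <- scores$stages %in% stages
  r <- rle(in_stage)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  lapply(keep, function(k)
    c((starts[k] - 1) * wl, min(ends[k] * wl, rec$n_samples)))
}

#' Average electrodes within scalp regions of interest
#'
#' Unweighted per-sample mean of each region's present member
#' electrodes; configured electrodes absent from the recording are
#' silently dropped (a region with no present electrode is an error).
#'
#' @param rec recording
#' @param roi_map named list of electrode vectors
#' @return regions x samples matrix, rownames = region names
#' @export
roi_average <- function(rec, roi_map = fastkit_defaults()$roi_map) {
  out <- matrix(0, length(roi_map), rec$n_samples,
                dimnames = list(names(roi_map), NULL))
  for (r in names(roi_map)) {
    present <- intersect(roi_map[[r]], rec$channels$name)
    if (!length(present))
      fk_stop("fk_configuration_error",
              "ROI '%s' has no electrode present in the recording", r)
    out[r, ] <- colMeans(read_window(rec, present))
  }
  out
}

## Zero-crossing times (seconds, sub-sample by linear interpolation; a
## sample exactly at zero is the crossing itself).
zero_crossings <- function(x, fs) {
  n <- length(x)
  i <- seq_len(n - 1)
  a <- x[i]; b <- x[i + 1]
  down_i <- which(a >= 0 & b < 0 & !(a == 0 & c(0, x)[i] <= 0))
  up_i <- which(a < 0 & b >= 0)
  t_down <- (down_i - 1 + ifelse(x[down_i] > 0,
                                 x[down_i] / (x[down_i] - x[down_i + 1]), 0)) / fs
  t_up <- (up_i - 1 + ifelse(x[up_i + 1] == 0, 1,
                             -x[up_i] / (x[up_i + 1] - x[up_i]))) / fs
  list(down = t_down, up = t_up)
}

#' Detect slow waves on one (ROI-averaged) signal
#'
#' Applies the five detection criteria to every down-to-up zero-crossing
#' pair of the signal, which must already be band-passed to the
#' configured detection band. The slope criterion's reference population
#' is the candidates passing criteria 1-3 within this same signal (one
#' episode, one region).
#'
#' @param roi_signal numeric vector, uV
#' @param fs sampling rate, Hz
#' @param cfg [sw_config()]
#' @param roi region name stamped on the output
#' @param time_offset_s added to all reported times (episode start)
#' @return list of `fk_slow_wave` objects in time order (possibly empty)
#' @export
detect_sw <- function(roi_signal, fs, cfg = sw_config(), roi = NA_character_,
                      time_offset_s = 0) {
  zc <- zero_crossings(roi_signal, fs)
  if (!length(zc$down)) return(list())
  n <- length(roi_signal)
  cand <- list()
  for (d in zc$down) {
    ups <- zc$up[zc$up > d]
    if (!length(ups)) next
    u <- ups[1]
    sep <- u - d
    if (sep < cfg$zx_separation_s[1] - EPS_T ||
        sep > cfg$zx_separation_s[2] + EPS_T) next        # criterion 1
    i0 <- max(1, ceiling(d * fs) + 1)
    i1 <- min(n, floor(u * fs) + 1)
    if (i1 <= i0) next
    neg_i <- i0 + which.min(roi_signal[i0:i1]) - 1
    neg_v <- roi_signal[neg_i]
    if (!(neg_v < cfg$neg_peak_uv * (1 + EPS_REL))) next  # criterion 2
    # positive phase: up crossing to next down crossing (or signal end)
    downs_after <- zc$down[zc$down > u]
    p1 <- if (length(downs_after)) min(n, floor(downs_after[1] * fs) + 1) else n
    p0 <- min(n, ceiling(u * fs) + 1)
    if (p1 <= p0) next
    pos_i <- p0 + which.max(roi_signal[p0:p1]) - 1
    pos_v <- roi_signal[pos_i]
    p2p <- pos_v - neg_v
    if (!(p2p > cfg$p2p_uv * (1 + EPS_REL))) next         # criterion 3
    seg <- roi_signal[neg_i:pos_i]
    slope <- if (length(seg) > 1) max(diff(seg)) * fs else 0
    cand[[length(cand) + 1]] <- list(
      roi = roi, down_zx_s = d, up_zx_s = u,
      neg_peak_s = (neg_i - 1) / fs, neg_peak_uv = neg_v,
      pos_peak_s = (pos_i - 1) / fs, pos_peak_uv = pos_v, p2p_uv = p2p,
      max_slope_uv_per_s = slope)
  }
  if (!length(cand)) return(list())
  max_slope <- max(vapply(cand, `[[`, 0, "max_slope_uv_per_s"))
  keep <- Filter(function(w) {
    w$max_slope_uv_per_s > cfg$slope_frac * max_slope * (1 + EPS_REL) &&  # criterion 4
      (w$pos_peak_s - w$up_zx_s) <= cfg$pos_peak_max_lag_s + EPS_T        # criterion 5
  }, cand)
  lapply(keep, function(w) {
    for (f in c("down_zx_s", "up_zx_s", "neg_peak_s", "pos_peak_s"))
      w[[f]] <- w[[f]] + time_offset_s
    structure(w, class = "fk_slow_wave")
  })
}

#' @export
print.fk_slow_wave <- function(x, ...) {
  cat(sprintf("<fk_slow_wave> %s @ %.2f s: neg %.1f uV, p2p %.1f uV, slope %.0f uV/s",
              x$roi, x$neg_peak_s, x$neg_peak_uv, x$p2p_uv,
              x$max_slope_uv_per_s))
  if (!is.null(x$electrode_delays))
    cat(sprintf(", origin %s, %d electrode(s)", x$origin_electrode,
                length(x$electrode_delays)))
  cat("\n")
  invisible(x)
}

#' Per-electrode trajectory of a detected slow wave
#'
#' An electrode participates in the wave when its own band-passed signal
#' shows a local negative peak below the negative-peak criterion within
#' +/- `electrode_match_window_s` of the region-average negative peak.
#' Each participating electrode's delay is its negative-peak time minus
#' the earliest participating electrode's; the earliest electrode is the
#' wave's origin.
#'
#' @param rec recording (electrode signals are band-passed internally)
#' @param wave a wave from [detect_sw()]
#' @param cfg [sw_config()]
#' @param electrodes electrode names to scan (default: all EEG channels)
#' @return the wave with `electrode_delays` (named, seconds, min 0),
#'   `origin_electrode` and `origin_time_s` filled in, or NULL when no
#'   electrode participates
#' @export
sw_trajectory <- function(rec, wave, cfg = sw_config(), electrodes = NULL) {
  if (is.null(electrodes))
    electrodes <- rec$channels$name[rec$channels$kind == "EEG"]
  fs <- rec$sampling_rate
  w <- cfg$electrode_match_window_s
  lo <- max(0, round((wave$neg_peak_s - w) * fs))
  hi <- min(rec$n_samples, round((wave$neg_peak_s + w) * fs) + 1)
  pad <- round(2 * fs)   # filter context around the window
  s0 <- max(0, lo - pad)
  s1 <- min(rec$n_samples, hi + pad)
  block <- read_window(rec, electrodes, s0, s1 - s0)
  block <- bandpass(block, fs, cfg$band_hz[1], cfg$band_hz[2])
  times <- setNames(rep(NA_real_, length(electrodes)), electrodes)
  for (k in seq_along(electrodes)) {
    x <- block[k, ]
    i0 <- lo - s0 + 1
    i1 <- hi - s0
    idx <- i0:i1
    idx <- idx[idx > 1 & idx < length(x)]
    mins <- idx[x[idx] < x[idx - 1] & x[idx] <= x[idx + 1] &
                  x[idx] < cfg$neg_peak_uv * (1 + EPS_REL)]
    if (length(mins)) {
      best <- mins[which.min(x[mins])]
      times[k] <- (s0 + best - 1) / fs
    }
  }
  times <- times[!is.na(times)]
  if (!length(times)) {
    fk_warn("slow wave at %.2f s: no participating electrode; dropped",
            wave$neg_peak_s)
    return(NULL)
  }
  t0 <- min(times)
  wave$electrode_delays <- times - t0
  wave$origin_electrode <- names(times)[which.min(times)]
  wave$origin_time_s <- t0
  wave
}

#' Merge duplicate detections across regions
#'
#' The four region streams can detect the same physical wave. Waves
#' whose negative peaks lie within 0.5 s of each other are merged,
#' keeping the most negative peak's measurements; electrode delay maps
#' are unioned (earliest peak per electrode) and re-zeroed to the new
#' minimum.
#'
#' @param waves time-sorted list of waves
#' @param merge_window_s merge radius, seconds (default 0.5)
#' @return deduplicated list of waves
#' @export
dedupe_across_rois <- function(waves, merge_window_s = 0.5) {
  if (!length(waves)) return(list())
  ord <- order(vapply(waves, `[[`, 0, "neg_peak_s"))
  waves <- waves[ord]
  out <- list()
  cluster <- list(waves[[1]])
  flush <- function(cluster) {
    best <- cluster[[which.min(vapply(cluster, `[[`, 0, "neg_peak_uv"))]]
    abs_times <- numeric()
    for (w in cluster) {
      if (is.null(w$electrode_delays)) next
      at <- w$electrode_delays + w$origin_time_s
      for (e in names(at))
        abs_times[e] <- if (e %in% names(abs_times))
          min(abs_times[e], at[e]) else at[e]
    }
    if (length(abs_times)) {
      t0 <- min(abs_times)
      best$electrode_delays <- abs_times - t0
      best$origin_electrode <- names(abs_times)[which.min(abs_times)]
      best$origin_time_s <- t0
    }
    best
  }
  for (w in waves[-1]) {
    if (w$neg_peak_s - cluster[[length(cluster)]]$neg_peak_s <= merge_window_s)
      cluster[[length(cluster) + 1]] <- w
    else {
      out[[length(out) + 1]] <- flush(cluster)
      cluster <- list(w)
    }
  }
  out[[length(out) + 1]] <- flush(cluster)
  out
}

#' Full slow-wave detection pipeline
#'
#' Resolves the episodes (whole file, explicit window, or sleep-stage
#' runs), averages the four regions of interest, band-passes, detects
#' waves per region and episode, extracts every wave's electrode
#' trajectory, merges duplicates across regions, and writes each wave
#' back as a `slow_wave` event for easy epoching.
#'
#' @param rec recording
#' @param cfg [sw_config()]
#' @param scores,stages,t0_s,t1_s episode specification, see
#'   [extract_episode()]
#' @return list(waves, recording) — the recording carries one
#'   `slow_wave` event per detected wave
#' @export
find_slow_waves <- function(rec, cfg = sw_config(), scores = NULL,
                            stages = c(3, 4), t0_s = NULL, t1_s = NULL) {
  fs <- rec$sampling_rate
  episodes <- extract_episode(rec, scores, stages, t0_s, t1_s)
  roi_sig <- roi_average(rec, cfg$roi_map)
  waves <- list()
  for (ep in episodes) {
    if (ep[2] - ep[1] < fs) next
    for (r in rownames(roi_sig)) {
      seg <- bandpass(roi_sig[r, (ep[1] + 1):ep[2]], fs,
                      cfg$band_hz[1], cfg$band_hz[2])
      waves <- c(waves, detect_sw(seg, fs, cfg, roi = r,
                                  time_offset_s = ep[1] / fs))
    }
  }
  waves <- Filter(Negate(is.null),
                  lapply(waves, function(w) sw_trajectory(rec, w, cfg)))
  waves <- dedupe_across_rois(waves)
  if (length(waves)) {
    ev <- events_table("slow_wave",
                       vapply(waves, function(w) round(w$neg_peak_s * fs), 0),
                       0, vapply(waves, `[[`, "", "roi"))
    rec <- add_events(rec, ev)
  }
  list(waves = waves, recording = rec)
}

#' Export a slow-wave table
#'
#' One row per wave (times, amplitudes, slope, origin electrode) plus,
#' optionally, a long-format electrode delay table.
#' @param waves list of waves
#' @param path TSV output path
#' @param delays_path optional TSV path for the long delay table
#' @export
export_sw_table <- function(waves, path, delays_path = NULL) {
  df <- do.call(rbind, lapply(waves, function(w)
    data.frame(roi = w$roi, down_zx_s = w$down_zx_s, up_zx_s = w$up_zx_s,
               neg_peak_s = w$neg_peak_s, neg_peak_uv = w$neg_peak_uv,
               pos_peak_s = w$pos_peak_s, pos_peak_uv = w$pos_peak_uv,
               p2p_uv = w$p2p_uv, max_slope_uv_per_s = w$max_slope_uv_per_s,
               origin_electrode = w$origin_electrode %||% NA_character_)))
  if (is.null(df)) df <- data.frame()
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(delays_path)) {
    dl <- do.call(rbind, lapply(seq_along(waves), function(i) {
      w <- waves[[i]]
      if (is.null(w$electrode_delays)) return(NULL)
      data.frame(wave = i, electrode = names(w$electrode_delays),
                 delay_s = as.numeric(w$electrode_delays))
    }))
    if (is.null(dl)) dl <- data.frame()
    utils::write.table(dl, delays_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
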