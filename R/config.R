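#' Lab defaults
#'
#' The editable defaults bundle: display scales per channel kind, bipolar
#' montage pairs for EOG/EMG, region-of-interest electrode lists for
#' slow-wave detection, and every method's default parameters. Site
#' overrides are merged from a JSON file with [load_config()].
#'
#' @return nested list of defaults
#' @export
fastkit_defaults <- function() {
  list(
    scales_uv = list(EEG = 75, EOG = 150, EMG = 100, ECG = 1000, OTHER = 100),
    bipolar_pairs = list(
      HEOG = c("EOG1", "EOG2"),
      VEOG = c("EOG3", "EOG4"),
      EMGb = c("EMG1", "EMG2")
    ),
    roi_map = list(
      frontal       = c("Fp1", "Fp2", "AF3", "AF4", "F3", "Fz", "F4"),
      central_left  = c("FC3", "C3", "CP3"),
      central_right = c("FC4", "C4", "CP4"),
      parietal      = c("P3", "Pz", "P4", "POz")
    ),
    ga = list(n_average_volumes = 30, detect_window_s = 1,
              detect_threshold_uv = 350, target_rate_hz = 500),
    pa = list(method = "combined", n_obs_components = 4, gm_window_beats = 21,
              gm_sigma_beats = 5, epoch_pre_frac = 0.25, epoch_post_frac = 0.75,
              split_hz = 4),
    spectral = list(window_s = 30, subwindow_s = 4, overlap_frac = 0.5,
                    deep_sleep_stages = c(3, 4)),
    sw = list(band_hz = c(0.25, 4.0), zx_separation_s = c(0.25, 1.25),
              neg_peak_uv = -80, p2p_uv = 140, slope_frac = 0.90,
              pos_peak_max_lag_s = 2.0, electrode_match_window_s = 0.3)
  )
}

#' Load site defaults from a JSON config file
#'
#' Values present in the file override the shipped defaults; everything
#' else is kept. Nesting mirrors [fastkit_defaults()].
#' @param path JSON file path, or NULL for shipped defaults
#' @return merged defaults list
#' @export
load_config <- function(path = NULL) {
  defaults <- fastkit_defaults()
  if (is.null(path)) return(defaults)
  if (!file.exists(path))
    fk_stop("fk_parameter_error", "config file not found: %s", path)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  modifyList(defaults, user)
}
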