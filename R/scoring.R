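## Sleep scoring: per-window stage codes, hypnograms, and sleep
## statistics between the FPL ("lights off") and OPL ("lights on")
## boundary markers. Stage codes follow the classical R&K convention:
## 0 wake, 1-4 NREM stages, 5 REM, 6 movement time, -1 unscored.

STAGE_CODES <- c(-1L, 0L, 1L, 2L, 3L, 4L, 5L, 6L)
SLEEP_STAGES <- 1:5

#' Create a score set
#'
#' One scorer's per-window staging of a recording: stage codes, artefact
#' flags, and optional FPL/OPL boundary markers. Several score sets (one
#' per scorer) can coexist on a recording.
#'
#' @param scorer_id scorer identifier string
#' @param window_length_s scoring window length, seconds (> 0)
#' @param duration_s scored recording duration, seconds; the set holds
#'   `ceiling(duration_s / window_length_s)` windows, all initially
#'   unscored (-1)
#' @param fpl_sample,opl_sample optional boundary markers, 0-based samples
#' @param sampling_rate sampling rate the boundary samples refer to
#' @return object of class `fk_scoreset`
#' @export
scoreset <- function(scorer_id, window_length_s, duration_s,
                     fpl_sample = NULL, opl_sample = NULL,
                     sampling_rate = NULL) {
  if (window_length_s <= 0)
    fk_stop("fk_parameter_error", "window_length_s must be > 0")
  n <- ceiling(duration_s / window_length_s)
  structure(
    list(scorer_id = scorer_id, window_length_s = window_length_s,
         stages = rep(-1L, n), artefact_flags = rep(FALSE, n),
         fpl_sample = fpl_sample, opl_sample = opl_sample,
         sampling_rate = sampling_rate, events = empty_events()),
    class = "fk_scoreset"
  )
}

#' @export
print.fk_scoreset <- function(x, ...) {
  cat(sprintf("<fk_scoreset> scorer '%s', %d windows of %g s (%d scored)\n",
              x$scorer_id, length(x$stages), x$window_length_s,
              sum(x$stages >= 0)))
  invisible(x)
}

#' Assign a stage code to a scoring window
#'
#' Pure update: returns a new score set. Valid codes are -1 (unscored),
#' 0 (wake), 1-4 (NREM), 5 (REM), 6 (movement time).
#' @param ss score set
#' @param window_index 0-based window index
#' @param code stage code
#' @return updated score set
#' @export
set_stage <- function(ss, window_index, code) {
  if (!all(code %in% STAGE_CODES))
    fk_stop("fk_parameter_error", "invalid stage code %s",
            paste(setdiff(code, STAGE_CODES), collapse = ","))
  if (any(window_index < 0) || any(window_index >= length(ss$stages)))
    fk_stop("fk_bounds_error", "window index out of range")
  ss$stages[window_index + 1L] <- as.integer(code)
  ss
}

#' Flag a scoring window as artefacted
#' @inheritParams set_stage
#' @param flag logical
#' @export
set_artefact <- function(ss, window_index, flag = TRUE) {
  if (any(window_index < 0) || any(window_index >= length(ss$stages)))
    fk_stop("fk_bounds_error", "window index out of range")
  ss$artefact_flags[window_index + 1L] <- flag
  ss
}

#' Hypnogram of a score set
#'
#' @param ss score set
#' @return data.frame with `window` (0-based), `time_s` (window start)
#'   and `stage` columns; unscored windows carry -1
#' @export
hypnogram <- function(ss) {
  n <- length(ss$stages)
  data.frame(window = seq_len(n) - 1L,
             time_s = (seq_len(n) - 1L) * ss$window_length_s,
             stage = ss$stages)
}

stage_names <- c(`0` = "wake", `1` = "stage1", `2` = "stage2",
                 `3` = "stage3", `4` = "stage4", `5` = "rem",
                 `6` = "movement")

#' Sleep statistics between the FPL and OPL markers
#'
#' Computed over scoring windows lying fully inside the half-open sample
#' interval `[fpl_sample, opl_sample)`: time in bed, total sleep time
#' (stages 1-5), sleep efficiency, sleep latency (first sleep-stage
#' window after FPL), REM latency (first REM window after sleep onset),
#' per-stage durations and percentages of TST, and the number of
#' awakenings (maximal wake runs after sleep onset). Latencies are NA
#' when undefined (e.g. a night without sleep).
#'
#' @param ss score set with both boundary markers and a sampling rate set
#' @return list of statistics (durations in seconds)
#' @export
sleep_statistics <- function(ss) {
  if (is.null(ss$fpl_sample))
    fk_stop("fk_parameter_error", "missing FPL (lights off) marker")
  if (is.null(ss$opl_sample))
    fk_stop("fk_parameter_error", "missing OPL (lights on) marker")
  if (is.null(ss$sampling_rate))
    fk_stop("fk_parameter_error", "scoreset has no sampling_rate")
  if (ss$fpl_sample >= ss$opl_sample)
    fk_stop("fk_parameter_error", "FPL must precede OPL")
  wl_samp <- ss$window_length_s * ss$sampling_rate
  n <- length(ss$stages)
  w_start <- (seq_len(n) - 1L) * wl_samp
  inside <- which(w_start >= ss$fpl_sample & w_start + wl_samp <= ss$opl_sample)
  st <- ss$stages[inside]
  wl <- ss$window_length_s

  time_in_bed <- length(inside) * wl
  is_sleep <- st %in% SLEEP_STAGES
  tst <- sum(is_sleep) * wl
  onset_idx <- if (any(is_sleep)) which(is_sleep)[1] else NA_integer_
  sleep_latency <- if (is.na(onset_idx)) NA_real_ else (onset_idx - 1) * wl
  rem_latency <- NA_real_
  if (!is.na(onset_idx)) {
    rem_after <- which(st == 5L & seq_along(st) >= onset_idx)
    if (length(rem_after)) rem_latency <- (rem_after[1] - onset_idx) * wl
  }
  per_stage <- sapply(names(stage_names), function(code)
    sum(st == as.integer(code)) * wl)
  names(per_stage) <- stage_names
  pct_tst <- if (tst > 0)
    100 * per_stage[stage_names[as.character(SLEEP_STAGES)]] / tst
  else setNames(rep(NA_real_, 5), stage_names[as.character(SLEEP_STAGES)])
  awakenings <- 0L
  if (!is.na(onset_idx)) {
    after <- st[onset_idx:length(st)]
    r <- rle(after == 0L)
    awakenings <- sum(r$values)
  }
  list(time_in_bed_s = time_in_bed, total_sleep_time_s = tst,
       sleep_efficiency = if (time_in_bed > 0) tst / time_in_bed else NA_real_,
       sleep_latency_s = sleep_latency, rem_latency_s = rem_latency,
       stage_duration_s = as.list(per_stage),
       stage_pct_tst = as.list(pct_tst), n_awakenings = awakenings)
}

#' Import / export scores as plain tabular files
#'
#' Tab-separated, one row per window: `window` (0-based), `stage`,
#' `artefact` (0/1). This is also the interchange path for externally
#' produced scores (e.g. automatic scorers).
#' @param ss score set
#' @param path file path
#' @export
export_scores <- function(ss, path) {
  df <- data.frame(window = seq_along(ss$stages) - 1L, stage = ss$stages,
                   artefact = as.integer(ss$artefact_flags))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname export_scores
#' @param scorer_id scorer id for the imported set
#' @param window_length_s scoring window length of the file
#' @param sampling_rate sampling rate the set will refer to
#' @return `import_scores()` returns a score set
#' @export
import_scores <- function(path, scorer_id, window_length_s, sampling_rate) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  ss <- scoreset(scorer_id, window_length_s,
                 nrow(df) * window_length_s, sampling_rate = sampling_rate)
  ss$stages <- as.integer(df$stage)
  if (!all(ss$stages %in% STAGE_CODES))
    fk_stop("fk_parameter_error", "invalid stage codes in %s", path)
  if ("artefact" %in% names(df))
    ss$artefact_flags <- df$artefact != 0
  ss
}

#' Attach a score set to a recording
#'
#' Score sets are keyed by scorer id; re-attaching with the same id
#' replaces that scorer's set.
#' @param rec recording
#' @param ss score set
#' @return recording
#' @export
add_scoreset <- function(rec, ss) {
  if (is.null(ss$sampling_rate)) ss$sampling_rate <- rec$sampling_rate
  ids <- vapply(rec$scores, function(s) s$scorer_id, "")
  if (ss$scorer_id %in% ids) rec$scores[[match(ss$scorer_id, ids)]] <- ss
  else rec$scores <- c(rec$scores, list(ss))
  rec
}

#' @export
get_scoreset <- function(rec, scorer_id) {
  ids <- vapply(rec$scores, function(s) s$scorer_id, "")
  i <- match(scorer_id, ids)
  if (is.na(i))
    fk_stop("fk_name_error", "no scores by '%s' (available: %s)", scorer_id,
            paste(ids, collapse = ", "))
  rec$scores[[i]]
}

serialize_scoreset <- function(ss) {
  list(scorer_id = ss$scorer_id, window_length_s = ss$window_length_s,
       stages = ss$stages, artefact_flags = ss$artefact_flags,
       fpl_sample = ss$fpl_sample, opl_sample = ss$opl_sample,
       sampling_rate = ss$sampling_rate)
}

deserialize_scores <- function(raw) {
  if (is.null(raw) || length(raw) == 0) return(list())
  if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
  opt <- function(v) if (is.null(v) || length(v) == 0 || is.na(v)) NULL else v
  lapply(raw, function(s) {
    ss <- scoreset(s$scorer_id, s$window_length_s,
                   length(unlist(s$stages)) * s$window_length_s,
                   fpl_sample = opt(s$fpl_sample),
                   opl_sample = opt(s$opl_sample),
                   sampling_rate = s$sampling_rate)
    ss$stages <- as.integer(unlist(s$stages))
    ss$artefact_flags <- as.logical(unlist(s$artefact_flags))
    ss
  })
}
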