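## Internal on-disk format: <basename>.json header + <basename>.bin raw
## samples (little-endian float32, channel-multiplexed frames). The header
## carries everything except samples, so header-only edits (events, scores,
## clock) never rewrite the binary.

FK_FORMAT <- "fastkit-1"

#' Write a recording in the internal header+binary format
#'
#' @param rec a [recording()]
#' @param basename output path without extension; writes `basename.json`
#'   and `basename.bin`
#' @param rewrite_binary set FALSE to only rewrite the header when the
#'   binary already exists and matches (header-only edit)
#' @return invisibly, c(header = ..., binary = ...) paths
#' @export
write_internal <- function(rec, basename, rewrite_binary = TRUE) {
  hdr_path <- paste0(basename, ".json")
  bin_path <- paste0(basename, ".bin")
  nch <- nrow(rec$channels)
  if (rewrite_binary) {
    con <- file(bin_path, "wb")
    # stream by bounded windows: the full signal is never materialized
    chunk <- max(1, floor(2^20 / max(nch, 1)))
    s <- 0
    while (s < rec$n_samples) {
      w <- min(chunk, rec$n_samples - s)
      block <- read_window(rec, rec$channels$name, s, w)
      writeBin(as.numeric(block), con, size = 4L, endian = "little")
      s <- s + w
    }
    close(con)
  }
  header <- list(
    format = FK_FORMAT,
    sampling_rate = rec$sampling_rate,
    n_samples = rec$n_samples,
    start_clock_time = format_clock_iso(rec$start_clock_time),
    channels = rec$channels,
    events = rec$events,
    scores = lapply(rec$scores, serialize_scoreset),
    history = rec$history,
    binary = list(path = basename(bin_path), dtype = "float32",
                  orientation = "MULTIPLEXED", byte_order = "little")
  )
  jsonlite::write_json(header, hdr_path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns")
  invisible(c(header = hdr_path, binary = bin_path))
}

#' Read a recording from the internal format
#'
#' Returns a file-backed recording: only the header is loaded, samples
#' are read window by window from the binary on demand.
#'
#' @param basename path without extension (or the `.json` path itself)
#' @return a [recording()]
#' @export
read_internal <- function(basename) {
  hdr_path <- if (grepl("\\.json$", basename)) basename
              else paste0(basename, ".json")
  if (!file.exists(hdr_path))
    fk_stop("fk_parameter_error", "header not found: %s", hdr_path)
  h <- jsonlite::read_json(hdr_path, simplifyVector = TRUE)
  if (!identical(h$format, FK_FORMAT))
    fk_stop("fk_integrity_error", "not an internal-format header: %s", hdr_path)
  bin_path <- file.path(dirname(hdr_path), h$binary$path)
  nch <- length(h$channels$name)
  expected <- as.numeric(h$n_samples) * nch * 4
  if (!file.exists(bin_path) || file.size(bin_path) != expected)
    fk_stop("fk_integrity_error",
            "binary %s has %s bytes, header implies %s", bin_path,
            if (file.exists(bin_path)) file.size(bin_path) else "no",
            format(expected, scientific = FALSE))
  channels <- as.data.frame(h$channels, stringsAsFactors = FALSE)
  events <- if (length(h$events) && length(h$events$label))
    as.data.frame(h$events, stringsAsFactors = FALSE) else empty_events()
  scores <- lapply(seq_along(h$scores$scorer_id %||% list()), function(i) NULL)
  scores <- deserialize_scores(h$scores)
  src <- list(type = "file", path = bin_path, dtype = "float32",
              orientation = "MULTIPLEXED", n_channels = nch,
              n_samples = as.numeric(h$n_samples), resolution = NULL)
  recording(src, h$sampling_rate, channels, events = events,
            start_clock_time = h$start_clock_time,
            scores = scores, history = as.character(h$history %||% character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Materialize a file-backed recording into memory (small recordings only;
## used by operations that must transform the whole signal).
materialize <- function(rec) {
  if (rec$source$type == "memory") return(rec)
  with_data(rec, read_window(rec))
}
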