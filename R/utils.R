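#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx fft rnorm runif spline median quantile sd var prcomp setNames
#' @importFrom utils modifyList head tail
NULL

fk_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "fastkit_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

fk_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Disk size of a raw continuous recording
#'
#' Convenience calculator for the storage footprint of an uncompressed
#' multichannel recording, e.g. a 72-channel, 4-hour, 5000 Hz EEG-fMRI
#' session stored as 2-byte integers occupies about 9.7 GiB.
#'
#' @param n_channels number of channels
#' @param duration_s recording duration in seconds
#' @param sampling_rate_hz sampling rate in Hz
#' @param bytes_per_sample storage bytes per sample (2 for INT16, 4 for
#'   IEEE float32)
#' @return `storage_bytes()` returns bytes; `storage_gib()` gibibytes.
#' @export
storage_bytes <- function(n_channels, duration_s, sampling_rate_hz,
                          bytes_per_sample = 2) {
  n_channels * duration_s * sampling_rate_hz * bytes_per_sample
}

#' @rdname storage_bytes
#' @export
storage_gib <- function(n_channels, duration_s, sampling_rate_hz,
                        bytes_per_sample = 2) {
  storage_bytes(n_channels, duration_s, sampling_rate_hz, bytes_per_sample) / 2^30
}

## Parse a BrainVision-style 20-digit timestamp (YYYYMMDDHHMMSSuuuuuu)
## into numeric seconds since the POSIX epoch (UTC), microsecond precision.
parse_bv_timestamp <- function(s) {
  s <- trimws(s)
  if (!grepl("^[0-9]{20}$", s)) return(NULL)
  base <- as.POSIXct(
    sprintf("%s-%s-%s %s:%s:%s",
            substr(s, 1, 4), substr(s, 5, 6), substr(s, 7, 8),
            substr(s, 9, 10), substr(s, 11, 12), substr(s, 13, 14)),
    tz = "UTC"
  )
  if (is.na(base)) return(NULL)
  as.numeric(base) + as.numeric(substr(s, 15, 20)) * 1e-6
}

## Numeric epoch seconds -> ISO-8601 string with microseconds (UTC).
format_clock_iso <- function(t) {
  if (is.null(t)) return(NULL)
  whole <- floor(t)
  us <- round((t - whole) * 1e6)
  if (us >= 1e6) { whole <- whole + 1; us <- 0 }
  sprintf("%s.%06dZ",
          format(as.POSIXct(whole, origin = "1970-01-01", tz = "UTC"),
                 "%Y-%m-%dT%H:%M:%S"),
          us)
}

parse_clock_iso <- function(s) {
  if (is.null(s) || is.na(s) || !nzchar(s)) return(NULL)
  m <- regmatches(s, regexec(
    "^(\\d{4}-\\d{2}-\\d{2})[T ](\\d{2}:\\d{2}:\\d{2})(?:\\.(\\d{1,6}))?Z?$", s))[[1]]
  if (length(m) == 0) return(NULL)
  base <- as.POSIXct(paste(m[2], m[3]), tz = "UTC")
  frac <- if (nzchar(m[4])) as.numeric(paste0("0.", m[4])) else 0
  as.numeric(base) + frac
}
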