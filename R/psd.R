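## Welch power spectral density estimation (Hamming taper, overlapping
## subwindows, one-sided density in uV^2/Hz).

hamming_window <- function(n) {
  if (n == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Welch power spectral density
#'
#' Averaged periodogram over overlapping tapered subwindows. The density
#' is one-sided and scaled so that `sum(psd) * df` approximates the
#' signal variance (Parseval).
#'
#' @param x numeric vector, microvolts
#' @param fs sampling rate, Hz
#' @param subwindow_s subwindow length in seconds
#' @param overlap_frac fractional overlap between subwindows in [0, 1)
#' @param demean subtract the subwindow mean before tapering
#' @return list(freq, psd) — frequencies in Hz, densities in uV^2/Hz
#' @export
welch_psd <- function(x, fs, subwindow_s = 4, overlap_frac = 0.5,
                      demean = TRUE) {
  nper <- round(subwindow_s * fs)
  if (nper < 2 || nper > length(x))
    fk_stop("fk_parameter_error",
            "subwindow of %g s does not fit signal of %d samples at %g Hz",
            subwindow_s, length(x), fs)
  step <- max(1, round(nper * (1 - overlap_frac)))
  starts <- seq(1, length(x) - nper + 1, by = step)
  w <- hamming_window(nper)
  u <- sum(w^2)
  nfreq <- floor(nper / 2) + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nper - 1)]
    if (demean) seg <- seg - mean(seg)
    sp <- abs(fft(w * seg)[seq_len(nfreq)])^2
    acc <- acc + sp
  }
  psd <- acc / (length(starts) * fs * u)
  # one-sided: double everything except DC (and Nyquist when nper even)
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (nper %% 2 == 0) dbl[nfreq] <- 1
  list(freq = seq(0, nfreq - 1) * fs / nper, psd = psd * dbl)
}

#' Power spectrum of one channel window
#'
#' Welch-averaged power spectral density of a channel over a sample
#' window of a recording.
#'
#' @param rec a [recording()]
#' @param channel channel name
#' @param start 0-based first sample (default 0)
#' @param length window length in samples (default to end)
#' @param subwindow_s Welch subwindow, seconds
#' @param overlap_frac Welch overlap fraction
#' @return list(freq, psd)
#' @export
compute_psd <- function(rec, channel, start = 0,
                        length = rec$n_samples - start,
                        subwindow_s = 4, overlap_frac = 0.5) {
  x <- read_window(rec, channel, start, length)[1, ]
  welch_psd(x, rec$sampling_rate, subwindow_s, overlap_frac)
}

## Integrated power in [band[1], band[2]] from a (freq, psd) pair.
band_integral <- function(freq, psd, band) {
  sel <- freq >= band[1] & freq <= band[2]
  if (!any(sel)) return(0)
  df <- if (length(freq) > 1) freq[2] - freq[1] else 1
  sum(psd[sel]) * df
}
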