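## Zero-phase Butterworth filtering.
##
## Filters are applied in the frequency domain with the squared magnitude
## response of an order-4 Butterworth design — the transfer function of a
## forward-backward (filtfilt) application, with exactly zero phase so
## artefact template and slow-wave peak latencies are never shifted.
## Mirror padding suppresses circular wrap-around at the edges. A pleasant
## consequence: low-pass and high-pass branches at the same cutoff are
## exactly amplitude-complementary (G_lp + G_hp = 1), which the combined
## pulse-artefact method relies on.

butter_order <- 4L

## Squared-magnitude (zero-phase) gain at frequencies f for one branch.
butter_gain <- function(f, cutoff_hz, type = c("low", "high"),
                        order = butter_order) {
  type <- match.arg(type)
  r <- (f / cutoff_hz)^(2L * order)
  if (type == "low") 1 / (1 + r) else r / (1 + r)
}

apply_fft_gain <- function(x, fs, gain_fun) {
  n <- length(x)
  if (n < 2) return(x)
  npad <- min(n - 1L, as.integer(round(3 * fs)))
  xp <- c(rev(x[seq_len(npad) + 1L]), x, rev(x[seq(n - npad, n - 1L)]))
  m <- length(xp)
  f <- seq(0, m - 1) / m * fs
  f <- pmin(f, fs - f)                       # two-sided -> folded frequency
  y <- Re(fft(fft(xp) * gain_fun(f), inverse = TRUE)) / m
  y[seq_len(n) + npad]
}

#' Zero-phase bandpass filter
#'
#' Order-4 Butterworth magnitude applied with exactly zero phase (the
#' forward-backward transfer function). `low_hz = 0` gives a pure
#' low-pass; `high_hz` at or above Nyquist gives a pure high-pass.
#'
#' @param block channels x samples matrix, or a numeric vector
#' @param sampling_rate Hz
#' @param low_hz lower band edge (>= 0)
#' @param high_hz upper band edge (<= Nyquist)
#' @return filtered block, same shape; length is preserved
#' @export
bandpass <- function(block, sampling_rate, low_hz, high_hz) {
  nyq <- sampling_rate / 2
  if (low_hz < 0 || high_hz <= low_hz || high_hz > nyq)
    fk_stop("fk_parameter_error",
            "invalid band [%g, %g] Hz at fs = %g Hz", low_hz, high_hz,
            sampling_rate)
  gain <- function(f) {
    g <- rep(1, length(f))
    if (high_hz < nyq) g <- g * butter_gain(f, high_hz, "low")
    if (low_hz > 0)    g <- g * butter_gain(f, low_hz, "high")
    g
  }
  filter_block(block, sampling_rate, gain)
}

#' Zero-phase low-pass / high-pass filters
#'
#' The two complementary branch filters used by the combined
#' pulse-artefact method: at every frequency the low and high gains sum
#' to exactly 1, and their magnitude responses cross at `cutoff_hz`.
#' @inheritParams bandpass
#' @param cutoff_hz branch cutoff in Hz
#' @return filtered block
#' @export
lowpass <- function(block, sampling_rate, cutoff_hz) {
  filter_block(block, sampling_rate,
               function(f) butter_gain(f, cutoff_hz, "low"))
}

#' @rdname lowpass
#' @export
highpass <- function(block, sampling_rate, cutoff_hz) {
  filter_block(block, sampling_rate,
               function(f) butter_gain(f, cutoff_hz, "high"))
}

filter_block <- function(block, fs, gain_fun) {
  if (is.matrix(block)) {
    out <- block
    for (i in seq_len(nrow(block)))
      out[i, ] <- apply_fft_gain(block[i, ], fs, gain_fun)
    out
  } else {
    apply_fft_gain(block, fs, gain_fun)
  }
}

#' Anti-aliased downsampling
#'
#' Zero-phase low-pass at `0.4 * target_rate` followed by decimation.
#' Integer ratios keep every M-th sample; non-integer ratios fall back to
#' linear interpolation onto the target grid with a warning.
#'
#' @param block channels x samples matrix or vector
#' @param sampling_rate input rate, Hz
#' @param target_rate output rate, Hz (<= sampling_rate)
#' @return list(data, rate, ratio) — ratio = sampling_rate / target_rate
#' @export
decimate <- function(block, sampling_rate, target_rate) {
  if (target_rate > sampling_rate)
    fk_stop("fk_parameter_error", "target rate above input rate")
  if (target_rate == sampling_rate)
    return(list(data = block, rate = sampling_rate, ratio = 1))
  filt <- lowpass(block, sampling_rate, 0.4 * target_rate)
  vec <- !is.matrix(filt)
  if (vec) filt <- matrix(filt, nrow = 1)
  ratio <- sampling_rate / target_rate
  if (abs(ratio - round(ratio)) < 1e-9) {
    ratio <- round(ratio)
    keep <- seq(1, ncol(filt), by = ratio)
    out <- filt[, keep, drop = FALSE]
  } else {
    fk_warn("sampling rate %g not an integer multiple of %g; resampling by interpolation",
            sampling_rate, target_rate)
    n_out <- floor(ncol(filt) * target_rate / sampling_rate)
    t_out <- (seq_len(n_out) - 1) / target_rate
    t_in <- (seq_len(ncol(filt)) - 1) / sampling_rate
    out <- matrix(0, nrow(filt), n_out)
    for (i in seq_len(nrow(filt)))
      out[i, ] <- approx(t_in, filt[i, ], xout = t_out, rule = 2)$y
  }
  if (vec) out <- out[1, ]
  list(data = out, rate = target_rate, ratio = ratio)
}
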