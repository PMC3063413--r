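#' Rereference a signal block
#'
#' On-display semantics: rereferencing is a pure transform of an
#' already-read block; the stored recording is never modified. For EEG
#' channels the reference may be any single channel, the mean of all EEG
#' channels, or the mean of the two mastoids (M1, M2). EOG/EMG channels
#' additionally support bipolar montages declared in the defaults config.
#'
#' @param block channels x samples matrix with rownames (as returned by
#'   [read_window()])
#' @param channel_infos channel table covering at least the block's rows
#' @param mode one of `"none"`, `"single_channel"`, `"mean_eeg"`,
#'   `"mastoids"`, `"bipolar"`
#' @param ref_channel reference channel name (single_channel mode)
#' @param mastoids names of the two mastoid channels
#' @param config defaults list ([fastkit_defaults()]), used for bipolar
#'   pairs
#' @return rereferenced block, same shape; in bipolar mode channels
#'   without a declared pair are returned unchanged
#' @export
rereference <- function(block, channel_infos,
                        mode = c("none", "single_channel", "mean_eeg",
                                 "mastoids", "bipolar"),
                        ref_channel = NULL, mastoids = c("M1", "M2"),
                        config = fastkit_defaults()) {
  mode <- match.arg(mode)
  if (mode == "none") return(block)
  nm <- rownames(block)
  info <- channel_infos[match(nm, channel_infos$name), ]
  if (anyNA(info$name))
    fk_stop("fk_name_error", "block rows missing from channel table")

  if (mode == "single_channel") {
    if (is.null(ref_channel) || !(ref_channel %in% nm))
      fk_stop("fk_configuration_error",
              "single_channel reference requires a channel present in the block")
    ref <- block[ref_channel, ]
    out <- sweep(block, 2, ref, "-")
    return(out)
  }
  if (mode == "mean_eeg") {
    eeg <- which(info$kind == "EEG")
    if (length(eeg) == 0)
      fk_stop("fk_configuration_error", "no EEG channels present for mean_eeg")
    ref <- colMeans(block[eeg, , drop = FALSE])
    out <- block
    out[eeg, ] <- sweep(block[eeg, , drop = FALSE], 2, ref, "-")
    return(out)
  }
  if (mode == "mastoids") {
    if (!all(mastoids %in% nm))
      fk_stop("fk_configuration_error",
              "mastoids mode needs both %s present", paste(mastoids, collapse = ", "))
    ref <- colMeans(block[mastoids, , drop = FALSE])
    eeg <- which(info$kind == "EEG")
    out <- block
    out[eeg, ] <- sweep(block[eeg, , drop = FALSE], 2, ref, "-")
    return(out)
  }
  # bipolar: only for declared EOG/EMG pairs
  out <- block
  for (pair in config$bipolar_pairs) {
    a <- pair[1]; b <- pair[2]
    if (a %in% nm && b %in% nm) {
      ka <- info$kind[match(a, nm)]
      if (ka %in% c("EOG", "EMG"))
        out[a, ] <- block[a, ] - block[b, ]
    }
  }
  out
}
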