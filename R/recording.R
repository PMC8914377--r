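#' The 19-electrode montage and its lobe map
#'
#' `eeg_channels()` returns the 19 electrode labels of the international
#' 10-20 layout used throughout the package. `eeg_lobe_map()` returns the
#' electrode-to-lobe assignment: FP (frontopolar, 2 electrodes), F (frontal,
#' 5), C (central, 3), T (temporal, 4), P (parietal, 3), O (occipital, 2).
#' The total cortex region TC averages all 19 electrodes directly (not the
#' 6 lobe means, which would weight small lobes up).
#'
#' @return `eeg_channels()`: character vector of length 19.
#'   `eeg_lobe_map()`: named list of character vectors.
#' @examples
#' lengths(eeg_lobe_map())
#' @export
eeg_channels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
    "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' @rdname eeg_channels
#' @export
eeg_lobe_map <- function() {
  list(
    FP = c("Fp1", "Fp2"),
    F  = c("F7", "F3", "Fz", "F4", "F8"),
    C  = c("C3", "Cz", "C4"),
    T  = c("T3", "T4", "T5", "T6"),
    P  = c("P3", "Pz", "P4"),
    O  = c("O1", "O2"))
}

#' A synchronized multichannel recording
#'
#' Container for one subject-phase block of synchronized signals: a channels
#' x samples matrix with sampling rate, channel labels and session metadata.
#' EEG channels are in microvolts, the ECG channel in millivolts; the
#' canonical acquisition rates are 1,024 Hz (hardware) and 256 Hz (analysis).
#'
#' @param signals numeric matrix, channels x samples.
#' @param fs sampling rate in Hz, > 0.
#' @param channels character vector of channel labels, one per row.
#' @param phase `"pre"` or `"post"`.
#' @param subject subject identifier.
#' @param condition condition label.
#' @return An object of class `session_recording`.
#' @export
session_recording <- function(signals, fs, channels,
                              phase = c("pre", "post"),
                              subject = NA_character_,
                              condition = NA_character_) {
  phase <- match.arg(phase)
  if (!is.matrix(signals)) signals <- matrix(signals, nrow = 1L)
  if (nrow(signals) != length(channels))
    abort("`channels` must label every row of `signals`.")
  if (fs <= 0) abort("`fs` must be > 0.")
  eeg <- setdiff(channels, "ECG")
  bad <- setdiff(eeg, eeg_channels())
  if (length(bad))
    abort(sprintf("unknown EEG channel label(s): %s (valid: %s, ECG)",
                  paste(bad, collapse = ", "),
                  paste(eeg_channels(), collapse = ", ")))
  structure(
    list(signals = signals, fs = fs, channels = as.character(channels),
         phase = phase, subject = as.character(subject),
         condition = as.character(condition)),
    class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf(
    "<session_recording> subject %s, condition %s, phase %s\n  %d channels x %d samples @ %g Hz (%.1f s)\n",
    x$subject, x$condition, x$phase, nrow(x$signals), ncol(x$signals),
    x$fs, ncol(x$signals) / x$fs))
  invisible(x)
}
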