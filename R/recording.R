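#' Multichannel EEG recording
#'
#' A channels-by-samples voltage matrix with its sampling rate and 10/20
#' channel labels. This is the common container every preprocessing step
#' consumes and returns.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_names unique channel labels, one per row of `data`.
#'   Defaults to the 21-electrode 10/20 montage for 21-row matrices and to
#'   `ch01, ch02, ...` otherwise.
#' @param subject_id subject label.
#' @return object of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(4 * 512), 4), fs = 256)
#' @export
eeg_recording <- function(data, fs, channel_names = NULL, subject_id = "anon") {
  if (!is.matrix(data) || !is.numeric(data))
    abort_field("data", "must be a numeric channels x samples matrix")
  if (nrow(data) < 2)
    abort_field("data", "needs >= 2 channels")
  if (any(!is.finite(data)))
    abort_field("data", "contains non-finite samples")
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
    abort_field("fs", "must be a positive sampling rate in Hz")
  if (is.null(channel_names)) {
    channel_names <- if (nrow(data) == 21) montage_1020()
                     else sprintf("ch%02d", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data))
    abort_field("channel_names", "length must equal the number of channels")
  if (anyDuplicated(channel_names))
    abort_field("channel_names", "must be unique")
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 subject_id = subject_id),
            class = "eeg_recording")
}

#' Standard 21-electrode 10/20 montage labels
#'
#' @return character vector of 21 channel names.
#' @export
montage_1020 <- function() {
  c("Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "Oz", "O2")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}
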