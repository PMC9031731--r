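#' Re-reference a recording to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the channel mean is zero at each sample. The operation is idempotent and
#' removes any common-mode offset. GFP/GFS are computed on average-referenced
#' data, matching how clinical qEEG exports are referenced.
#'
#' @param rec an [eeg_recording()].
#' @return the re-referenced [eeg_recording()].
#' @export
apply_average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2)
    stop("average reference undefined for a single-channel recording",
         call. = FALSE)
  rec$data <- sweep(rec$data, 2, colMeans(rec$data), "-")
  rec
}

#' Cut a recording into screened 2-second epochs
#'
#' Splits the recording into consecutive non-overlapping windows of
#' `epoch_length` seconds and drops any window that (a) contains a sample
#' exceeding `threshold_uv` in absolute value ("amplitude") or (b) has a
#' zero-variance channel ("flat"). This deterministic screen is a stand-in
#' for clinical visual artifact rejection and ICA ocular cleaning; it is not
#' equivalent to the clinical procedure and is documented as such.
#'
#' @param rec an [eeg_recording()].
#' @param threshold_uv rejection threshold in microvolts (default 100).
#' @param epoch_length epoch duration in seconds (default 2).
#' @return object of class `epoch_set` with fields `data`
#'   (epochs x channels x samples), `fs`, `epoch_length`, `channel_names`,
#'   `kept_epoch_indices` and `rejection_log` (data frame of dropped epochs
#'   with reason codes).
#' @export
epoch_and_screen <- function(rec, threshold_uv = 100, epoch_length = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(threshold_uv) || length(threshold_uv) != 1 || threshold_uv <= 0)
    abort_field("threshold_uv", "must be a positive voltage")
  len <- round(epoch_length * rec$fs)
  if (ncol(rec$data) < len)
    stop(sprintf("recording shorter than one %g-s epoch", epoch_length),
         call. = FALSE)
  n_ep <- floor(ncol(rec$data) / len)
  keep <- logical(n_ep)
  reason <- character(n_ep)
  dat <- array(NA_real_, dim = c(n_ep, nrow(rec$data), len))
  for (e in seq_len(n_ep)) {
    win <- rec$data[, ((e - 1) * len + 1):(e * len), drop = FALSE]
    dat[e, , ] <- win
    if (max(abs(win)) > threshold_uv) {
      reason[e] <- "amplitude"
    } else if (any(apply(win, 1, stats::var) == 0)) {
      reason[e] <- "flat"
    } else {
      keep[e] <- TRUE
    }
  }
  if (!any(keep))
    stop("no analyzable data: all epochs rejected by the artifact screen",
         call. = FALSE)
  structure(list(
    data = dat[keep, , , drop = FALSE],
    fs = rec$fs,
    epoch_length = epoch_length,
    channel_names = rec$channel_names,
    subject_id = rec$subject_id,
    kept_epoch_indices = which(keep),
    rejection_log = data.frame(epoch = which(!keep),
                               reason = reason[!keep],
                               stringsAsFactors = FALSE)
  ), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %s: %d kept epochs (%g s) x %d channels, %d rejected\n",
              x$subject_id, dim(x$data)[1], x$epoch_length, dim(x$data)[2],
              nrow(x$rejection_log)))
  invisible(x)
}

#' Complex spectra of screened epochs
#'
#' Discrete Fourier transform of every kept epoch and channel, scaled to the
#' one-sided sinusoid-amplitude convention: a unit-amplitude sinusoid centred
#' on a frequency bin yields amplitude 1.0 (in the signal's units) at that
#' bin. Interior bins are scaled by 2/N, the DC bin by 1/N and the Nyquist
#' bin by sqrt(2)/N so that, with the default rectangular taper, the Parseval
#' identity `sum_k |c_k|^2 / 2 == var_pop(x)` holds exactly over the non-DC
#' bins. A Hann taper (amplitude-corrected by its coherent gain) is available
#' for leakage-sensitive use; Parseval then holds only approximately.
#'
#' @param epochs an `epoch_set` from [epoch_and_screen()].
#' @param taper `"none"` (rectangular, default) or `"hann"`.
#' @return object of class `epoch_spectra` with complex `coeffs`
#'   (epochs x channels x bins), `freqs` (0 to fs/2, 1/epoch_length Hz apart)
#'   and bookkeeping fields.
#' @export
spectra <- function(epochs, taper = c("none", "hann")) {
  stopifnot(inherits(epochs, "epoch_set"))
  taper <- match.arg(taper)
  n_ep <- dim(epochs$data)[1]
  n_ch <- dim(epochs$data)[2]
  n <- dim(epochs$data)[3]
  if (n_ep < 1) stop("no kept epochs", call. = FALSE)
  n_bins <- n %/% 2 + 1
  freqs <- seq(0, epochs$fs / 2, length.out = n_bins)
  scale <- c(1, rep(2, n_bins - 2), sqrt(2)) / n
  w <- if (taper == "hann") {
    h <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
    h / mean(h)  # coherent-gain correction keeps tone amplitudes ~ exact
  } else rep(1, n)
  coeffs <- array(0i, dim = c(n_ep, n_ch, n_bins))
  for (e in seq_len(n_ep)) {
    x <- t(epochs$data[e, , , drop = TRUE] * rep(w, each = n_ch))  # samples x channels
    X <- stats::mvfft(x)[seq_len(n_bins), , drop = FALSE]
    coeffs[e, , ] <- t(X * scale)
  }
  structure(list(coeffs = coeffs, freqs = freqs,
                 bin_width = 1 / epochs$epoch_length, fs = epochs$fs,
                 channel_names = epochs$channel_names,
                 subject_id = epochs$subject_id, taper = taper,
                 n_epochs = n_ep), class = "epoch_spectra")
}

#' @export
print.epoch_spectra <- function(x, ...) {
  cat(sprintf("<epoch_spectra> %s: %d epochs x %d channels x %d bins (0-%g Hz, %g Hz grid, %s taper)\n",
              x$subject_id, dim(x$coeffs)[1], dim(x$coeffs)[2], dim(x$coeffs)[3],
              max(x$freqs), x$bin_width, x$taper))
  invisible(x)
}
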