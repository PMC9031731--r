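# Minimal EDF (European Data Format) writer/reader for continuous
# recordings, plus a raw binary fixture format with a JSON sidecar. EDF
# stores 16-bit integers with per-signal physical/digital scaling; this
# implementation writes one data record per second and truncates a trailing
# partial second. No annotations, no EDF+.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording as an EDF file
#'
#' Physical scaling is symmetric around 0 and spans the data range; start
#' date/time are fixed placeholders so re-exports of identical data are
#' byte-identical.
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- nrow(rec$data)
  spr <- as.integer(round(rec$fs))  # samples per 1-s record
  if (abs(rec$fs - spr) > 1e-9)
    abort_field("fs", "EDF export requires an integer sampling rate")
  n_rec <- floor(ncol(rec$data) / spr)
  if (n_rec < 1) abort_field("data", "shorter than one 1-s EDF record")
  phys_max <- max(1e-6, max(abs(rec$data)))
  dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_pad(x, width), con, width, eos = NULL)
  wr("0", 8)
  wr(rec$subject_id, 80)
  wr("qeegsync export", 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(256 * (1 + ns), 8)
  wr("", 44)
  wr(n_rec, 8)
  wr("1", 8)
  wr(ns, 4)
  for (nm in rec$channel_names) wr(paste("EEG", nm), 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(sprintf("%.6g", -phys_max), 8)
  for (i in seq_len(ns)) wr(sprintf("%.6g", phys_max), 8)
  for (i in seq_len(ns)) wr(-dig_max, 8)
  for (i in seq_len(ns)) wr(dig_max, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(spr, 8)
  for (i in seq_len(ns)) wr("", 32)
  scale <- dig_max / phys_max
  for (r in seq_len(n_rec)) {
    block <- rec$data[, ((r - 1) * spr + 1):(r * spr), drop = FALSE]
    dig <- as.integer(round(t(block) * scale))  # channel-major blocks
    writeBin(as.vector(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Supports continuous EDF with identical per-signal sampling rates (the
#' layout [write_edf()] produces and the common clinical export).
#'
#' @param path EDF file path.
#' @param channels optional channel-name subset (10/20 labels; matched
#'   against the EDF label with any `"EEG "` prefix stripped).
#' @return an [eeg_recording()].
#' @export
read_edf <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  ver <- rd(8)
  subject <- rd(80)
  rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  labels <- sub("^EEG ", "", labels)
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1)
    stop("mixed per-signal sampling rates are not supported", call. = FALSE)
  fs <- spr[1] / rec_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  data <- matrix(NA_real_, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2,
                   endian = "little")
    block <- matrix(raw, nrow = spr[1], ncol = ns)  # samples x channels
    data[, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
      t(block) * gain + offset
  }
  if (!is.null(channels)) {
    miss <- setdiff(channels, labels)
    if (length(miss))
      abort_field("channels", paste("not in file:", paste(miss, collapse = ", ")))
    data <- data[match(channels, labels), , drop = FALSE]
    labels <- channels
  }
  eeg_recording(data, fs, channel_names = labels, subject_id = subject)
}

#' Write a recording as a raw binary fixture with a JSON sidecar
#'
#' `<stem>.dat` holds channel-major float64 little-endian samples;
#' `<stem>.json` records dimensions, sampling rate, channel names, subject
#' id and the storage layout.
#'
#' @param rec an [eeg_recording()].
#' @param stem output path without extension.
#' @return the sidecar path, invisibly.
#' @export
write_fixture <- function(rec, stem) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(paste0(stem, ".dat"), "wb")
  writeBin(as.vector(rec$data), con, size = 8, endian = "little")
  close(con)
  meta <- list(format = "qeegsync-fixture-v1", n_channels = nrow(rec$data),
               n_samples = ncol(rec$data), fs = rec$fs,
               channel_names = rec$channel_names,
               subject_id = rec$subject_id,
               dtype = "float64le", order = "channel_major")
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paste0(stem, ".json"))
}

#' Read a raw binary fixture written by [write_fixture()]
#'
#' @param stem path without extension (or the `.json` sidecar path).
#' @return an [eeg_recording()].
#' @export
read_fixture <- function(stem) {
  stem <- sub("\\.json$", "", stem)
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "qeegsync-fixture-v1"))
    stop("not a qeegsync fixture sidecar: ", stem, ".json", call. = FALSE)
  con <- file(paste0(stem, ".dat"), "rb")
  x <- readBin(con, "numeric", n = meta$n_channels * meta$n_samples,
               size = 8, endian = "little")
  close(con)
  eeg_recording(matrix(x, nrow = meta$n_channels), meta$fs,
                channel_names = meta$channel_names,
                subject_id = meta$subject_id)
}
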