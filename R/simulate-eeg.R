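#' Specification for synthetic multichannel EEG
#'
#' Parameterizes a 10/20-style eyes-closed resting EEG generator in which
#' each frequency band carries (a) one band-limited waveform shared by all
#' channels — a globally phase-locked component whose strength is the RMS
#' amplitude `common_amp` — and (b) independent band-limited noise per
#' channel of RMS amplitude `noise_amp`, on top of per-channel 1/f ("pink")
#' background activity. The common-to-independent power ratio
#' `common_amp^2 / noise_amp^2` is the dial that sets the true global field
#' synchronization in a band, which is what makes the generator a ground
#' truth for the GFS estimator.
#'
#' Defaults emulate a 21-channel eyes-closed recording: alpha-dominant
#' spectrum, 256 Hz sampling, 300 s duration (a deliberately shorter default
#' than a full 15-20 min clinical session; pass `duration = 900` for a
#' session-length record).
#'
#' @param n_channels number of channels (default 21).
#' @param fs sampling rate in Hz (default 256); must be at least twice the
#'   highest band edge.
#' @param duration recording length in seconds (default 300).
#' @param bands named list of [band_spec()]s (default [default_bands()]).
#' @param common_amp per-band RMS amplitude (microvolts) of the common,
#'   globally phase-locked source; named by band.
#' @param noise_amp per-band RMS amplitude (microvolts) of the independent
#'   per-channel noise; named by band.
#' @param bg_exponent spectral exponent of the 1/f background (default 1).
#' @param bg_amp RMS amplitude (microvolts) of the background per channel
#'   (default 2).
#' @param channel_gains per-channel gains applied to the common source: the
#'   source's scalp topography. Default `NULL` draws a random unit-RMS
#'   standard-normal topography per recording; mixed signs emulate the
#'   dipolar projection of a cortical source, and the near-zero channel mean
#'   lets the common component survive average referencing (a constant
#'   topography would be common-mode and vanish under it). GFS is invariant
#'   to any real per-channel gains on the common source.
#' @param channel_names optional channel labels.
#' @param subject_id subject label.
#' @param seed optional RNG seed; a fixed seed reproduces the recording
#'   exactly.
#' @return object of class `eeg_sim_spec`.
#' @export
eeg_sim_spec <- function(n_channels = 21, fs = 256, duration = 300,
                         bands = default_bands(),
                         common_amp = c(delta = 1.5, theta = 1, alpha = 3,
                                        beta = 0.5),
                         noise_amp = c(delta = 1.5, theta = 1.2, alpha = 2,
                                       beta = 1),
                         bg_exponent = 1, bg_amp = 2,
                         channel_gains = NULL,
                         channel_names = NULL, subject_id = "sim",
                         seed = NULL) {
  if (!is.numeric(n_channels) || n_channels < 2)
    abort_field("n_channels", "must be >= 2")
  band_names <- vapply(bands, `[[`, character(1), "name")
  f_max <- max(vapply(bands, `[[`, numeric(1), "f_hi"))
  if (!is.numeric(fs) || fs < 2 * f_max)
    abort_field("fs", sprintf("must be >= twice the highest band edge (%g Hz)",
                              f_max))
  if (!is.numeric(duration) || duration <= 0)
    abort_field("duration", "must be a positive number of seconds")
  common_amp <- resolve_band_amp(common_amp, band_names, "common_amp")
  noise_amp <- resolve_band_amp(noise_amp, band_names, "noise_amp")
  if (!is.numeric(bg_amp) || bg_amp < 0)
    abort_field("bg_amp", "must be >= 0")
  if (!is.numeric(bg_exponent) || bg_exponent < 0)
    abort_field("bg_exponent", "must be >= 0")
  if (!is.null(channel_gains) && length(channel_gains) != n_channels)
    abort_field("channel_gains", "length must equal n_channels")
  structure(list(n_channels = as.integer(n_channels), fs = fs,
                 duration = duration, bands = bands,
                 common_amp = common_amp, noise_amp = noise_amp,
                 bg_exponent = bg_exponent, bg_amp = bg_amp,
                 channel_gains = channel_gains,
                 channel_names = channel_names, subject_id = subject_id,
                 seed = seed), class = "eeg_sim_spec")
}

resolve_band_amp <- function(amp, band_names, field) {
  if (length(amp) == 1 && is.null(names(amp)))
    amp <- stats::setNames(rep(amp, length(band_names)), band_names)
  if (is.null(names(amp)) && length(amp) == length(band_names))
    names(amp) <- band_names
  if (!all(band_names %in% names(amp)))
    abort_field(field, "must name an amplitude for every band")
  amp <- amp[band_names]
  if (any(!is.finite(amp)) || any(amp < 0))
    abort_field(field, "amplitudes must be finite and >= 0")
  amp
}

# Band-limited Gaussian noise: white noise through a 4th-order Butterworth
# bandpass applied forward and backward (zero phase), edge-padded, scaled to
# unit RMS.
bandlimited_noise <- function(n, fs, f_lo, f_hi, pad = 4 * fs) {
  bf <- signal::butter(4, c(f_lo, f_hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n + 2 * pad))
  x <- x[(pad + 1):(pad + n)]
  x / rms(x)
}

# 1/f^alpha background via spectral shaping of white noise, unit RMS.
pink_noise <- function(n, exponent) {
  W <- stats::fft(stats::rnorm(n))
  f <- c(1, seq_len(n - 1))  # DC handled separately
  f <- pmin(f, n - f + 1)    # symmetric axis keeps the signal real
  W <- W * f^(-exponent / 2)
  W[1] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x / rms(x)
}

#' Simulate a multichannel EEG recording
#'
#' Channel k is built as
#' `g_k * sum_b c_b s_b(t) + sum_b u_b n_kb(t) + bg_amp p_k(t)`,
#' where `s_b` is one band-limited waveform shared by all channels (common
#' phase), `n_kb` are independent band-limited noises, `p_k` is per-channel
#' 1/f background and `g_k` are per-channel gains. Exactly reproducible for
#' a fixed `seed`.
#'
#' @param spec an [eeg_sim_spec()].
#' @return an [eeg_recording()].
#' @examples
#' rec <- simulate_eeg(eeg_sim_spec(duration = 10, seed = 1))
#' @export
simulate_eeg <- function(spec) {
  stopifnot(inherits(spec, "eeg_sim_spec"))
  with_seed(spec$seed, {
    n <- round(spec$fs * spec$duration)
    K <- spec$n_channels
    gains <- if (!is.null(spec$channel_gains)) {
      spec$channel_gains
    } else {
      g <- stats::rnorm(K)
      g / rms(g)  # random dipolar topography, unit RMS
    }
    common <- numeric(n)
    for (b in spec$bands) {
      s <- bandlimited_noise(n, spec$fs, b$f_lo, b$f_hi)
      common <- common + spec$common_amp[[b$name]] * s
    }
    x <- outer(gains, common)  # K x n
    for (b in spec$bands) {
      u <- spec$noise_amp[[b$name]]
      if (u > 0) {
        for (k in seq_len(K))
          x[k, ] <- x[k, ] + u * bandlimited_noise(n, spec$fs, b$f_lo, b$f_hi)
      }
    }
    if (spec$bg_amp > 0) {
      for (k in seq_len(K))
        x[k, ] <- x[k, ] + spec$bg_amp * pink_noise(n, spec$bg_exponent)
    }
    eeg_recording(x, spec$fs, channel_names = spec$channel_names,
                  subject_id = spec$subject_id)
  })
}
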