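# Shared fixtures, all generated in code.

# Short synthetic recording with a known per-band synchronization dial.
# A flat per-band amplitude profile keeps cross-band spectral leakage from
# dominating low-power bands, so every band sees the same nominal
# common-to-independent power ratio.
quick_sim <- function(ratio, duration = 30, seed = 1, bg_amp = 2,
                      n_channels = 21, fs = 256) {
  flat <- c(delta = 1, theta = 1, alpha = 1, beta = 1)
  simulate_eeg(eeg_sim_spec(
    n_channels = n_channels, fs = fs, duration = duration,
    common_amp = sqrt(ratio) * flat, noise_amp = flat,
    bg_amp = bg_amp, seed = seed))
}

# Per-band GFP/GFS features of a recording, preprocessed the standard way.
quick_features <- function(rec, threshold_uv = Inf, ...) {
  rec <- apply_average_reference(rec)
  features_for_subject(spectra(epoch_and_screen(rec, threshold_uv)), ...)
}

# Recording whose channels are pure sinusoids: amplitude `amps[k]`,
# frequency `freq`, phase `phases[k]` on channel k.
tone_recording <- function(amps, freq, phases = NULL, fs = 256,
                           duration = 2) {
  k <- length(amps)
  if (is.null(phases)) phases <- rep(0, k)
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  data <- t(sapply(seq_len(k), function(i)
    amps[i] * sin(2 * pi * freq * t + phases[i])))
  eeg_recording(data, fs, subject_id = "tone")
}

# Perfectly separable two-class data: disjoint supports on one feature.
separable_cohort <- function(n_per = 30, seed = 42) {
  set.seed(seed)
  data.frame(
    group = factor(rep(c("a", "b"), each = n_per)),
    signal = c(runif(n_per, 0, 1), runif(n_per, 2, 3)),
    other = rnorm(2 * n_per),
    noise = rnorm(2 * n_per))
}

rf_predictor_names <- c(
  "age", "sex", "education", "mmse",
  "csf_abeta42", "csf_ptau", "csf_ttau", "csf_ng",
  "gfp_delta", "gfp_theta", "gfp_alpha", "gfp_beta",
  "gfs_delta", "gfs_theta", "gfs_alpha", "gfs_beta")

ref_stats <- function(variable, group) {
  ref <- mci_reference_summaries()
  r <- ref[ref$variable == variable & ref$group == group, ]
  summary_stats(r$mean, r$sd, r$n)
}
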