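#' Global field power at one frequency
#'
#' Root mean square of the spectral amplitudes across channels at one
#' frequency bin: `sqrt(mean(|c_k|^2))`. A reference-free scalar summary of
#' generalized EEG signal strength, in the amplitude units of the spectra
#' (microvolts under this package's scaling).
#'
#' @param coeffs complex vector, one Fourier coefficient per channel.
#' @return non-negative scalar, in microvolts.
#' @export
gfp_at_freq <- function(coeffs) {
  if (length(coeffs) < 2)
    abort_field("coeffs", "needs >= 2 channels")
  sqrt(mean(Mod(coeffs)^2))
}

#' Global field synchronization at one frequency
#'
#' Measures how much of the multichannel activity at one frequency can be
#' explained by a single common phase. The per-channel complex Fourier
#' coefficients are taken as a K x 2 cloud of (Re, Im) points; with
#' eigenvalues `l1 >= l2` of the 2 x 2 origin-anchored scatter matrix
#' `M'M`, GFS is `(l1 - l2) / (l1 + l2)`. The value is 1 when all channels
#' share one phase (collinear cloud), 0 for a perfectly isotropic cloud, and
#' is invariant to multiplying all coefficients by any nonzero complex
#' scalar. Computed with the closed-form 2 x 2 eigenvalue difference
#' `sqrt(tr^2 - 4 det) / tr`.
#'
#' The default keeps the scatter matrix anchored at the origin, preserving
#' the "common phase through the origin" reading and the GFS = 1 identity
#' for gain-scaled common sources; `center = TRUE` mean-centers the cloud
#' first (a sensitivity-analysis variant, not the default definition).
#'
#' @param coeffs complex vector, one Fourier coefficient per channel.
#' @param center logical; mean-center the (Re, Im) cloud before the
#'   eigendecomposition (default `FALSE`).
#' @return scalar in \[0, 1\].
#' @export
gfs_at_freq <- function(coeffs, center = FALSE) {
  if (length(coeffs) < 2)
    abort_field("coeffs", "needs >= 2 channels")
  M <- cbind(Re(coeffs), Im(coeffs))
  if (center) M <- sweep(M, 2, colMeans(M), "-")
  gfs_from_scatter(crossprod(M))
}

# GFS from a 2x2 scatter matrix via the closed-form eigenvalue difference.
gfs_from_scatter <- function(S) {
  tr <- S[1, 1] + S[2, 2]
  if (tr <= 0)
    stop("GFS undefined at silent frequency (all coefficients zero)",
         call. = FALSE)
  det <- S[1, 1] * S[2, 2] - S[1, 2]^2
  d <- tr^2 - 4 * det
  min(1, sqrt(max(d, 0)) / tr)
}

#' Monte-Carlo chance level of GFS for independent channels
#'
#' GFS is positively biased for finite channel counts: even fully
#' independent channels yield a nonzero expected value. This oracle
#' estimates the chance level by drawing random coefficient vectors and
#' computing GFS numerically per draw. `amplitude = "rayleigh"` draws
#' complex Gaussian coefficients (the distribution of filtered-noise Fourier
#' coefficients); `"unit"` places all channels on the unit circle with
#' uniform random phases. `reference = "average"` subtracts the channel-mean
#' coefficient per draw, matching data that were average-referenced before
#' the spectral transform (re-referencing couples the channels and raises
#' the chance level slightly).
#'
#' @param n_channels number of independent channels.
#' @param n_draws number of Monte-Carlo draws (default 2000).
#' @param amplitude `"rayleigh"` (default) or `"unit"`.
#' @param reference `"none"` (default) or `"average"`.
#' @param seed optional RNG seed.
#' @return list with `mean`, `sd`, `se` and the vector of `draws`.
#' @export
gfs_chance <- function(n_channels, n_draws = 2000,
                       amplitude = c("rayleigh", "unit"),
                       reference = c("none", "average"), seed = NULL) {
  amplitude <- match.arg(amplitude)
  reference <- match.arg(reference)
  stopifnot(n_channels >= 2, n_draws >= 2)
  with_seed(seed, {
    draws <- vapply(seq_len(n_draws), function(i) {
      z <- if (amplitude == "rayleigh")
        complex(real = stats::rnorm(n_channels),
                imaginary = stats::rnorm(n_channels))
      else
        exp(2i * pi * stats::runif(n_channels))
      if (reference == "average") z <- z - mean(z)
      gfs_at_freq(z)
    }, numeric(1))
    list(mean = mean(draws), sd = stats::sd(draws),
         se = stats::sd(draws) / sqrt(n_draws), draws = draws)
  })
}

#' Per-band GFP and GFS features for one subject
#'
#' Computes GFP and GFS at every non-DC frequency bin of every epoch,
#' averages across epochs, then averages within each frequency band. This
#' per-epoch-then-average order matches how qEEG measures are averaged
#' within subjects; `gfs_mode = "pooled"` instead sums the per-epoch scatter
#' eigenvalue pairs before forming the ratio, i.e. a total-power-weighted
#' average of per-epoch GFS (the per-epoch eigendecomposition is kept
#' because the common phase is only coherent within an epoch).
#'
#' @param spec an `epoch_spectra` from [spectra()].
#' @param bands list of [band_spec()]s (default [default_bands()]).
#' @param gfs_mode `"per_epoch"` (default) or `"pooled"`.
#' @param center passed to [gfs_at_freq()].
#' @return object of class `qeeg_features` with `gfp_by_freq`, `gfs_by_freq`,
#'   `freqs`, named `gfp_band` and `gfs_band` vectors and `n_epochs_used`.
#' @export
features_for_subject <- function(spec, bands = default_bands(),
                                 gfs_mode = c("per_epoch", "pooled"),
                                 center = FALSE) {
  stopifnot(inherits(spec, "epoch_spectra"))
  gfs_mode <- match.arg(gfs_mode)
  n_ep <- dim(spec$coeffs)[1]
  sel <- which(spec$freqs > 0)  # DC bin excluded from all band math
  freqs <- spec$freqs[sel]
  nf <- length(sel)
  gfp_e <- matrix(NA_real_, n_ep, nf)
  gfs_e <- matrix(NA_real_, n_ep, nf)
  for (e in seq_len(n_ep)) {
    for (i in seq_len(nf)) {
      z <- spec$coeffs[e, , sel[i]]
      gfp_e[e, i] <- gfp_at_freq(z)
      if (gfs_mode == "per_epoch") gfs_e[e, i] <- gfs_at_freq(z, center = center)
    }
  }
  gfp <- colMeans(gfp_e)
  gfs <- if (gfs_mode == "per_epoch") {
    colMeans(gfs_e)
  } else {
    vapply(seq_len(nf), function(i) {
      l1 <- 0
      l2 <- 0
      for (e in seq_len(n_ep)) {
        z <- spec$coeffs[e, , sel[i]]
        M <- cbind(Re(z), Im(z))
        if (center) M <- sweep(M, 2, colMeans(M), "-")
        S <- crossprod(M)
        tr <- S[1, 1] + S[2, 2]
        det <- S[1, 1] * S[2, 2] - S[1, 2]^2
        half_diff <- sqrt(max(tr^2 - 4 * det, 0)) / 2
        l1 <- l1 + tr / 2 + half_diff
        l2 <- l2 + tr / 2 - half_diff
      }
      if (l1 + l2 <= 0)
        stop("GFS undefined at silent frequency (all coefficients zero)",
             call. = FALSE)
      min(1, (l1 - l2) / (l1 + l2))
    }, numeric(1))
  }
  band_names <- vapply(bands, `[[`, character(1), "name")
  gfp_band <- vapply(bands, function(b) band_average(gfp, freqs, b), numeric(1))
  gfs_band <- vapply(bands, function(b) band_average(gfs, freqs, b), numeric(1))
  names(gfp_band) <- names(gfs_band) <- band_names
  structure(list(gfp_by_freq = gfp, gfs_by_freq = gfs, freqs = freqs,
                 gfp_band = gfp_band, gfs_band = gfs_band,
                 n_epochs_used = n_ep, bands = bands,
                 subject_id = spec$subject_id), class = "qeeg_features")
}

#' @export
print.qeeg_features <- function(x, ...) {
  cat(sprintf("<qeeg_features> %s (%d epochs)\n", x$subject_id, x$n_epochs_used))
  print(round(rbind(GFP = x$gfp_band, GFS = x$gfs_band), 4))
  invisible(x)
}
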