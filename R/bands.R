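#' Frequency band specification
#'
#' A named frequency interval on the spectral axis. The conventional
#' resting-state bands used throughout the package are delta (1-3.5 Hz),
#' theta (4-7.5 Hz), alpha (8-11.5 Hz) and beta (12-19.5 Hz); beta is capped
#' below 20 Hz because higher frequencies in clinical scalp EEG are commonly
#' contaminated with muscle activity. Gamma is deliberately not analysed.
#'
#' @param name band label.
#' @param f_lo,f_hi lower and upper band edge in Hz, `0 < f_lo < f_hi`.
#' @return an object of class `band_spec`.
#' @examples
#' band_spec("alpha", 8, 11.5)
#' @export
band_spec <- function(name, f_lo, f_hi) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    abort_field("name", "must be a non-empty string")
  if (!is.numeric(f_lo) || length(f_lo) != 1 || !is.finite(f_lo) || f_lo <= 0)
    abort_field("f_lo", "must be a positive finite number")
  if (!is.numeric(f_hi) || length(f_hi) != 1 || !is.finite(f_hi) || f_hi <= f_lo)
    abort_field("f_hi", "must be finite and greater than f_lo")
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi), class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %s: %g-%g Hz\n", x$name, x$f_lo, x$f_hi))
  invisible(x)
}

#' Default frequency bands
#'
#' @return named list of four [band_spec()] objects (delta, theta, alpha,
#'   beta).
#' @export
default_bands <- function() {
  list(delta = band_spec("delta", 1, 3.5),
       theta = band_spec("theta", 4, 7.5),
       alpha = band_spec("alpha", 8, 11.5),
       beta  = band_spec("beta", 12, 19.5))
}

#' Average a spectral curve over a frequency band
#'
#' Unweighted mean over all frequency bins with `f_lo <= f <= f_hi`
#' (endpoints inclusive). On the 0.5 Hz grid of 2-second epochs the delta
#' band therefore averages exactly the six bins 1.0, 1.5, ..., 3.5 Hz.
#'
#' @param values numeric vector of per-bin values.
#' @param freqs numeric vector of bin frequencies in Hz, same length.
#' @param band a [band_spec()].
#' @return scalar band average.
#' @export
band_average <- function(values, freqs, band) {
  stopifnot(inherits(band, "band_spec"))
  if (length(values) != length(freqs))
    abort_field("values", "length must match `freqs`")
  sel <- freqs >= band$f_lo & freqs <= band$f_hi
  if (!any(sel))
    stop(sprintf("band '%s' [%g, %g] Hz contains no frequency bins",
                 band$name, band$f_lo, band$f_hi), call. = FALSE)
  mean(values[sel])
}
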