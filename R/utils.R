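# Internal helpers shared across modules.

# Validation failure that names the offending field.
abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream. `seed = NULL` leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

#' Derive a stage-level child seed from a global seed
#'
#' A single pipeline seed is fanned out to per-stage seeds with a fixed
#' multiplicative congruential step (Lehmer constants, modulus 2^31 - 1), so
#' any stage can be re-run in isolation with a reproducible stream.
#'
#' @param seed integer global seed.
#' @param stage integer stage index (>= 1).
#' @return an integer seed in [1, 2^31 - 2].
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed),
            is.numeric(stage), length(stage) == 1, stage >= 1)
  m <- 2147483647
  s <- (abs(seed) %% m) + 1
  for (i in seq_len(stage)) s <- (48271 * s) %% m
  as.integer(s)
}

rms <- function(x) sqrt(mean(x^2))
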