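#' Derive a child seed for a named random stream
#'
#' All randomness in the synthetic-data generators flows from a single
#' user-supplied seed. Independent streams (one per channel, per fixture,
#' per profile, ...) are derived deterministically from that seed and a
#' stream label, so that fixtures are bit-reproducible across platforms and
#' adding a new stream never perturbs existing ones.
#'
#' The child seed is `(seed + djb2(label)) mod (2^31 - 1)`, where `djb2` is
#' the Bernstein string hash computed modulo `2^31 - 1`. The result always
#' fits in a 32-bit signed integer.
#'
#' @param seed Integer master seed.
#' @param stream Character label naming the stream, e.g. `"sideview/CH3"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' split_seed(1, "sideview/CH1")
split_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(stream), length(stream) == 1L)
  m <- 2147483647
  h <- 5381
  for (code in utf8ToInt(stream)) h <- (h * 33 + code) %% m
  as.integer((abs(seed) %% m + h) %% m)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the R random seed, evaluates `expr`, and restores the caller's RNG
#' state on exit, so package functions never disturb user-level randomness.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}
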