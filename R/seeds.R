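#' Derive a child seed from a master seed
#'
#' All stochastic stages draw their own seed from the run's master seed plus a
#' sequence of integer indices (participant, condition, purpose, iteration,
#' ...), so that streams are reproducible and mutually independent without any
#' stage sharing the global RNG state.
#'
#' The scheme is a multiplicative congruential mix modulo the Mersenne prime
#' 2^31 - 1: starting from `master mod (2^31 - 1)`, each index `k` updates
#' `s <- (s * 69069 + k + 1) mod (2^31 - 1)`. All intermediate products stay
#' below 2^53, so the arithmetic is exact in double precision.
#'
#' @param master Integer master seed.
#' @param ... Integer indices identifying the stream (coerced with
#'   `as.integer`); character values are hashed by their bytes.
#' @return A single integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' derive_seed(42, 3, 1)      # participant 3, condition 1
#' derive_seed(42, "decode", 7)
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647
  s <- as.numeric(master) %% m
  idx <- list(...)
  for (x in idx) {
    if (is.character(x)) x <- utf8ToInt(paste(x, collapse = "")) else x <- as.numeric(x)
    for (k in x) {
      s <- (s * 69069 + k + 1) %% m
    }
  }
  # one extra scramble so short index lists do not collide with master + n
  s <- (s * 69069 + 1) %% m
  as.integer(if (s == 0) 1 else s)
}

# run code with a local RNG stream without touching the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
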