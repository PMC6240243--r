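#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic stages draw their randomness from a single master seed via
#' this counter-based derivation, so that sub-generators can be re-run
#' independently and reproducibly.
#'
#' @param seed integer master seed.
#' @param counter non-negative integer stream index.
#' @return an integer seed < 2^31.
#' @export
derive_seed <- function(seed, counter = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(counter))
  m <- 2147483647 # 2^31 - 1 (Mersenne prime, Lehmer modulus)
  s <- (abs(as.numeric(seed)) %% m)
  for (i in seq_len(counter + 1L)) {
    s <- (s * 48271 + 11) %% m
  }
  as.integer(s)
}

local_seed <- function(seed, code) {
  # evaluate `code` under set.seed(seed), restoring the caller's RNG state
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
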