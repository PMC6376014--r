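#' Derive a reproducible sub-seed for a named stage
#'
#' All randomness in a pipeline flows from one root seed. Each stage
#' (production sampling, conversion, reconstruction, each repetition, ...)
#' draws from its own stream, seeded by `derive_seed(root, stage)`, so stages
#' are independently reproducible and no stage reads global RNG state left
#' behind by another.
#'
#' The derivation is a multiplicative-congruential mix of the root seed with a
#' polynomial hash of the stage name, reduced modulo 2^31 - 1 (always a valid
#' 32-bit R seed).
#'
#' @param seed Integer root seed.
#' @param stage Character scalar naming the stage.
#' @return An integer in `[1, 2^31 - 1]`.
#' @export
#' @examples
#' derive_seed(1, "production")
#' derive_seed(1, "reconstruction")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage),
            length(stage) == 1)
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% m
  # seed %% m <= 2^31; * 48271 <= 1.04e14 < 2^53: exact in doubles
  s <- ((abs(seed) %% m) * 48271 + h) %% (m - 1)
  as.integer(s) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
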