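#' Derive a reproducible child seed for a named pipeline stage
#'
#' A single user-facing seed is fanned out to per-stage streams by hashing the
#' stage name into an offset. Deterministic, stage-order independent, and the
#' result always fits a 32-bit signed integer.
#'
#' @param seed integer master seed.
#' @param stage character scalar naming the stage (e.g. "genome",
#'   "reads:egc1").
#' @return An integer seed in [0, 2^31 - 2].
#' @export
deriveSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (v in utf8ToInt(stage)) h <- (h * 131 + v) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
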