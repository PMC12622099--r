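#' Derive a stage seed from a master seed
#'
#' Every stochastic stage of a run (jitter for the mutual-information
#' estimator, fold assignment, undersampling, the synthetic generator)
#' draws its own seed from one master seed through this splitter, so any
#' stage can be reproduced in isolation and no two stages share a random
#' stream. The splitter hashes the stage labels with a multiplicative
#' polynomial hash modulo 2^31 - 1.
#'
#' @param master integer master seed of the run.
#' @param ... stage labels (characters or integers) identifying the stage,
#'   e.g. `stage_seed(42, "folds", 3)`.
#' @return an integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' stage_seed(42, "mi", "age") != stage_seed(42, "mi", "labels")
stage_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  m <- 2147483647 # 2^31 - 1, prime
  h <- (abs(as.numeric(master)) %% m)
  for (part in list(...)) {
    for (ch in utf8ToInt(paste0(as.character(part), "|"))) {
      h <- (h * 131 + ch) %% m
    }
  }
  as.integer(h %% (m - 2) + 1)
}

# run `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
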