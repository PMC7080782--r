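#' Derive a stage sub-seed from a top-level seed
#'
#' Stages of the pipeline (read sampling, permutation tests, random-pair
#' nulls) each receive their own seed so that re-running a single stage
#' reproduces its output without replaying the whole pipeline. The rule is
#' `(seed * 1009 + index) mod (2^31 - 1)`, documented so results can be
#' reproduced outside [run_pipeline()].
#'
#' @param seed integer top-level seed.
#' @param index non-negative integer stage index.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
sub_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), is.numeric(index))
  as.integer((as.double(seed) * 1009 + as.double(index)) %% 2147483647)
}

# run code under a temporary RNG state without disturbing the caller's
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# lower-triangle vector of a square matrix, column-major (dist order)
lower_tri <- function(m) m[lower.tri(m)]

`%||%` <- rlang::`%||%`
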