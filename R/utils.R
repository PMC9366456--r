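#' Derive a stream of child seeds from one master seed
#'
#' All stochastic operations in the package take a single integer seed and,
#' when they need several independent random streams (one per simulated
#' matrix, one per replicate), derive child seeds with this fixed rule:
#' seed the R generator with the master seed and draw `n` integers uniformly
#' from 1..(2^31 - 2).  The rule is part of the package's reproducibility
#' contract: identical master seed and `n` always yield identical children.
#'
#' @param master integer master seed.
#' @param n number of child seeds to derive.
#' @return integer vector of length `n`.
#' @export
split_seed <- function(master, n) {
  master <- as.integer(master)  # force before snapshotting the RNG state
  stopifnot(length(master) == 1L, !is.na(master),
            is.numeric(n), length(n) == 1L, n >= 0)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

## run code under a temporary RNG state, restoring the caller's stream;
## the seed promise is forced *before* the snapshot so callers may draw it
## from the ambient stream
with_seed <- function(seed, code) {
  seed <- as.integer(seed)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## the four body-size categories, smallest to largest
#' @export
SIZE_CATEGORIES <- c("small", "medium", "large", "very_large")
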