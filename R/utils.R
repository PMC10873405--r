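#' @importFrom stats rnorm rbinom runif median cor sd quantile var predict
#'   coef setNames complete.cases
#' @importFrom methods new validObject is slot
NULL

#' Derive reproducible sub-seeds from one master seed
#'
#' Draws `n` integer seeds from a generator initialised at `seed`, restoring
#' the caller's RNG state afterwards. Used so that one seed per repetition
#' drives covariates, effect sizes and noise through independent substreams.
#'
#' @param seed integer master seed.
#' @param n number of sub-seeds to derive.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
deriveSeeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(n), n >= 1L)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

## run expr under a local RNG stream, restoring caller state
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## order by decreasing score, ties broken by lower index
orderDesc <- function(score) order(-score, seq_along(score))

## equal-frequency discretisation into k bins (integer codes 1..k)
discretizeEF <- function(x, k) {
  stopifnot(k >= 2)
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * k / length(x)))
}
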