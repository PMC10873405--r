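#' Build a simulation configuration
#'
#' Defines the generating model for a synthetic high-dimensional dataset:
#' i.i.d. standard-normal covariates, and an outcome that is either a sparse
#' linear combination of the first `p0` features or a sine/cosine non-linear
#' function of them, with additive Gaussian noise. Binary outcomes are
#' obtained by dichotomising the continuous outcome at its median.
#'
#' @param n sample count (default 1000).
#' @param p feature count (default 5000).
#' @param p0 number of causal features; must be even for the non-linear
#'   model, which splits the causal set into a sine half and a cosine half.
#' @param effectModel `"linear"` or `"nonlinear"`.
#' @param outcomeType `"continuous"` or `"binary"`.
#' @param noiseSd standard deviation of the additive noise; defaults to 1
#'   for the linear model and 0.1 for the non-linear model.
#' @param seed integer RNG seed; one seed drives covariates, effect sizes
#'   and noise through independently derived substreams.
#' @param causalPlacement `"prefix"` places the causal features in columns
#'   `1..p0`; `"random"` scatters them (for robustness checks).
#' @return a validated [SimulationConfig-class].
#' @examples
#' simulationConfig(n = 100, p = 200, p0 = 10, seed = 1)
#' @export
simulationConfig <- function(n = 1000, p = 5000, p0 = 100,
                             effectModel = c("linear", "nonlinear"),
                             outcomeType = c("continuous", "binary"),
                             noiseSd = NULL, seed = 1L,
                             causalPlacement = c("prefix", "random")) {
  effectModel <- match.arg(effectModel)
  outcomeType <- match.arg(outcomeType)
  causalPlacement <- match.arg(causalPlacement)
  if (is.null(noiseSd))
    noiseSd <- if (effectModel == "linear") 1 else 0.1
  new("SimulationConfig", n = as.integer(n), p = as.integer(p),
      p0 = as.integer(p0), effectModel = effectModel,
      outcomeType = outcomeType, noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed), causalPlacement = causalPlacement)
}

#' Draw sparse linear effect sizes with a guaranteed detectability floor
#'
#' Effects are `(-1)^U * (5 log(n)/sqrt(n) + |Z|)` with `U ~ Bernoulli(0.5)`
#' and `Z ~ N(0,1)` (natural logarithm), so every effect magnitude exceeds
#' the classical sure-screening threshold `5 log(n)/sqrt(n)`.
#'
#' @param n sample count the floor is computed from.
#' @param p0 number of effects to draw.
#' @param seed integer seed.
#' @return numeric vector of `p0` signed effect sizes.
#' @examples
#' w <- drawLinearWeights(1000, 5, seed = 1)
#' all(abs(w) >= 5 * log(1000) / sqrt(1000))
#' @export
drawLinearWeights <- function(n, p0, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("'n' must be a single value >= 2")
  if (!is.numeric(p0) || length(p0) != 1L || p0 < 1)
    stop("'p0' must be a single positive value")
  floorMag <- 5 * log(n) / sqrt(n)
  withSeed(seed, {
    sign <- (-1)^rbinom(p0, 1L, 0.5)
    sign * (floorMag + abs(rnorm(p0)))
  })
}

#' Dichotomise a continuous outcome at its median
#'
#' Values greater than or equal to the sample median map to class 1, values
#' strictly below it to class 0. For continuous draws this balances the two
#' classes to within one sample.
#'
#' @param y numeric vector of length at least 2.
#' @return integer 0/1 vector of the same length.
#' @examples
#' binarizeAtMedian(c(1, 2, 3, 4))
#' @export
binarizeAtMedian <- function(y) {
  if (!is.numeric(y) || length(y) < 2L)
    stop("'y' must be a numeric vector of length >= 2")
  as.integer(y >= median(y))
}

#' Simulate a high-dimensional dataset with known causal features
#'
#' Covariates are i.i.d. `N(0,1)`. Under the linear model the outcome is
#' `X[, causal] %*% w + eps` with effects from [drawLinearWeights()] and
#' `eps ~ N(0, noiseSd^2)`. Under the non-linear model the causal set of
#' size `p0` is split in half: the outcome is the sum of `sin()` over the
#' first half plus `1.8 *` the sum of `cos()` over the second half, plus
#' noise. Binary outcomes are the median dichotomisation of the continuous
#' outcome (noise included).
#'
#' @param config a [SimulationConfig-class], or arguments forwarded to
#'   [simulationConfig()] when `config` is missing.
#' @param ... passed to [simulationConfig()] when `config` is missing.
#' @return a [SimulatedDataset-class].
#' @examples
#' d <- simulateDataset(simulationConfig(n = 50, p = 20, p0 = 4, seed = 7))
#' dim(simX(d))
#' @export
simulateDataset <- function(config, ...) {
  if (missing(config)) config <- simulationConfig(...)
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  n <- config@n; p <- config@p; p0 <- config@p0
  seeds <- deriveSeeds(config@seed, 4L)
  X <- withSeed(seeds[1L], matrix(rnorm(n * p), nrow = n, ncol = p))
  causal <- if (config@causalPlacement == "prefix") seq_len(p0)
            else withSeed(seeds[4L], sort(sample.int(p, p0)))
  if (config@effectModel == "linear") {
    w <- drawLinearWeights(n, p0, seed = seeds[2L])
    signal <- as.vector(X[, causal, drop = FALSE] %*% w)
  } else {
    p1 <- p0 %/% 2L
    sinSet <- causal[seq_len(p1)]
    cosSet <- causal[seq.int(p0 - p1 + 1L, p0)]
    signal <- rowSums(sin(X[, sinSet, drop = FALSE])) +
      1.8 * rowSums(cos(X[, cosSet, drop = FALSE]))
    w <- numeric(0)
  }
  eps <- withSeed(seeds[3L], rnorm(n, sd = config@noiseSd))
  y <- signal + eps
  if (config@outcomeType == "binary") y <- as.numeric(binarizeAtMedian(y))
  new("SimulatedDataset", X = X, y = y, causalIndices = as.integer(causal),
      weights = w, config = config)
}
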