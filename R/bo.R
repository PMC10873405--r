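#' Declare a box-bounded hyper-parameter search space
#'
#' @param ... one or more parameter descriptors created by [boParam()].
#' @return a [HyperParameterSpace-class].
#' @examples
#' hyperParameterSpace(boParam("lambda", 0.001, 1))
#' @export
hyperParameterSpace <- function(...) {
  pars <- list(...)
  if (!length(pars)) stop("at least one parameter is required")
  df <- do.call(rbind, lapply(pars, as.data.frame))
  new("HyperParameterSpace", parameters = df)
}

#' @rdname hyperParameterSpace
#' @param name parameter name.
#' @param lower,upper bounds (lower < upper; lower > 0 for log scale).
#' @param scale `"linear"` or `"log"`: the scale on which the parameter is
#'   sampled uniformly and measured by the GP kernel.
#' @param kind `"continuous"` or `"integer"` (integer parameters are
#'   evaluated at rounded values).
#' @export
boParam <- function(name, lower, upper, scale = c("linear", "log"),
                    kind = c("continuous", "integer")) {
  list(name = name, lower = lower, upper = upper,
       scale = match.arg(scale), kind = match.arg(kind))
}

## map native values (matrix, cols = params) to [0,1]^d on the declared scale
normalizeSpace <- function(space, M) {
  pr <- space@parameters
  Z <- M
  for (j in seq_len(nrow(pr))) {
    if (pr$scale[j] == "log")
      Z[, j] <- (log(M[, j]) - log(pr$lower[j])) /
        (log(pr$upper[j]) - log(pr$lower[j]))
    else
      Z[, j] <- (M[, j] - pr$lower[j]) / (pr$upper[j] - pr$lower[j])
  }
  Z
}

## uniform sample of k points on the declared scales, native values
sampleSpace <- function(space, k) {
  pr <- space@parameters
  M <- matrix(NA_real_, nrow = k, ncol = nrow(pr),
              dimnames = list(NULL, pr$name))
  for (j in seq_len(nrow(pr))) {
    u <- runif(k)
    v <- if (pr$scale[j] == "log")
      exp(log(pr$lower[j]) + u * (log(pr$upper[j]) - log(pr$lower[j])))
    else pr$lower[j] + u * (pr$upper[j] - pr$lower[j])
    if (pr$kind[j] == "integer") v <- round(v)
    M[, j] <- v
  }
  M
}

#' Bayesian optimization over a box-bounded hyper-parameter space
#'
#' Maximises a black-box objective: after `nInitial` uniformly sampled
#' evaluations, each iteration draws `nCandidates` fresh uniform candidate
#' points, scores them by the upper confidence bound
#' ([gpPosterior()] + [acquisitionUCB()]) of a Gaussian-process surrogate
#' fitted to all evaluations so far, and evaluates the objective at the
#' acquisition argmax (ties broken by lowest candidate index). Inputs are
#' rescaled to the unit box for the kernel; objectives are standardised
#' internally before surrogate fitting. Loss-type objectives should be
#' negated by the caller.
#'
#' @param objective function taking a named list of parameter values and
#'   returning a finite scalar (higher is better).
#' @param space a [HyperParameterSpace-class].
#' @param nIterations number of acquisition-driven evaluations (>= 1).
#' @param nCandidates uniform candidate pool size per iteration.
#' @param nInitial number of uniform evaluations before the first surrogate
#'   fit.
#' @param kappa UCB exploration weight.
#' @param lengthscale GP kernel lengthscale as a fraction of the normalized
#'   unit range (default 0.2); kernel variance is fixed at 1 on the
#'   standardised objective scale.
#' @param noiseVariance GP observation-noise variance on the standardised
#'   objective scale.
#' @param seed integer seed; the run is fully reproducible given the seed.
#' @return a [BOTrace-class].
#' @examples
#' sp <- hyperParameterSpace(boParam("x", 0, 1))
#' tr <- boOptimize(function(p) -(p$x - 0.3)^2, sp,
#'                  nIterations = 10, nCandidates = 100, seed = 1)
#' bestPoint(tr)
#' @export
boOptimize <- function(objective, space, nIterations = 100L,
                       nCandidates = 500L, nInitial = 5L, kappa = 2,
                       lengthscale = 0.2, noiseVariance = 1e-6, seed = 1L) {
  stopifnot(is(space, "HyperParameterSpace"))
  validObject(space)
  if (nIterations < 1L) stop("nIterations must be >= 1")
  if (nInitial < 1L) stop("nInitial must be >= 1")
  pr <- space@parameters
  d <- nrow(pr)

  evalPoint <- function(row) {
    pt <- as.list(row)
    names(pt) <- pr$name
    val <- tryCatch(objective(pt), error = function(e) NA_real_)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
      NA_real_ else as.numeric(val)
  }

  withSeed(seed, {
    P <- sampleSpace(space, nInitial)
    obj <- apply(P, 1L, evalPoint)
    iter <- rep(0L, nInitial)
    for (it in seq_len(nIterations)) {
      cand <- sampleSpace(space, nCandidates)
      ok <- is.finite(obj)
      if (sum(ok) >= 1L) {
        y <- obj[ok]
        mu <- mean(y); s <- sd(y)
        ys <- if (is.finite(s) && s > 0) (y - mu) / s else y - mu
        post <- gpPosterior(normalizeSpace(space, P[ok, , drop = FALSE]), ys,
                            normalizeSpace(space, cand),
                            lengthscale = lengthscale, kernelVariance = 1,
                            noiseVariance = noiseVariance)
        score <- acquisitionUCB(post$mean, post$sd, kappa)
        pick <- which.max(score)           # first max: lowest index on ties
      } else {
        pick <- 1L                          # no usable surrogate yet
      }
      P <- rbind(P, cand[pick, , drop = FALSE])
      obj <- c(obj, evalPoint(cand[pick, ]))
      iter <- c(iter, it)
      if (mean(!is.finite(obj)) > 0.5)
        stop("objective returned non-finite values on more than half of ",
             length(obj), " evaluations; aborting")
    }
    bsf <- cummax(ifelse(is.finite(obj), obj, -Inf))
    ev <- data.frame(iteration = iter, P, objective = obj,
                     best_so_far = bsf, check.names = FALSE)
    best <- which.max(ifelse(is.finite(obj), obj, -Inf))
    bp <- as.list(P[best, ])
    names(bp) <- pr$name
    new("BOTrace", evaluations = ev, bestPoint = bp,
        bestObjective = obj[best], kappa = as.numeric(kappa),
        nIterations = as.integer(nIterations), seed = as.integer(seed))
  })
}

#' Export a Bayesian-optimization trace
#'
#' Writes the evaluation history as CSV (`iteration`, parameter values,
#' `objective`, `best_so_far`) and, optionally, a JSON summary with the best
#' point, its objective, `kappa` and the seed.
#'
#' @param trace a [BOTrace-class].
#' @param csvPath path for the CSV history.
#' @param jsonPath optional path for the JSON summary.
#' @return invisibly, the paths written.
#' @export
exportTrace <- function(trace, csvPath, jsonPath = NULL) {
  stopifnot(is(trace, "BOTrace"))
  utils::write.csv(trace@evaluations, csvPath, row.names = FALSE)
  if (!is.null(jsonPath)) {
    jsonlite::write_json(
      list(best_point = trace@bestPoint,
           best_objective = trace@bestObjective,
           kappa = trace@kappa, n_iterations = trace@nIterations,
           seed = trace@seed),
      jsonPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(csvPath, jsonPath))
}
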