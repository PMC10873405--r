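#' SimulationConfig: generating configuration for a synthetic dataset
#'
#' Holds every parameter of the simulation model: sample size, feature count,
#' number of causal features, the effect model (linear or non-linear
#' sine/cosine), the outcome type, the noise standard deviation and the seed.
#'
#' @slot n integer, sample count.
#' @slot p integer, feature count.
#' @slot p0 integer, causal feature count.
#' @slot effectModel `"linear"` or `"nonlinear"`.
#' @slot outcomeType `"continuous"` or `"binary"`.
#' @slot noiseSd numeric, standard deviation of the additive noise.
#' @slot seed integer RNG seed.
#' @slot causalPlacement `"prefix"` (causal features are columns
#'   `1..p0`) or `"random"`.
#' @export
setClass("SimulationConfig",
  representation(n = "integer", p = "integer", p0 = "integer",
                 effectModel = "character", outcomeType = "character",
                 noiseSd = "numeric", seed = "integer",
                 causalPlacement = "character"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@n < 2L) msg <- c(msg, "n must be >= 2")
  if (object@p0 < 1L || object@p0 > object@p)
    msg <- c(msg, "p0 must satisfy 0 < p0 <= p")
  if (!object@effectModel %in% c("linear", "nonlinear"))
    msg <- c(msg, "effectModel must be 'linear' or 'nonlinear'")
  if (!object@outcomeType %in% c("continuous", "binary"))
    msg <- c(msg, "outcomeType must be 'continuous' or 'binary'")
  if (!is.finite(object@noiseSd) || object@noiseSd <= 0)
    msg <- c(msg, "noiseSd must be > 0")
  if (object@effectModel == "nonlinear" && object@p0 %% 2L != 0L)
    msg <- c(msg, "nonlinear model requires an even p0 (p1 = p0/2)")
  if (!object@causalPlacement %in% c("prefix", "random"))
    msg <- c(msg, "causalPlacement must be 'prefix' or 'random'")
  if (length(msg)) msg else TRUE
})

#' SimulatedDataset: covariates, outcome and ground truth
#'
#' @slot X numeric matrix, `n` samples by `p` features.
#' @slot y numeric outcome vector (real-valued, or 0/1 for binary).
#' @slot causalIndices integer vector of the truly causal columns.
#' @slot weights numeric effect sizes (length `p0`; empty for the
#'   non-linear model, whose effects are fixed sine/cosine terms).
#' @slot config the [SimulationConfig-class] used.
#' @export
setClass("SimulatedDataset",
  representation(X = "matrix", y = "numeric", causalIndices = "integer",
                 weights = "numeric", config = "SimulationConfig"))

setValidity("SimulatedDataset", function(object) {
  msg <- character()
  cfg <- object@config
  if (!identical(dim(object@X), c(cfg@n, cfg@p)))
    msg <- c(msg, "X must be n x p")
  if (length(object@y) != cfg@n) msg <- c(msg, "y must have length n")
  if (length(object@causalIndices) != cfg@p0)
    msg <- c(msg, "causalIndices must have length p0")
  if (anyDuplicated(object@causalIndices))
    msg <- c(msg, "causalIndices must be unique")
  if (length(object@causalIndices) &&
      (min(object@causalIndices) < 1L || max(object@causalIndices) > cfg@p))
    msg <- c(msg, "causalIndices out of range")
  if (cfg@effectModel == "linear" && length(object@weights) != cfg@p0)
    msg <- c(msg, "weights must have length p0 for the linear model")
  if (cfg@outcomeType == "binary") {
    if (!all(object@y %in% c(0, 1)))
      msg <- c(msg, "binary outcome must be 0/1")
    if (abs(sum(object@y == 1) - sum(object@y == 0)) > 1)
      msg <- c(msg, "binary classes must be balanced to within one sample")
  }
  if (length(msg)) msg else TRUE
})

#' HyperParameterSpace: box-bounded search domain
#'
#' An ordered set of named parameters, each with a lower and upper bound, a
#' sampling scale (`linear` or `log`) and a kind (`continuous` or `integer`).
#'
#' @slot parameters data.frame with columns `name`, `lower`, `upper`,
#'   `scale`, `kind`.
#' @export
setClass("HyperParameterSpace",
  representation(parameters = "data.frame"))

setValidity("HyperParameterSpace", function(object) {
  pr <- object@parameters
  need <- c("name", "lower", "upper", "scale", "kind")
  if (!all(need %in% names(pr))) return("missing parameter columns")
  msg <- character()
  if (anyDuplicated(pr$name)) msg <- c(msg, "parameter names must be unique")
  if (any(pr$lower >= pr$upper)) msg <- c(msg, "lower must be < upper")
  if (!all(pr$scale %in% c("linear", "log")))
    msg <- c(msg, "scale must be 'linear' or 'log'")
  if (!all(pr$kind %in% c("continuous", "integer")))
    msg <- c(msg, "kind must be 'continuous' or 'integer'")
  if (any(pr$scale == "log" & pr$lower <= 0))
    msg <- c(msg, "log scale requires lower > 0")
  if (length(msg)) msg else TRUE
})

#' BOTrace: history of a Bayesian-optimization run
#'
#' @slot evaluations data.frame with one row per objective evaluation:
#'   `iteration` (0 for the initial design), one column per parameter,
#'   `objective` and `best_so_far`.
#' @slot bestPoint named list, the best parameter setting found.
#' @slot bestObjective numeric, the best objective value.
#' @slot kappa numeric, the UCB exploration weight used.
#' @slot nIterations integer, number of acquisition-driven iterations.
#' @slot seed integer seed of the run.
#' @export
setClass("BOTrace",
  representation(evaluations = "data.frame", bestPoint = "list",
                 bestObjective = "numeric", kappa = "numeric",
                 nIterations = "integer", seed = "integer"))

setValidity("BOTrace", function(object) {
  ev <- object@evaluations
  msg <- character()
  if (nrow(ev)) {
    obj <- ev$objective[is.finite(ev$objective)]
    if (length(obj) && abs(max(obj) - object@bestObjective) > 1e-12)
      msg <- c(msg, "bestObjective must equal the max over evaluations")
    bsf <- ev$best_so_far
    if (any(diff(bsf) < -1e-12))
      msg <- c(msg, "best-so-far sequence must be non-decreasing")
  }
  if (length(msg)) msg else TRUE
})

#' SelectionResult: a ranked feature list
#'
#' @slot method one of `"lasso"`, `"enet"`, `"xgboost"`, `"sis"`,
#'   `"mrmr"`, `"splsda"`.
#' @slot tuner one of `"BO"`, `"AIC"`, `"CV"`, `"DE"`, `"none"`.
#' @slot rankedIndices integer vector of feature indices, best first.
#' @slot scores numeric score per ranked feature (non-increasing within a
#'   ranking tier).
#' @slot hyperparams named list of the hyper-parameter values actually used.
#' @slot nRequested integer, the requested number of features `n_s`.
#' @slot trace the [BOTrace-class] of the tuning run, or `NULL`.
#' @export
setClass("SelectionResult",
  representation(method = "character", tuner = "character",
                 rankedIndices = "integer", scores = "numeric",
                 hyperparams = "list", nRequested = "integer",
                 trace = "ANY"))

setValidity("SelectionResult", function(object) {
  msg <- character()
  if (!object@method %in% c("lasso", "enet", "xgboost", "sis", "mrmr", "splsda"))
    msg <- c(msg, "unknown method")
  if (!object@tuner %in% c("BO", "AIC", "CV", "DE", "none"))
    msg <- c(msg, "unknown tuner")
  if (anyDuplicated(object@rankedIndices))
    msg <- c(msg, "rankedIndices must be unique")
  if (length(object@rankedIndices) > object@nRequested)
    msg <- c(msg, "ranking longer than nRequested")
  if (length(object@scores) != length(object@rankedIndices))
    msg <- c(msg, "scores must match rankedIndices in length")
  if (length(msg)) msg else TRUE
})
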