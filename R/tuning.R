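#' Search spaces for the Bayesian-optimized selectors
#'
#' The lasso searches the penalty `lambda` in (0, 1); the elastic net
#' searches `lambda` and the L1 share `rho`, both in (0, 1); the boosting
#' selector searches learning rate (log scale), maximum depth, row and
#' column subsampling and the two penalty terms, with the number of
#' boosting rounds fixed at 100.
#'
#' @param method `"lasso"`, `"enet"` or `"xgboost"`.
#' @return a [HyperParameterSpace-class].
#' @export
selectorSearchSpace <- function(method = c("lasso", "enet", "xgboost")) {
  method <- match.arg(method)
  switch(method,
    lasso = hyperParameterSpace(boParam("lambda", 1e-3, 1 - 1e-3)),
    enet = hyperParameterSpace(boParam("lambda", 1e-3, 1 - 1e-3),
                               boParam("rho", 1e-3, 1 - 1e-3)),
    xgboost = hyperParameterSpace(
      boParam("eta", 0.01, 0.3, scale = "log"),
      boParam("max_depth", 2, 10, kind = "integer"),
      boParam("subsample", 0.5, 1),
      boParam("colsample_bytree", 0.5, 1),
      boParam("gamma", 1e-6, 5),
      boParam("lambda", 1e-6, 10)))
}

## seeded fold assignment
makeFolds <- function(n, k, seed) {
  withSeed(seed, sample(rep(seq_len(k), length.out = n)))
}

## mean k-fold CV predictive performance (higher is better):
## negative MSE for gaussian, accuracy for binomial
cvObjective <- function(X, y, folds, family, fitPredict) {
  k <- max(folds)
  perf <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    pred <- fitPredict(X[tr, , drop = FALSE], y[tr],
                       X[!tr, , drop = FALSE])
    perf[f] <- if (family == "gaussian") -mean((pred - y[!tr])^2)
               else mean((pred >= 0.5) == (y[!tr] == 1))
  }
  mean(perf)
}

penalizedCvObjective <- function(X, y, folds, family) {
  function(pt) {
    rho <- if (is.null(pt$rho)) 1 else pt$rho
    cvObjective(X, y, folds, family, function(Xtr, ytr, Xte) {
      path <- lambdaPathTo(pt$lambda)
      fit <- glmnet::glmnet(Xtr, ytr, family = family, alpha = rho,
                            lambda = path, standardize = TRUE)
      type <- if (family == "gaussian") "link" else "response"
      predict(fit, Xte, s = pt$lambda, type = type)[, 1L]
    })
  }
}

xgbCvObjective <- function(X, y, folds, family, nrounds, seed) {
  obj <- if (family == "gaussian") "reg:squarederror" else "binary:logistic"
  function(pt) {
    cvObjective(X, y, folds, family, function(Xtr, ytr, Xte) {
      withSeed(seed, {
        dtr <- xgboost::xgb.DMatrix(Xtr, label = ytr, nthread = 1L)
        fit <- xgboost::xgb.train(
          params = c(pt, list(objective = obj, nthread = 1L,
                              tree_method = "hist")),
          data = dtr, nrounds = nrounds, verbose = 0)
        predict(fit, xgboost::xgb.DMatrix(Xte, nthread = 1L))
      })
    })
  }
}

#' Bayesian-optimized feature selection
#'
#' Tunes the hyper-parameters of the lasso, elastic net or boosting
#' selector by Bayesian optimization ([boOptimize()]): the objective is the
#' mean k-fold cross-validated predictive performance at the candidate
#' hyper-parameters (negative mean squared error for continuous outcomes,
#' accuracy for binary ones). The final ranking is produced at the best
#' hyper-parameters found, with the tier-2 correlation fill enabled, and
#' the optimization trace is attached to the result.
#'
#' @param method `"lasso"`, `"enet"` or `"xgboost"`.
#' @param X numeric matrix, samples by features.
#' @param y outcome vector.
#' @param nS number of features requested.
#' @param family `"gaussian"` or `"binomial"`.
#' @param nIterations Bayesian-optimization iterations (default 100).
#' @param cvFolds folds of the tuning objective (default 5).
#' @param kappa,nCandidates,nInitial forwarded to [boOptimize()].
#' @param nrounds boosting rounds for `method = "xgboost"`.
#' @param seed integer seed driving folds, optimizer and final fit.
#' @return a [SelectionResult-class] with tuner `"BO"` and the
#'   [BOTrace-class] attached.
#' @export
boTunedSelect <- function(method = c("lasso", "enet", "xgboost"),
                          X, y, nS, family = c("gaussian", "binomial"),
                          nIterations = 100L, cvFolds = 5L, kappa = 2,
                          nCandidates = 500L, nInitial = 5L,
                          nrounds = 100L, seed = 1L) {
  method <- match.arg(method)
  family <- match.arg(family)
  seeds <- deriveSeeds(seed, 3L)
  folds <- makeFolds(nrow(X), cvFolds, seeds[1L])
  space <- selectorSearchSpace(method)
  objective <- switch(method,
    lasso = , enet = penalizedCvObjective(X, y, folds, family),
    xgboost = xgbCvObjective(X, y, folds, family, nrounds, seeds[3L]))
  trace <- boOptimize(objective, space, nIterations = nIterations,
                      nCandidates = nCandidates, nInitial = nInitial,
                      kappa = kappa, seed = seeds[2L])
  best <- bestPoint(trace)
  res <- switch(method,
    lasso = selectPenalized(X, y, lambda = best$lambda, rho = 1, nS = nS,
                            family = family, fallback = TRUE, tuner = "BO"),
    enet = selectPenalized(X, y, lambda = best$lambda, rho = best$rho,
                           nS = nS, family = family, fallback = TRUE,
                           tuner = "BO"),
    xgboost = selectXgboost(X, y, nS = nS, params = best, nrounds = nrounds,
                            family = family, fallback = TRUE, tuner = "BO",
                            seed = seeds[3L]))
  res@trace <- trace
  validObject(res)
  res
}

#' Default hyper-parameters for the default-setting (DE) variants
#'
#' Fixed, documented settings standing in for the cited packages' defaults:
#' a light penalty `lambda = 0.01` for the lasso, the same penalty with an
#' even L1/L2 mix for the elastic net, and the boosting backend's own
#' defaults ([defaultXgbParams()]).
#'
#' @param method `"lasso"`, `"enet"` or `"xgboost"`.
#' @return named list of hyper-parameter values.
#' @export
defaultSelectorParams <- function(method = c("lasso", "enet", "xgboost")) {
  method <- match.arg(method)
  switch(method,
    lasso = list(lambda = 0.01, rho = 1),
    enet = list(lambda = 0.01, rho = 0.5),
    xgboost = defaultXgbParams())
}

#' Run any selector under any tuning strategy
#'
#' One entry point over the six selection methods and the tuning variants
#' studied: Bayesian optimization (`BO`), Akaike information criterion
#' (`AIC`), k-fold cross-validation (`CV`) and package defaults (`DE`) for
#' the penalized and boosting selectors; `none` for the tuner-free filters
#' (SIS, MRMR) and sPLSda. Continuous outcomes are rescaled to unit
#' variance before penalized fits so that the (0, 1) penalty range is on
#' the correlation scale. The `AIC`/`CV`/`DE` baselines do not use the
#' tier-2 correlation fill and may return fewer than `nS` features once
#' their fitted support is exhausted; the `BO` and `none` variants always
#' return `nS` features.
#'
#' @param X numeric matrix (samples by features), or a
#'   [SimulatedDataset-class] in which case `y` is taken from it.
#' @param y outcome vector (ignored when `X` is a dataset).
#' @param method one of `"lasso"`, `"enet"`, `"xgboost"`, `"sis"`,
#'   `"mrmr"`, `"splsda"`.
#' @param tuner one of `"BO"`, `"AIC"`, `"CV"`, `"DE"`, `"none"`.
#' @param nS number of features requested.
#' @param family `"gaussian"` or `"binomial"`; inferred from the outcome
#'   when missing.
#' @param nIterations Bayesian-optimization iterations for `tuner = "BO"`.
#' @param seed integer seed.
#' @param ... further arguments passed to the underlying selector.
#' @return a [SelectionResult-class].
#' @examples
#' d <- simulateDataset(simulationConfig(n = 60, p = 30, p0 = 4, seed = 1))
#' selectFeatures(d, method = "sis", nS = 4)
#' @export
selectFeatures <- function(X, y = NULL,
                           method = c("lasso", "enet", "xgboost", "sis",
                                      "mrmr", "splsda"),
                           tuner = c("BO", "AIC", "CV", "DE", "none"),
                           nS, family = NULL, nIterations = 100L,
                           seed = 1L, ...) {
  method <- match.arg(method)
  tuner <- match.arg(tuner)
  if (is(X, "SimulatedDataset")) { y <- simY(X); X <- simX(X) }
  if (is.null(family))
    family <- if (all(y %in% c(0, 1))) "binomial" else "gaussian"
  ys <- if (family == "gaussian" && sd(y) > 0) y / sd(y) else y
  if (method %in% c("sis", "mrmr", "splsda")) {
    return(switch(method,
      sis = selectSIS(X, y, nS),
      mrmr = selectMRMR(X, y, nS, ...),
      splsda = selectSPLSda(X, y, nS, ...)))
  }
  if (tuner == "BO")
    return(boTunedSelect(method, X, ys, nS, family = family,
                         nIterations = nIterations, seed = seed, ...))
  if (method == "xgboost") {
    if (!tuner %in% c("DE", "none"))
      stop("the boosting selector supports tuners 'BO', 'DE' and 'none'")
    return(selectXgboost(X, ys, nS, params = defaultXgbParams(),
                         family = family, fallback = tuner == "none",
                         tuner = tuner, seed = seed, ...))
  }
  rho <- if (method == "lasso") 1 else 0.5
  cfg <- switch(tuner,
    AIC = tunePenalizedAIC(X, ys, rho = rho, family = family, ...),
    CV = tunePenalizedCV(X, ys, rho = rho, family = family,
                         seed = seed, ...),
    DE = defaultSelectorParams(method),
    none = defaultSelectorParams(method))
  selectPenalized(X, ys, lambda = cfg$lambda, rho = cfg$rho, nS = nS,
                  family = family, fallback = tuner == "none",
                  tuner = tuner)
}
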