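## decreasing lambda path ending exactly at `lambda`, for warm-started fits;
## glmnet is unreliable when asked for one small lambda cold
lambdaPathTo <- function(lambda, from = 1, length.out = 25L) {
  if (lambda >= from) return(lambda)
  exp(seq(log(from), log(lambda), length.out = length.out))
}

#' Default penalty grid
#'
#' Fifty log-spaced penalty values spanning (0, 1], the search range used
#' for AIC and cross-validated tuning of the lasso and elastic net.
#'
#' @return decreasing numeric vector of penalty values in (0, 1].
#' @export
defaultLambdaGrid <- function() {
  rev(exp(seq(log(1e-3), log(1), length.out = 50L)))
}

#' Fit a penalized regression at one penalty setting
#'
#' Elastic-net objective: loss (scaled by 1/(2n) for Gaussian) plus
#' `lambda * rho * ||w||_1 + lambda * (1 - rho) / 2 * ||w||_2^2`. `rho = 1`
#' is the lasso; `0 < rho < 1` the elastic net. Columns of `X` are
#' standardised internally; coefficients are reported on the original scale.
#'
#' @param X numeric matrix, samples by features.
#' @param y outcome vector (numeric, or 0/1 for `family = "binomial"`).
#' @param lambda penalty strength in (0, 1].
#' @param rho L1 share of the penalty in (0, 1].
#' @param family `"gaussian"` or `"binomial"`.
#' @return numeric coefficient vector of length `ncol(X)` (no intercept),
#'   with the intercept in attribute `"intercept"` and a logical
#'   `"converged"` attribute.
#' @export
fitPenalized <- function(X, y, lambda, rho = 1,
                         family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  if (!is.numeric(lambda) || lambda <= 0 || lambda > 1)
    stop("'lambda' must lie in (0, 1]")
  if (!is.numeric(rho) || rho <= 0 || rho > 1)
    stop("'rho' must lie in (0, 1]")
  path <- lambdaPathTo(lambda)
  fit <- glmnet::glmnet(X, y, family = family, alpha = rho, lambda = path,
                        standardize = TRUE)
  converged <- fit$jerr == 0
  if (!converged)
    warning("penalized fit did not fully converge; returning partial result")
  k <- length(fit$lambda)           # last fitted = requested lambda
  beta <- as.vector(fit$beta[, k])
  attr(beta, "intercept") <- fit$a0[k]
  attr(beta, "converged") <- converged
  beta
}

## ranked selection from a coefficient vector: tier 1 nonzero by |coef|,
## optional tier 2 fallback over the rest by |marginal correlation|
rankFromCoefficients <- function(beta, X, y, nS, fallback) {
  p <- length(beta)
  if (nS > p) stop("requested more features than available")
  nz <- which(beta != 0)
  tier1 <- nz[orderDesc(abs(beta[nz]))]
  scores1 <- abs(beta[tier1])
  if (fallback && length(tier1) < nS) {
    r <- suppressWarnings(as.vector(cor(X, y)))
    r[!is.finite(r)] <- 0
    rest <- setdiff(orderDesc(abs(r)), tier1)
    idx <- c(tier1, rest)[seq_len(nS)]
    sc <- c(scores1, abs(r)[rest])[seq_len(nS)]
  } else {
    keep <- seq_len(min(nS, length(tier1)))
    idx <- tier1[keep]
    sc <- scores1[keep]
  }
  list(indices = as.integer(idx), scores = as.numeric(sc))
}

#' Ranked feature selection by penalized regression
#'
#' Fits the lasso / elastic net at the supplied penalty and ranks features:
#' tier 1 holds the nonzero coefficients ordered by decreasing magnitude;
#' when fewer than `nS` coefficients are nonzero and `fallback = TRUE`, the
#' remaining slots are filled by the unselected features ordered by absolute
#' marginal correlation with the outcome. With `fallback = FALSE` (the
#' behaviour of the AIC/CV/default-tuned baselines, whose selections plateau
#' at the fitted support), fewer than `nS` features may be returned.
#'
#' @inheritParams fitPenalized
#' @param nS number of features requested.
#' @param fallback logical, enable the tier-2 correlation fill.
#' @param tuner label recorded in the result.
#' @return a [SelectionResult-class].
#' @export
selectPenalized <- function(X, y, lambda, rho = 1, nS,
                            family = c("gaussian", "binomial"),
                            fallback = TRUE, tuner = "none") {
  family <- match.arg(family)
  beta <- fitPenalized(X, y, lambda, rho, family)
  rk <- rankFromCoefficients(beta, X, y, nS, fallback)
  new("SelectionResult",
      method = if (rho == 1) "lasso" else "enet",
      tuner = tuner, rankedIndices = rk$indices, scores = rk$scores,
      hyperparams = list(lambda = lambda, rho = rho),
      nRequested = as.integer(nS), trace = NULL)
}

## coefficient matrix over a decreasing penalty grid (p x length(grid))
pathCoefficients <- function(X, y, rho, grid, family) {
  grid <- rev(sort(grid))
  fit <- glmnet::glmnet(X, y, family = family, alpha = rho, lambda = grid,
                        standardize = TRUE)
  list(fit = fit, grid = fit$lambda)
}

#' Tune the penalty by the Akaike information criterion
#'
#' Fits the full penalty path and picks the value minimising
#' `n * log(RSS/n) + 2 * df` (Gaussian) or `deviance + 2 * df` (binomial),
#' with `df` the number of nonzero coefficients. Ties go to the sparser
#' (larger) penalty.
#'
#' @inheritParams fitPenalized
#' @param lambdaGrid candidate penalties in (0, 1]; default
#'   [defaultLambdaGrid()].
#' @return list with elements `lambda`, `rho` and the per-grid `criterion`.
#' @export
tunePenalizedAIC <- function(X, y, rho = 1, lambdaGrid = defaultLambdaGrid(),
                             family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  if (!length(lambdaGrid)) stop("'lambdaGrid' must be non-empty")
  pc <- pathCoefficients(X, y, rho, lambdaGrid, family)
  n <- nrow(X)
  df <- pc$fit$df
  if (family == "gaussian") {
    pred <- predict(pc$fit, X)
    rss <- colSums((pred - y)^2)
    crit <- n * log(rss / n) + 2 * df
  } else {
    dev <- (1 - pc$fit$dev.ratio) * pc$fit$nulldev
    crit <- dev + 2 * df
  }
  best <- which.min(crit)    # first (largest lambda) wins ties
  list(lambda = pc$grid[best], rho = rho,
       criterion = setNames(crit, signif(pc$grid, 4)))
}

## held-out loss for each grid lambda: MSE (gaussian) or deviance (binomial)
foldLoss <- function(fit, Xte, yte, family) {
  if (family == "gaussian") {
    pred <- predict(fit, Xte)
    colMeans((pred - yte)^2)
  } else {
    pr <- predict(fit, Xte, type = "response")
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    -2 * colMeans(yte * log(pr) + (1 - yte) * log(1 - pr))
  }
}

#' Tune the penalty by k-fold cross-validation
#'
#' Seeded fold assignment; the penalty minimising the mean held-out loss
#' (squared error for Gaussian, deviance for binomial) across folds is
#' returned. Ties go to the sparser (larger) penalty.
#'
#' @inheritParams tunePenalizedAIC
#' @param kFolds number of folds (default 10; must not exceed `nrow(X)`).
#' @param seed integer seed for the fold assignment.
#' @return list with elements `lambda`, `rho` and the per-grid `cvLoss`.
#' @export
tunePenalizedCV <- function(X, y, rho = 1, lambdaGrid = defaultLambdaGrid(),
                            family = c("gaussian", "binomial"),
                            kFolds = 10L, seed = 1L) {
  family <- match.arg(family)
  if (!length(lambdaGrid)) stop("'lambdaGrid' must be non-empty")
  n <- nrow(X)
  if (kFolds > n) stop("'kFolds' must not exceed the sample count")
  grid <- rev(sort(lambdaGrid))
  folds <- withSeed(seed, sample(rep(seq_len(kFolds), length.out = n)))
  loss <- matrix(NA_real_, nrow = kFolds, ncol = length(grid))
  for (k in seq_len(kFolds)) {
    tr <- folds != k
    fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = family,
                          alpha = rho, lambda = grid, standardize = TRUE)
    pl <- foldLoss(fit, X[!tr, , drop = FALSE], y[!tr], family)
    loss[k, seq_along(pl)] <- pl
  }
  mLoss <- colMeans(loss)
  best <- which.min(mLoss)
  list(lambda = grid[best], rho = rho,
       cvLoss = setNames(mLoss, signif(grid, 4)))
}
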