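#' Split gain of a gradient-boosted tree node
#'
#' The improvement in the regularised boosting objective from splitting a
#' node into left and right children with gradient sums `GL`, `GR` and
#' Hessian sums `HL`, `HR`:
#' `0.5 * (GL^2/(HL+lambda) + GR^2/(HR+lambda) - (GL+GR)^2/(HL+HR+lambda)) - gamma`.
#' Provided as an audited reference for the gain semantics that the
#' boosting-based selector ranks features by.
#'
#' @param GL,GR first-order gradient sums of the left and right child.
#' @param HL,HR second-order gradient sums (>= 0 for convex losses).
#' @param lambda L2 leaf-weight penalty (>= 0).
#' @param gamma per-split complexity penalty (>= 0).
#' @return numeric gain (vectorised over the arguments).
#' @examples
#' xgbGain(2, -2, 1, 1, lambda = 1, gamma = 0)  # 2
#' @export
xgbGain <- function(GL, GR, HL, HR, lambda = 0, gamma = 0) {
  if (any(HL < 0) || any(HR < 0)) stop("Hessian sums must be non-negative")
  if (any(lambda < 0) || any(gamma < 0)) stop("penalties must be non-negative")
  0.5 * (GL^2 / (HL + lambda) + GR^2 / (HR + lambda) -
           (GL + GR)^2 / (HL + HR + lambda)) - gamma
}

#' Default boosting hyper-parameters
#'
#' The documented defaults of the xgboost backend, used by the
#' default-setting (`DE`) variant of the boosting selector.
#'
#' @return named list of hyper-parameter values.
#' @export
defaultXgbParams <- function() {
  list(eta = 0.3, max_depth = 6, subsample = 1, colsample_bytree = 1,
       gamma = 0, lambda = 1)
}

#' Ranked feature selection by gradient boosting
#'
#' Fits a gradient-boosted tree ensemble and ranks features by the total
#' split gain they accumulate over the ensemble. Features that are never
#' split are appended after all gain-ranked features, ordered by absolute
#' marginal correlation with the outcome (tier-2 fill, disabled with
#' `fallback = FALSE`).
#'
#' @param X numeric matrix, samples by features.
#' @param y outcome (numeric, or 0/1 for `family = "binomial"`).
#' @param nS number of features requested.
#' @param params named list of boosting hyper-parameters (see
#'   [defaultXgbParams()]).
#' @param nrounds number of boosting rounds (default 100).
#' @param family `"gaussian"` or `"binomial"`.
#' @param fallback logical, enable the correlation fill for unsplit features.
#' @param tuner label recorded in the result.
#' @param seed integer seed (single-threaded, so the fit is reproducible).
#' @return a [SelectionResult-class].
#' @export
selectXgboost <- function(X, y, nS, params = defaultXgbParams(),
                          nrounds = 100L,
                          family = c("gaussian", "binomial"),
                          fallback = TRUE, tuner = "none", seed = 1L) {
  family <- match.arg(family)
  if (nS > ncol(X)) stop("requested more features than available")
  if (var(y) == 0) stop("outcome is constant; boosting fit is degenerate")
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  obj <- if (family == "gaussian") "reg:squarederror" else "binary:logistic"
  fullParams <- c(params,
                  list(objective = obj, nthread = 1L,
                       max_bin = 256L, tree_method = "hist"))
  fit <- withSeed(seed, {
    dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1L)
    xgboost::xgb.train(params = fullParams, data = dtrain,
                       nrounds = as.integer(nrounds), verbose = 0)
  })
  imp <- xgboost::xgb.importance(model = fit)
  gain <- setNames(numeric(ncol(X)), colnames(X))
  if (!is.null(imp) && nrow(imp))
    gain[imp$Feature] <- imp$Gain
  split <- which(gain > 0)
  tier1 <- split[orderDesc(gain[split])]
  scores1 <- gain[tier1]
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
  new("SelectionResult", method = "xgboost", tuner = tuner,
      rankedIndices = as.integer(unname(idx)), scores = as.numeric(sc),
      hyperparams = c(params, list(nrounds = nrounds)),
      nRequested = as.integer(nS), trace = NULL)
}
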