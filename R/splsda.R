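## leading singular-vector pair of M via svd; deterministic sign convention
## (largest-magnitude entry of the feature-side vector is positive)
leadingPair <- function(M) {
  sv <- svd(M, nu = 1L, nv = 1L)
  a <- sv$u[, 1L]; b <- sv$v[, 1L]
  s <- sign(a[which.max(abs(a))])
  if (s < 0) { a <- -a; b <- -b }
  list(alpha = a, beta = b, d = sv$d[1L])
}

## soft-threshold a to its k largest-magnitude entries, renormalised
softThresholdTopK <- function(a, k) {
  if (k >= length(a)) return(a / sqrt(sum(a^2)))
  thr <- sort(abs(a), decreasing = TRUE)[k + 1L]
  st <- sign(a) * pmax(abs(a) - thr, 0)
  nrm <- sqrt(sum(st^2))
  if (nrm > 0) st / nrm else st
}

#' Sparse partial least squares discriminant analysis selection
#'
#' The response is discretised into `nCategories` equal-frequency classes
#' (binary outcomes are used as two classes) and one-hot encoded. Each
#' component maximises the squared covariance between the latent scores
#' `X %*% alpha` and `Y %*% beta` via the leading singular-vector pair of
#' the column-centred cross-covariance `t(X) %*% Y`; the feature-side
#' vector is soft-thresholded to a per-component sparsity of
#' `ceiling(nS / nComponents)`, both matrices are deflated by the realised
#' latent score, and the procedure repeats. Features are ranked by the
#' component in which they first enter a support, ties within a component
#' by absolute loading; any remaining slots are filled by the largest
#' absolute loadings over all components.
#'
#' @param X numeric matrix, samples by features.
#' @param y outcome vector (continuous, or 0/1).
#' @param nS number of features requested.
#' @param nCategories number of equal-frequency classes for a continuous
#'   response (default 50).
#' @param nComponents number of sparse components (default 5).
#' @return a [SelectionResult-class].
#' @export
selectSPLSda <- function(X, y, nS, nCategories = 50L, nComponents = 5L) {
  if (nComponents < 1L) stop("'nComponents' must be >= 1")
  p <- ncol(X); n <- nrow(X)
  if (nS > p) stop("requested more features than available")
  cls <- if (all(y %in% c(0, 1))) as.integer(y) + 1L
         else discretizeEF(y, min(nCategories, n))
  kCls <- max(cls)
  Y <- matrix(0, n, kCls)
  Y[cbind(seq_len(n), cls)] <- 1
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  perComp <- ceiling(nS / nComponents)
  entered <- integer(0)
  entryScore <- numeric(0)
  maxLoad <- numeric(p)
  for (h in seq_len(nComponents)) {
    M <- crossprod(Xc, Yc)
    if (max(abs(M)) < 1e-12) break
    pair <- leadingPair(M)
    aSt <- softThresholdTopK(pair$alpha, perComp)
    supp <- which(aSt != 0)
    maxLoad <- pmax(maxLoad, abs(aSt))
    newFeat <- setdiff(supp, entered)
    newFeat <- newFeat[orderDesc(abs(aSt[newFeat]))]
    entered <- c(entered, newFeat)
    entryScore <- c(entryScore, abs(aSt[newFeat]))
    tScore <- as.vector(Xc %*% aSt)
    tt <- sum(tScore^2)
    if (tt < 1e-12) break
    cLoad <- crossprod(Xc, tScore) / tt
    Xc <- Xc - tcrossprod(tScore, cLoad)
    dLoad <- crossprod(Yc, tScore) / tt
    Yc <- Yc - tcrossprod(tScore, dLoad)
  }
  if (length(entered) < nS) {
    rest <- setdiff(orderDesc(maxLoad), entered)
    fill <- rest[seq_len(nS - length(entered))]
    entered <- c(entered, fill)
    entryScore <- c(entryScore, maxLoad[fill])
  }
  keep <- seq_len(min(nS, length(entered)))
  new("SelectionResult", method = "splsda", tuner = "none",
      rankedIndices = as.integer(entered[keep]),
      scores = as.numeric(entryScore[keep]),
      hyperparams = list(nCategories = nCategories,
                         nComponents = nComponents),
      nRequested = as.integer(nS), trace = NULL)
}
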