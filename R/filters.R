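#' Sure independence screening
#'
#' Ranks features by absolute Pearson correlation with the outcome and
#' returns the top `nS`. Zero-variance features get score 0; ties are broken
#' by lower feature index.
#'
#' @param X numeric matrix, samples by features.
#' @param y outcome vector.
#' @param nS number of features requested.
#' @return a [SelectionResult-class] with the absolute correlations as
#'   scores.
#' @export
selectSIS <- function(X, y, nS) {
  if (nrow(X) < 3L) stop("at least 3 samples are required")
  if (nS > ncol(X)) stop("requested more features than available")
  r <- suppressWarnings(as.vector(cor(X, y)))
  r[!is.finite(r)] <- 0
  idx <- orderDesc(abs(r))[seq_len(nS)]
  new("SelectionResult", method = "sis", tuner = "none",
      rankedIndices = as.integer(idx), scores = abs(r)[idx],
      hyperparams = list(), nRequested = as.integer(nS), trace = NULL)
}

## mutual information (bits) between two integer-coded discrete vectors
miDiscrete <- function(a, b, ka = max(a), kb = max(b)) {
  joint <- tabulate(a + ka * (b - 1L), ka * kb) / length(a)
  pa <- tabulate(a, ka) / length(a)
  pb <- tabulate(b, kb) / length(b)
  outerP <- as.vector(outer(pa, pb))
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outerP[nz]))
}

## discretise y for MI estimation: binary kept as-is, else equal-frequency
discretizeOutcome <- function(y, nBins) {
  if (all(y %in% c(0, 1))) list(code = as.integer(y) + 1L, k = 2L)
  else list(code = discretizeEF(y, nBins), k = as.integer(nBins))
}

#' Minimum-redundancy maximum-relevance selection
#'
#' Greedy forward selection on mutual information estimated from
#' equal-frequency discretised variables: the first pick maximises
#' `MI(y, x_i)`; each subsequent pick maximises relevance minus the mean
#' redundancy `MI(x_i, x_j)` over the already-selected set. Binary outcomes
#' are used as two classes without discretisation.
#'
#' @param X numeric matrix, samples by features.
#' @param y outcome vector.
#' @param nS number of features to select.
#' @param nBins number of equal-frequency bins (default 10).
#' @return a [SelectionResult-class]; scores are the MRMR criterion at the
#'   moment of selection (relevance for the first pick).
#' @export
selectMRMR <- function(X, y, nS, nBins = 10L) {
  p <- ncol(X); n <- nrow(X)
  if (nS > p) stop("requested more features than available")
  if (nBins < 2L) stop("'nBins' must be >= 2")
  B <- matrix(0L, n, p)
  for (j in seq_len(p)) B[, j] <- discretizeEF(X[, j], nBins)
  yd <- discretizeOutcome(y, nBins)
  rel <- vapply(seq_len(p), function(j)
    miDiscrete(B[, j], yd$code, nBins, yd$k), numeric(1))
  selected <- integer(0)
  scores <- numeric(0)
  redSum <- numeric(p)
  avail <- rep(TRUE, p)
  for (s in seq_len(nS)) {
    crit <- if (s == 1L) rel else rel - redSum / length(selected)
    crit[!avail] <- -Inf
    pick <- which.max(crit)       # first max: lowest index on ties
    selected <- c(selected, pick)
    scores <- c(scores, crit[pick])
    avail[pick] <- FALSE
    if (s < nS) {
      upd <- which(avail)
      redSum[upd] <- redSum[upd] + vapply(upd, function(j)
        miDiscrete(B[, pick], B[, j], nBins, nBins), numeric(1))
    }
  }
  new("SelectionResult", method = "mrmr", tuner = "none",
      rankedIndices = as.integer(selected), scores = scores,
      hyperparams = list(nBins = nBins),
      nRequested = as.integer(nS), trace = NULL)
}
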