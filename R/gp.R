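## Squared-exponential kernel on row vectors of A (m x d) and B (k x d)
seKernel <- function(A, B, lengthscale, variance) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  variance * exp(-0.5 * d2 / lengthscale^2)
}

#' Gaussian-process regression posterior
#'
#' Standard GP posterior mean and standard deviation under a
#' squared-exponential kernel, with observation noise and a small diagonal
#' jitter for numerical stability. The prior mean is the average of the
#' observed objectives, so predictions far from all observations revert to
#' that average with standard deviation `sqrt(kernelVariance)`.
#'
#' @param points numeric matrix of evaluated points (rows), or a vector for
#'   one-dimensional problems.
#' @param objectives numeric vector of observed objective values.
#' @param candidates numeric matrix (or vector) of points to predict at.
#' @param lengthscale kernel lengthscale (> 0).
#' @param kernelVariance kernel signal variance (> 0).
#' @param noiseVariance observation noise variance (>= 0).
#' @param jitter diagonal stabiliser added to the covariance (default 1e-8).
#' @return list with components `mean` and `sd`, one value per candidate.
#' @examples
#' post <- gpPosterior(c(0.2, 0.8), c(1, 2), c(0.2, 0.5),
#'                     lengthscale = 0.2, kernelVariance = 1,
#'                     noiseVariance = 0)
#' @export
gpPosterior <- function(points, objectives, candidates,
                        lengthscale, kernelVariance = 1,
                        noiseVariance = 1e-6, jitter = 1e-8) {
  A <- as.matrix(points)
  B <- as.matrix(candidates)
  if (ncol(A) != ncol(B)) stop("points and candidates must share dimension")
  if (nrow(A) < 1L) stop("at least one evaluation is required")
  if (length(objectives) != nrow(A))
    stop("objectives must match points in length")
  if (!all(is.finite(objectives))) stop("objectives must be finite")
  if (lengthscale <= 0 || kernelVariance <= 0)
    stop("kernel parameters must be positive")
  if (noiseVariance < 0) stop("noiseVariance must be >= 0")
  mu0 <- mean(objectives)
  K <- seKernel(A, A, lengthscale, kernelVariance)
  diag(K) <- diag(K) + noiseVariance + jitter
  L <- tryCatch(chol(K), error = function(e)
    stop("singular GP covariance; increase noiseVariance or jitter"))
  Ks <- seKernel(A, B, lengthscale, kernelVariance)  # m x k
  alpha <- backsolve(L, forwardsolve(t(L), objectives - mu0))
  postMean <- mu0 + as.vector(crossprod(Ks, alpha))
  V <- forwardsolve(t(L), Ks)                        # m x k
  postVar <- kernelVariance - colSums(V^2)
  postVar[postVar < 0] <- 0
  list(mean = postMean, sd = sqrt(postVar))
}

#' Upper-confidence-bound acquisition
#'
#' Scores candidates as `mean + kappa * sd`: the posterior mean rewards
#' exploitation, the posterior standard deviation rewards exploration, and
#' `kappa` sets the trade-off.
#'
#' @param mean numeric vector of posterior means.
#' @param sd numeric vector of posterior standard deviations (>= 0).
#' @param kappa non-negative exploration weight.
#' @return numeric vector of acquisition scores.
#' @examples
#' acquisitionUCB(0.5, 0.1, kappa = 2)  # 0.7
#' @export
acquisitionUCB <- function(mean, sd, kappa) {
  if (length(mean) != length(sd)) stop("mean and sd must match in length")
  if (any(sd < 0)) stop("sd must be non-negative")
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa < 0)
    stop("kappa must be a single non-negative number")
  mean + kappa * sd
}
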