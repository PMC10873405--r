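# Independent oracles used to freeze or cross-check expected values.
# Each is written directly from the defining formula, independent of the
# package's implementation path.

# closed-form GP posterior for exactly two observations: explicit 2x2
# matrix inversion of the squared-exponential GP equations
gpTwoPointOracle <- function(x1, x2, y1, y2, xstar, l, v, s2, j = 1e-8) {
  k <- function(a, b) v * exp(-0.5 * (a - b)^2 / l^2)
  mu0 <- (y1 + y2) / 2
  K11 <- v + s2 + j; K22 <- v + s2 + j; K12 <- k(x1, x2)
  det <- K11 * K22 - K12^2
  vapply(xstar, function(x) {
    k1 <- k(x, x1); k2 <- k(x, x2)
    a1 <- (K22 * (y1 - mu0) - K12 * (y2 - mu0)) / det
    a2 <- (-K12 * (y1 - mu0) + K11 * (y2 - mu0)) / det
    m <- mu0 + k1 * a1 + k2 * a2
    q1 <- (K22 * k1 - K12 * k2) / det
    q2 <- (-K12 * k1 + K11 * k2) / det
    c(mean = m, sd = sqrt(v - (k1 * q1 + k2 * q2)))
  }, numeric(2))
}

# brute-force marginal-correlation ranking, one feature at a time
sisOracle <- function(X, y) {
  r <- vapply(seq_len(ncol(X)), function(j) {
    xj <- X[, j]
    if (sd(xj) == 0) return(0)
    sum((xj - mean(xj)) * (y - mean(y))) /
      ((length(y) - 1) * sd(xj) * sd(y))
  }, numeric(1))
  order(-abs(r), seq_along(r))
}

# entropy-based mutual information (bits) from a contingency table
miOracle <- function(a, b) {
  H <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  tab <- table(a, b) / length(a)
  H(rowSums(tab)) + H(colSums(tab)) - H(as.vector(tab))
}

# exhaustive greedy MRMR on already-discrete variables
mrmrOracle <- function(B, ycode, nS) {
  p <- ncol(B)
  rel <- vapply(seq_len(p), function(j) miOracle(B[, j], ycode), numeric(1))
  sel <- integer(0)
  for (s in seq_len(nS)) {
    crit <- vapply(seq_len(p), function(i) {
      if (i %in% sel) return(-Inf)
      if (!length(sel)) return(rel[i])
      rel[i] - mean(vapply(sel, function(j) miOracle(B[, i], B[, j]),
                           numeric(1)))
    }, numeric(1))
    sel <- c(sel, which.max(crit))
  }
  sel
}

# small simulated dataset shorthand
tinyDataset <- function(n = 60, p = 30, p0 = 4, seed = 1, ...) {
  simulateDataset(simulationConfig(n = n, p = p, p0 = p0, seed = seed, ...))
}
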