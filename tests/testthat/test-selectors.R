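test_that("split gain matches hand arithmetic on ten fixed cases", {
  GL <- c(2, -3, 0, 5, 1.5, -2.5, 4, 0, -1, 10)
  GR <- c(-2, 1, 0, -5, 2.5, -2.5, 0, 3, -1, -4)
  HL <- c(1, 2, 0.5, 4, 1, 3, 2, 0, 1.5, 8)
  HR <- c(1, 1, 0.5, 4, 2, 3, 0, 2, 1.5, 2)
  lam <- c(1, 0.5, 1, 2, 0, 1, 1, 0.5, 2, 5)
  gam <- c(0, 0.1, 0.3, 1, 0.2, 0, 0.5, 0, 0.25, 2)
  expected <- c(2, 1.461904761905, -0.3, 3.166666666667, -0.179166666667,
                -0.223214285714, -0.5, 0, -0.364285714286, 1.789010989011)
  expect_equal(xgbGain(GL, GR, HL, HR, lam, gam), expected,
               tolerance = 1e-12)
  # no-gradient split and an empty right child both cost exactly gamma
  expect_equal(xgbGain(0, 0, 1, 1, 0.5, 0.7), -0.7)
  expect_equal(xgbGain(3, 0, 2, 0, 1, 0.4), -0.4)
  expect_error(xgbGain(1, 1, -1, 1), "non-negative")
})

test_that("the boosting selector finds a dominant step-function feature", {
  set.seed(14)
  n <- 200; p <- 20
  X <- matrix(rnorm(n * p), n, p)
  y <- ifelse(X[, 7] > 0, 2, -2) + rnorm(n, sd = 0.1)
  r <- selectXgboost(X, y, nS = 5, seed = 3)
  expect_identical(rankedFeatures(r)[1], 7L)

  r0 <- selectXgboost(X, y, nS = 0, seed = 3)
  expect_length(rankedFeatures(r0), 0)

  r2 <- selectXgboost(X, y, nS = 5, seed = 3)
  expect_identical(rankedFeatures(r), rankedFeatures(r2))
  expect_error(selectXgboost(X, rep(1, n), nS = 5), "constant")
})

test_that("screening by correlation agrees with the brute-force sort", {
  d <- tinyDataset(n = 80, p = 15, p0 = 3, seed = 3)
  X <- simX(d)
  y7 <- X[, 7]
  r <- selectSIS(X, y7, nS = 15)
  expect_identical(rankedFeatures(r)[1], 7L)
  expect_equal(selectionScores(r)[1], 1.0, tolerance = 1e-12)

  for (s in 1:100) {
    set.seed(1000 + s)
    Xr <- matrix(rnorm(30 * 15), 30, 15)
    yr <- rnorm(30)
    expect_identical(rankedFeatures(selectSIS(Xr, yr, nS = 15)),
                     as.integer(sisOracle(Xr, yr)))
  }

  # zero-variance features score zero rather than failing
  Xz <- cbind(simX(d)[, 1:4], 0)
  rz <- selectSIS(Xz, simY(d), nS = 5)
  expect_identical(rankedFeatures(rz)[5], 5L)
  expect_equal(selectionScores(rz)[5], 0)
})

test_that("greedy MRMR matches the exhaustive oracle and penalises duplicates", {
  # hand-built discrete toys: copies are picked once, then heavily penalised
  set.seed(9)
  n <- 120
  a <- sample(1:3, n, replace = TRUE)
  b <- a                                  # exact copy of a
  c3 <- sample(1:3, n, replace = TRUE)    # second informative feature
  d4 <- sample(1:3, n, replace = TRUE)
  e5 <- sample(1:3, n, replace = TRUE)
  ycode <- ifelse(a == 1, 1L, ifelse(c3 == 2, 2L, 3L))
  B <- cbind(a, b, c3, d4, e5)
  Xcont <- B + matrix(runif(n * 5, -0.2, 0.2), n, 5)  # jitter keeps ranks
  r <- selectMRMR(Xcont, as.numeric(ycode), nS = 3, nBins = 3)
  expect_true(rankedFeatures(r)[1] %in% c(1L, 2L))    # a copy is picked first
  expect_false(rankedFeatures(r)[2] %in% c(1L, 2L))   # the other copy is not second
  expect_true(3L %in% rankedFeatures(r))

  # exhaustive-greedy agreement on random 5-feature discrete fixtures;
  # balanced category counts make the equal-frequency binning an identity
  for (s in 1:10) {
    set.seed(200 + s)
    Bd <- vapply(1:5, function(j) sample(rep(1:4, 10)), integer(40))
    yd <- sample(rep(1:4, 10))
    got <- rankedFeatures(selectMRMR(Bd + matrix(runif(200, -0.1, 0.1), 40),
                                     as.numeric(yd), nS = 5, nBins = 4))
    expect_identical(got, as.integer(mrmrOracle(Bd, yd, 5)))
  }

  r1 <- selectMRMR(matrix(rnorm(50), 50, 1), rnorm(50), nS = 1)
  expect_identical(rankedFeatures(r1), 1L)

  # independent noise: the first pick's score sits at the discretisation
  # bias level (k-1)^2 / (2 n ln 2) bits
  set.seed(4)
  Xn <- matrix(runif(500 * 8), 500, 8)
  yn <- runif(500)
  rn <- selectMRMR(Xn, yn, nS = 8, nBins = 5)
  bias <- (5 - 1)^2 / (2 * 500 * log(2))
  expect_lt(selectionScores(rn)[1], 4 * bias)
})

test_that("sparse PLS-DA tracks the cross-covariance SVD and finds strong signals", {
  set.seed(11)
  n <- 50; p <- 8
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  # one-component, no-threshold limit: ranking = |first singular vector| order
  r <- selectSPLSda(X, y, nS = p, nCategories = 10, nComponents = 1)
  Yc <- scale(stats::model.matrix(~ 0 + factor(bofs:::discretizeEF(y, 10))),
              center = TRUE, scale = FALSE)
  M <- crossprod(scale(X, center = TRUE, scale = FALSE), Yc)
  u1 <- svd(M)$u[, 1]
  expect_identical(rankedFeatures(r), as.integer(order(-abs(u1))))

  # a single strong driver enters the first component's support
  y1 <- X[, 1] * 3 + rnorm(n, sd = 0.1)
  r1 <- selectSPLSda(X, y1, nS = 2, nCategories = 5, nComponents = 2)
  expect_true(1L %in% rankedFeatures(r1))

  rAll <- selectSPLSda(X, y, nS = p, nCategories = 5, nComponents = 4)
  expect_setequal(rankedFeatures(rAll), seq_len(p))
  expect_error(selectSPLSda(X, y, nS = 2, nComponents = 0))
})

test_that("sparse PLS-DA agrees with an established implementation on a toy", {
  skip_if_not_installed("mixOmics")
  set.seed(15)
  n <- 60; p <- 12
  X <- matrix(rnorm(n * p), n, p)
  yb <- as.numeric(binarizeAtMedian(X[, 3]))  # feature 3 separates the classes
  ours <- rankedFeatures(selectSPLSda(X, yb, nS = 2, nComponents = 1))
  mo <- mixOmics::splsda(X, factor(yb), ncomp = 1, keepX = 2)
  theirs <- which(mo$loadings$X[, 1] != 0)
  expect_true(length(intersect(ours, theirs)) >= 1)
})

test_that("rankings are nested as the requested size grows", {
  d <- tinyDataset(n = 80, p = 25, p0 = 4, seed = 6)
  X <- simX(d); y <- simY(d)
  sel <- list(
    function(ns) rankedFeatures(selectSIS(X, y, ns)),
    function(ns) rankedFeatures(selectMRMR(X, y, ns, nBins = 5)),
    function(ns) rankedFeatures(selectPenalized(X, y / sd(y), 0.1, 1, ns)),
    function(ns) rankedFeatures(selectXgboost(X, y, ns, seed = 2)))
  for (f in sel) {
    r10 <- f(10); r20 <- f(20)
    expect_false(anyDuplicated(r20) > 0)
    expect_identical(r20[seq_along(r10)], r10)
  }
})

test_that("Bayesian-optimized selection uses the stated spaces and stays valid", {
  sp <- selectorSearchSpace("lasso")
  expect_identical(sp@parameters$name, "lambda")
  spE <- selectorSearchSpace("enet")
  expect_setequal(spE@parameters$name, c("lambda", "rho"))
  expect_true(all(spE@parameters$lower > 0 & spE@parameters$upper < 1))

  d <- tinyDataset(n = 60, p = 20, p0 = 3, seed = 2)
  # a one-iteration budget still returns a valid ranked result
  r <- boTunedSelect("lasso", simX(d), simY(d) / sd(simY(d)), nS = 5,
                     nIterations = 1, nCandidates = 50, seed = 3)
  expect_s4_class(r, "SelectionResult")
  expect_length(rankedFeatures(r), 5)
  expect_s4_class(boTrace(r), "BOTrace")
  expect_identical(r@tuner, "BO")
})

test_that("tuned lasso recovers strong signals at least as well as a fixed penalty", {
  wins <- 0L
  for (s in 1:20) {
    d <- simulateDataset(simulationConfig(n = 200, p = 50, p0 = 5,
                                          seed = 300 + s))
    X <- simX(d); ys <- simY(d) / sd(simY(d))
    rBO <- boTunedSelect("lasso", X, ys, nS = 5, nIterations = 10,
                         nCandidates = 100, seed = s)
    rFix <- selectPenalized(X, ys, lambda = 0.5, rho = 1, nS = 5)
    recBO <- recallRate(rankedFeatures(rBO), causalIndices(d))
    recFix <- recallRate(rankedFeatures(rFix), causalIndices(d))
    if (recBO >= recFix) wins <- wins + 1L
  }
  expect_gte(wins, 12L)  # >= 60% of 20 seeds
})
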