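## fit one downstream predictor on the selected training features and
## return predictions on the test features; fixed, documented settings
fitPredictor <- function(predictor, Xtr, ytr, Xte, seed) {
  switch(predictor,
    svm = {
      fit <- e1071::svm(Xtr, ytr)
      as.numeric(predict(fit, Xte))
    },
    lasso = {
      cv <- withSeed(seed, glmnet::cv.glmnet(Xtr, ytr, alpha = 1,
                                             nfolds = 5L))
      as.numeric(predict(cv, Xte, s = "lambda.min"))
    },
    rf = {
      fit <- withSeed(seed, randomForest::randomForest(Xtr, ytr,
                                                       ntree = 500L))
      as.numeric(predict(fit, Xte))
    },
    gbm = {
      withSeed(seed, {
        dtr <- xgboost::xgb.DMatrix(Xtr, label = ytr, nthread = 1L)
        fit <- xgboost::xgb.train(
          params = list(objective = "reg:squarederror", eta = 0.3,
                        max_depth = 6, nthread = 1L),
          data = dtr, nrounds = 100L, verbose = 0)
        as.numeric(predict(fit, xgboost::xgb.DMatrix(Xte, nthread = 1L)))
      })
    },
    stop("unknown predictor: ", predictor))
}

#' Run the downstream prediction study
#'
#' The train/test protocol used to judge selectors by what they feed a
#' prediction model: per repetition, split the samples into a training
#' fraction and a held-out test set, run each selector (and its tuning) on
#' the training data only, fit each predictor on the selected training
#' features, and score Pearson correlation and mean squared error on the
#' test set. Selector tuning is redone within every repetition.
#'
#' @param X numeric matrix (samples by features) or a
#'   [SimulatedDataset-class].
#' @param y continuous outcome vector (taken from the dataset when `X` is
#'   one).
#' @param selectors data.frame with columns `method`, `tuner`.
#' @param predictors character vector among `"svm"`, `"lasso"`, `"rf"`,
#'   `"gbm"`.
#' @param nS number of features each selector passes on.
#' @param splitFraction training fraction (default 0.7).
#' @param repeats number of random splits (default 100).
#' @param nIterations Bayesian-optimization iterations for BO selectors.
#' @param baseSeed integer master seed.
#' @return data.frame with one row per (selector, predictor, repetition):
#'   columns `method`, `tuner`, `predictor`, `repetition`, `n_s`,
#'   `pearson_r`, `mse`, `error`. A constant test outcome yields `NA`
#'   correlation.
#' @export
runPredictionStudy <- function(X, y = NULL,
                               selectors = data.frame(method = "lasso",
                                                      tuner = "BO"),
                               predictors = c("svm", "lasso", "rf", "gbm"),
                               nS = 100L, splitFraction = 0.7,
                               repeats = 100L, nIterations = 100L,
                               baseSeed = 1L) {
  if (is(X, "SimulatedDataset")) { y <- simY(X); X <- simX(X) }
  stopifnot(nrow(X) == length(y), splitFraction > 0, splitFraction < 1)
  n <- nrow(X)
  repSeeds <- deriveSeeds(baseSeed, repeats)
  out <- list()
  for (rep_ in seq_len(repeats)) {
    trIdx <- withSeed(repSeeds[rep_],
                      sample.int(n, round(splitFraction * n)))
    Xtr <- X[trIdx, , drop = FALSE]; ytr <- y[trIdx]
    Xte <- X[-trIdx, , drop = FALSE]; yte <- y[-trIdx]
    for (s in seq_len(nrow(selectors))) {
      meth <- selectors$method[s]; tun <- selectors$tuner[s]
      sel <- tryCatch(
        selectFeatures(Xtr, ytr, method = meth, tuner = tun, nS = nS,
                       nIterations = nIterations,
                       seed = repSeeds[rep_] %% 1000000L + s),
        error = function(e) e)
      for (pd in predictors) {
        row <- data.frame(method = meth, tuner = tun, predictor = pd,
                          repetition = rep_, n_s = nS,
                          pearson_r = NA_real_, mse = NA_real_,
                          error = NA_character_)
        if (inherits(sel, "error")) {
          row$error <- conditionMessage(sel)
        } else {
          feats <- rankedFeatures(sel)
          ans <- tryCatch({
            pred <- fitPredictor(pd, Xtr[, feats, drop = FALSE], ytr,
                                 Xte[, feats, drop = FALSE],
                                 seed = repSeeds[rep_] %% 1000000L + s)
            r <- if (sd(yte) > 0 && sd(pred) > 0)
              cor(pred, yte) else NA_real_
            c(r, mean((pred - yte)^2))
          }, error = function(e) e)
          if (inherits(ans, "error")) row$error <- conditionMessage(ans)
          else { row$pearson_r <- ans[1L]; row$mse <- ans[2L] }
        }
        out[[length(out) + 1L]] <- row
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
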