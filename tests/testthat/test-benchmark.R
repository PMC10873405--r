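test_that("recall rate is the causal-overlap fraction", {
  expect_identical(recallRate(1:100, 1:100), 1)
  expect_identical(recallRate(101:200, 1:100), 0)
  expect_identical(recallRate(c(1:50, 1001:1050), 1:100), 0.5)
  expect_error(recallRate(1:5, integer(0)), "non-empty")
})

test_that("the study produces one row per cell and is reproducible", {
  tab <- runSimulationStudy(p0Grid = 4, nsGrid = c(4, 8),
                            methods = data.frame(method = "sis",
                                                 tuner = "none"),
                            repeats = 2, n = 60, p = 30, baseSeed = 5)
  expect_identical(nrow(tab), 4L)  # 1 p0 x 2 ns x 1 method x 2 reps
  expect_true(all(tab$recall >= 0 & tab$recall <= 1))

  tab2 <- runSimulationStudy(p0Grid = 4, nsGrid = c(4, 8),
                             methods = data.frame(method = "sis",
                                                  tuner = "none"),
                             repeats = 2, n = 60, p = 30, baseSeed = 5)
  expect_identical(tab$recall, tab2$recall)

  # everything selected means everything recovered
  full <- runSimulationStudy(p0Grid = 4, nsGrid = 30,
                             methods = data.frame(method = "sis",
                                                  tuner = "none"),
                             repeats = 1, n = 60, p = 30, baseSeed = 2)
  expect_identical(full$recall, 1)

  # recall is monotone in the selection size within a repetition
  mono <- runSimulationStudy(p0Grid = 6, nsGrid = c(3, 6, 12, 24),
                             methods = data.frame(method = "sis",
                                                  tuner = "none"),
                             repeats = 3, n = 80, p = 40, baseSeed = 9)
  for (r in unique(mono$repetition)) {
    sub <- mono[mono$repetition == r, ]
    expect_true(all(diff(sub$recall[order(sub$n_s)]) >= -1e-12))
  }
})

test_that("selector failures are recorded as NA rows and the run continues", {
  tab <- runSimulationStudy(p0Grid = 4, nsGrid = 100,  # nS > p: must fail
                            methods = data.frame(
                              method = c("sis", "mrmr"),
                              tuner = c("none", "none")),
                            repeats = 1, n = 40, p = 20, baseSeed = 1)
  expect_identical(nrow(tab), 2L)
  expect_true(all(is.na(tab$recall)))
  expect_true(all(!is.na(tab$error)))
})

test_that("the scale factor shrinks the design consistently", {
  tab <- runSimulationStudy(p0Grid = 8, nsGrid = c(8, 16),
                            methods = data.frame(method = "sis",
                                                 tuner = "none"),
                            repeats = 1, n = 120, p = 60, scale = 0.5,
                            baseSeed = 3)
  expect_identical(sort(unique(tab$n_s)), c(4L, 8L))
  expect_identical(unique(tab$p0), 4L)
})

test_that("aggregation averages cells, tracks NA exclusion and flags empty cells", {
  rec <- data.frame(method = "sis", tuner = "none", p0 = 4L,
                    n_s = c(8L, 8L, 8L, 16L),
                    recall = c(0.2, 0.4, NA, NA))
  sm <- summarizeRecords(rec)
  r8 <- sm[sm$n_s == 8L, ]
  expect_equal(r8$mean_recall, 0.3)
  expect_identical(as.integer(r8$n_used), 2L)
  expect_identical(as.integer(r8$n_total), 3L)
  expect_true(sm$all_na[sm$n_s == 16L])

  one <- summarizeRecords(rec[1, ])
  expect_equal(one$mean_recall, 0.2)
  expect_equal(one$sd_recall, 0)

  p <- plotRecall(sm)
  expect_s3_class(p, "ggplot")
})

test_that("ordering sanity on linear data: tuned lasso beats redundancy filtering", {
  tab <- runSimulationStudy(
    p0Grid = 100, nsGrid = 100,
    methods = data.frame(method = c("lasso", "mrmr"),
                         tuner = c("CV", "none")),
    effectModel = "linear", repeats = 3, n = 500, p = 1000, baseSeed = 17)
  sm <- summarizeRecords(tab)
  expect_gte(sm$mean_recall[sm$method == "lasso"],
             sm$mean_recall[sm$method == "mrmr"])
})

test_that("the prediction stage scores held-out accuracy per selector and predictor", {
  d <- simulateDataset(simulationConfig(n = 120, p = 40, p0 = 4,
                                        noiseSd = 0.05, seed = 21))
  tab <- runPredictionStudy(d, selectors = data.frame(
    method = c("sis", "lasso"), tuner = c("none", "CV")),
    predictors = "lasso", nS = 8, repeats = 3, baseSeed = 11)
  expect_identical(nrow(tab), 6L)  # 2 selectors x 1 predictor x 3 reps
  expect_true(all(tab$pearson_r >= -1 & tab$pearson_r <= 1, na.rm = TRUE))
  expect_true(all(tab$mse >= 0, na.rm = TRUE))

  # near-noise-free linear data with a linear predictor: near-perfect fit
  expect_gt(mean(tab$pearson_r[tab$method == "sis"]), 0.95)

  # outcome permuted independently of the features: correlation near zero
  dn <- d
  dn@y <- withr::with_seed(5, sample(simY(d)))
  tabNull <- runPredictionStudy(dn, selectors = data.frame(
    method = "sis", tuner = "none"),
    predictors = "svm", nS = 8, repeats = 4, baseSeed = 12)
  expect_lt(abs(mean(tabNull$pearson_r, na.rm = TRUE)), 0.35)
})

test_that("datasets round-trip through the TSV interface", {
  d <- simulateDataset(simulationConfig(n = 12, p = 6, p0 = 2, seed = 8))
  prefix <- file.path(tempdir(), "roundtrip")
  paths <- writeSimulatedDataset(d, prefix)
  X <- readFeatureMatrix(paths[1])
  expect_equal(unname(X), unname(simX(d)), tolerance = 1e-12)
  y <- readPhenotype(paths[2], samples = rownames(X))
  expect_equal(unname(y), simY(d), tolerance = 1e-12)
  expect_identical(as.integer(readLines(paths[3])), causalIndices(d))
  cfg <- jsonlite::read_json(paths[4])
  expect_identical(cfg$p0, 2L)
})
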