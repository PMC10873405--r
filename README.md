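# bofs

Does Bayesian optimization of hyper-parameters make feature *selection*
better, not just prediction? `bofs` is an R package for answering that
question on high-dimensional data of the kind produced by expression
profiling: thousands of features, hundreds to a thousand samples, and a
small unknown causal subset. It is aimed at biostatisticians and
methodologists who want a controlled, fully seeded benchmark of selector
tuning strategies, and at analysts who want to run the same
select-then-predict protocol on their own sample × feature matrices.

## What it implements

* **Synthetic data with known truth** — covariates $X_i \sim N(0, I_p)$;
  a sparse linear outcome $Y = Xw + \varepsilon$ with effects
  $w_j = (-1)^{U_j}(5\log n/\sqrt n + |Z_j|)$ (every signal above the
  sure-screening detectability floor), or a non-linear outcome
  $Y_i = \sum_{j\le p_1}\sin X_{ij} + 1.8\sum_{j > p_0 - p_1}\cos X_{ij}
  + \varepsilon_i$; binary outcomes by median dichotomisation.
* **A Gaussian-process Bayesian optimizer** with upper-confidence-bound
  acquisition $\mathrm{AC}(x) = \mu(x) + \kappa\sigma(x)$, uniform
  candidate sampling and a fixed squared-exponential kernel.
* **Six selectors** — lasso, elastic net
  ($f_w + \lambda\rho\|w\|_1 + \lambda(1-\rho)\|w\|_2^2/2$), gradient
  boosting (ranked by split gain), sure independence screening,
  minimum-redundancy-maximum-relevance
  ($MI(y,x_i) - \overline{MI}(x_i, S)$), and sparse PLS discriminant
  analysis ($\max \mathrm{cov}^2(X\alpha, Y\beta)$ on a discretised
  response) — each under Bayesian-optimized, AIC, cross-validated or
  default tuning where hyper-parameters exist.
* **A benchmark layer** — recall rate $|S\cap C|/|C|$ across causal-set
  sizes, selection sizes and repetitions, plus a 70/30
  select-train-predict stage (SVM, lasso, random forest, gradient
  boosting) scored by Pearson correlation and mean squared error.

## A worked example

```r
library(bofs)

## a small dataset with 10 causal features among 300
d <- simulateDataset(simulationConfig(n = 300, p = 300, p0 = 10, seed = 42))
d
#> SimulatedDataset: 300 samples x 300 features, 10 causal ( linear / continuous )

## Bayesian-optimized lasso: tune the penalty, then rank features
sel <- selectFeatures(d, method = "lasso", tuner = "BO", nS = 10,
                      nIterations = 20, seed = 1)
sel
#> SelectionResult: BO -tuned lasso ranking of 10 features (requested 10 )
#>  top: 8 6 2 5 9
tunedParams(sel)$lambda
#> [1] 0.01423498
recallRate(rankedFeatures(sel), causalIndices(d))
#> [1] 1

## compare tuning strategies on a small, hard recall study
tab <- runSimulationStudy(p0Grid = 40, nsGrid = c(40, 80),
                          methods = data.frame(method = "lasso",
                                               tuner = c("BO", "CV")),
                          repeats = 2, n = 100, p = 500,
                          boIterations = 10, baseSeed = 3)
summarizeRecords(tab)[, c("method", "tuner", "n_s", "mean_recall")]
#>   method tuner n_s mean_recall
#> 1  lasso    BO  40      0.5125
#> 3  lasso    BO  80      0.6375
#> 2  lasso    CV  40      0.4875
#> 4  lasso    CV  80      0.6750
```

The recall numbers are the fraction of the 40 truly causal features
recovered at each selection size. At this tiny scale the two tuners trade
places within Monte-Carlo noise; the systematic differences between them
emerge in the half-scale benchmark that `scripts/acceptance.R` runs,
where the cross-validated baseline plateaus at its fitted support while
the Bayesian-optimized variant keeps climbing.

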