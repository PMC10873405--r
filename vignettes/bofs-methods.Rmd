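---
title: "Bayesian-optimized feature selection: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian-optimized feature selection: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bofs)
```

## The question the package addresses

Feature selection on high-dimensional molecular data (tens of thousands of
gene-expression probes, hundreds to a thousand samples) is routinely done
with methods whose behaviour depends on hyper-parameters: the penalty
strength of the lasso and elastic net, or the many knobs of gradient
boosting. `bofs` provides the machinery to ask, under controlled and fully
reproducible conditions, whether tuning those hyper-parameters by Bayesian
optimization improves the *selection* itself — measured as the recall of
truly causal features — rather than only downstream prediction.

The package has four layers: a synthetic-data generator with known causal
structure; a generic Gaussian-process Bayesian optimizer; six feature
selectors under four tuning strategies; and a benchmark layer that produces
recall tables, plots and a train/test prediction stage.

## The synthetic-data generator

Covariates are i.i.d. standard normal, $X_i \sim N(0, I_p)$, with defaults
$n = 1000$ samples and $p = 5000$ features. The number of causal features
$p_0$ is varied over $\{100, 200, 500, 1000\}$.

**Linear model.** $Y_i = X_{i,1:p_0} w + \varepsilon_i$ with
$\varepsilon_i \sim N(0, 1)$ and effects

$$w_j = (-1)^{U_j}\left(\frac{5\log n}{\sqrt n} + |Z_j|\right),
\qquad U_j \sim \mathrm{Ber}(0.5),\ Z_j \sim N(0,1),$$

the classical sure-screening design: every effect magnitude exceeds the
detectability floor $5\log(n)/\sqrt n$ (natural logarithm — the convention
of the screening literature), and signs are fair coin flips.

**Non-linear model.** The causal set of even size $p_0$ is split in half,
$p_1 = p_0/2$:

$$Y_i = \sum_{j=1}^{p_1} \sin(X_{ij})
      + 1.8 \sum_{j=p_0-p_1+1}^{p_0} \cos(X_{ij}) + \varepsilon_i,
\qquad \varepsilon_i \sim N(0, 0.1^2).$$

The sine half retains a linear trace ($\mathrm{E}[X\sin X] = e^{-1/2}$),
while the cosine half is invisible to any linear marginal statistic
($\mathrm{E}[X\cos X] = 0$) — which is exactly what makes this model hard
for penalized linear selectors.

**Binary outcomes** dichotomise the noisy continuous outcome at its sample
median, with values equal to the median mapped to class 1; classes are
balanced to within one sample. Thresholding is applied after noise is
added, since the continuous outcome is defined noise-inclusive.

Causal features occupy the first $p_0$ columns by default (the generating
equations index them as a prefix); `causalPlacement = "random"` scatters
them for robustness checks. One seed per dataset drives covariates,
effects and noise through independently derived substreams
(`deriveSeeds()`), so a repetition is reproducible in isolation.

What the generator deliberately does *not* emulate: correlated covariate
blocks, interaction/epistatic effects, heavy-tailed noise, batch structure.
Passing benchmarks here therefore speaks to the tuning question under
idealised independence, not to every property of real expression data.

## The Bayesian optimizer

`boOptimize()` maximises a black-box objective over a box-bounded space.
After `nInitial = 5` uniform evaluations, each iteration draws
`nCandidates = 500` fresh uniform candidates, fits a Gaussian-process
surrogate to all evaluations so far, scores the candidates by the upper
confidence bound

$$\mathrm{AC}(x) = \mu(x) + \kappa\,\sigma(x),$$

and evaluates the true objective at the acquisition argmax. The UCB rule
balances exploitation (the posterior mean $\mu$) against exploration (the
posterior uncertainty $\sigma$) through $\kappa$.

Numerical choices, all fixed and documented rather than learned:

* **Kernel.** Squared-exponential with unit signal variance and
  lengthscale 0.2 on inputs rescaled to $[0,1]^d$ (log-scaled parameters
  are rescaled on their log axis). Objectives are standardised to zero
  mean and unit variance before each surrogate fit. No marginal-likelihood
  kernel learning: a fixed kernel keeps runs bit-reproducible and cheap.
* **Prior mean.** The mean of the observed objectives; far from all
  observations the posterior reverts to it with sd $\sqrt{v}$.
* **Stability.** Observation-noise variance $10^{-6}$ plus jitter
  $10^{-8}$ on the covariance diagonal; posterior variances are clipped at
  zero.
* **$\kappa = 2$** by default — a standard moderately explorative setting;
  it is exposed as an argument.
* **Tie-breaking.** The acquisition argmax takes the lowest candidate
  index, so a run is a pure function of its seed.
* Maximisation convention throughout; loss objectives are negated by the
  caller.

An alternative reading of "identifying promising regions" would shrink a
trust region over iterations; we implement the more literal (and simpler)
scheme of acquisition-argmax over fresh uniform candidates, which also
matches the uniform-sampling description of the search.

## The selectors and their tuning variants

All selectors return a `SelectionResult`: a ranking of `nS` feature
indices with scores, the hyper-parameters actually used, and (for BO) the
optimization trace.

**Lasso / elastic net.** The objective is the elastic net
$f_w(x) + \lambda\rho\|w\|_1 + \tfrac{\lambda(1-\rho)}{2}\|w\|_2^2$
($\rho = 1$ is the lasso), fitted by `glmnet`, whose penalty definition
and $1/(2n)$ loss scaling match this form exactly. Continuous outcomes are
rescaled to unit variance before penalized fits so that the $(0,1)$ search
range for $\lambda$ spans the whole path from dense to empty models on the
correlation scale. Tier 1 of the ranking is the nonzero coefficients by
magnitude. When the fitted support is smaller than `nS`, the BO and
untuned variants fill the remaining slots with the unselected features by
absolute marginal correlation (tier 2); the AIC/CV/default baselines do
*not* fill and simply plateau at their support — mirroring how the
baseline recall curves flatten once the criterion has fixed the model
size, while the tuned variants keep climbing.

**Tuning.** `AIC` minimises $n\log(\mathrm{RSS}/n) + 2\,df$ (Gaussian) or
deviance $+\,2\,df$ (binomial) over a 50-point log-spaced grid in
$(10^{-3}, 1]$; `CV` minimises seeded 10-fold held-out loss over the same
grid (ties to the sparser penalty); `DE` uses fixed recorded defaults
($\lambda = 0.01$, $\rho = 0.5$ for the elastic net); `BO` searches
$\lambda \in (0,1)$ (and $\rho \in (0,1)$ for the elastic net) maximising
mean 5-fold cross-validated performance — negative squared error for
continuous outcomes, accuracy for binary — with 100 iterations at full
scale. Five folds inside the optimizer (versus ten for the CV baseline)
keep the objective affordable, since it is evaluated at every iteration.

**Gradient boosting.** Backed by `xgboost`; features are ranked by total
split gain, the per-split objective improvement
$\tfrac12[G_L^2/(H_L+\lambda) + G_R^2/(H_R+\lambda) -
(G_L+G_R)^2/(H_L+H_R+\lambda)] - \gamma$, whose arithmetic `xgbGain()`
exposes for audit. The BO space covers learning rate
$[0.01, 0.3]$ (log), depth $\{2..10\}$, row/column subsampling
$[0.5, 1]$, $\gamma \in [0,5]$ and $\lambda \in [0,10]$, with 100 rounds
fixed — standard ranges for the knobs that matter most; unsplit features
are filled by marginal correlation as above.

**SIS.** Ranking by absolute Pearson correlation with the outcome;
zero-variance features score 0; ties go to the lower index.

**MRMR.** Greedy forward selection maximising
$MI(y, x_i) - \tfrac{1}{|S|}\sum_{j \in S} MI(x_i, x_j)$, the mean
redundancy over the already-selected set $S$. Mutual information is
estimated on equal-frequency discretised variables (10 bins by default;
binary outcomes used as two classes) — the criterion presumes discrete
MI and the estimation scheme is otherwise open, so the simplest unbiased
choice is used and its small-sample bias level
$(k-1)^2 / (2n\ln 2)$ bits is checked in the tests.

**sPLSda.** The response is discretised into 50 equal-frequency classes
(a standard device for running a discriminant method on a continuous
phenotype) and one-hot encoded. Each component takes the leading
singular-vector pair of the centred cross-covariance $X^\top Y$ —
maximising $\mathrm{cov}^2(X\alpha, Y\beta)$ under unit norms — then
soft-thresholds the feature-side vector to a per-component sparsity of
$\lceil nS / 5 \rceil$ (5 components by default; the one-component
objective is canonical, multi-component behaviour is our documented
choice), deflates both matrices by the realised score, and repeats.
Features are ranked by first entry into a support, ties by loading
magnitude.

## The benchmark layer

`runSimulationStudy()` crosses causal-set sizes, selector variants,
selection sizes and repetitions; each repetition simulates, tunes and
ranks once at the largest selection size, then reads every smaller
selection size off the ranking prefix (the rankings are nested by
construction). Recall is $|S \cap C|/|C|$. Per-cell seeds are derived
deterministically from the base seed, so any execution order gives
identical tables; failures become `NA` rows with an error tag. A single
`scale` factor shrinks $n$, $p$, $p_0$, the selection sizes and the BO
budget jointly; repetitions are an explicit argument. The tests and the
acceptance script use scale 0.5 (so $n = 500$, $p = 2500$, $p_0 = 500$,
selection sizes 50 and 500) with 5 repetitions and 50 BO iterations —
sizes chosen so a desk run finishes in minutes while preserving the
$n : p : p_0$ geometry of the full design.

`runPredictionStudy()` implements the downstream protocol used for real
expression matrices: repeatedly split 70/30, select on the training split
only, fit SVM, lasso (`cv.glmnet`'s standard workflow), random forest and
gradient boosting on the selected training features with fixed documented
settings — only the selectors are tuned, never the predictors — and score
Pearson correlation and mean squared error on the held-out split.
Selector tuning is redone inside every repetition, the reading of
"repeat the whole process" that avoids information leaking across splits.

## Known limitations

* The CV loss surface of the penalized selectors is extremely flat in
  high dimensions, so the CV-chosen penalty (and hence baseline recall at
  large selection sizes) has substantial fold-assignment variance; the
  benchmark averages over repetitions but desk-scale means remain noisy.
* The optimizer is serial and assumes a cheap-enough objective; no batch
  acquisition or early stopping.
* MI estimation by fixed-width equal-frequency binning is biased upward
  at small $n$; rankings are compared within a dataset, where the bias is
  common to all features.
* The half-scale benchmark preserves design geometry but not effect
  geometry exactly: the detectability floor depends on $n$, so scaled
  recalls sit systematically below full-scale ones, and comparisons
  should be read as orderings and gaps, not absolute levels.
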