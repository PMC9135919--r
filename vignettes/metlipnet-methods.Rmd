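---
title: "Covariate-specific metabolite-lipid association networks: methods and design"
author: "MetLipNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate-specific metabolite-lipid association networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MetLipNet)
```

## The analysis problem

Serum NMR metabolomics panels in aging cohorts quantify a few dozen small
metabolites together with a large battery of lipoprotein main parameters and
sub-fractions. The correlation structure among these concentrations — the
*association network* — carries information that individual concentrations do
not: a rewiring of the network between two groups (women vs men, diseased vs
not) can indicate re-modulation of the underlying metabolism even when mean
levels barely move. MetLipNet implements a complete workflow for this style of
analysis:

1. **Covariate signal extraction** — isolate, per feature, the part of the
   concentration associated with one clinical covariate, adjusting for the
   rest;
2. **PCLRC network inference** — robust Spearman-correlation networks with
   resampled CLR background filtering;
3. **Differential connectivity analysis** — per-node comparison of two
   group-specific networks with a permutation null and FDR control;
4. **COVSCA** — simultaneous decomposition of a large collection of
   association matrices into a few shared rank-1 prototypes, with a t-SNE
   embedding of the resulting scores for cluster visualisation.

A seeded synthetic cohort generator with planted ground truth makes every
stage testable without access to any cohort data.

## Covariate signal extraction

Let $Y^{(p)}$ be the $n \times 1$ concentration vector of feature $p$ and
$X$ the $n \times M$ clinical covariate matrix. For a target covariate $m$,
each feature is regressed on all standardized covariate main effects plus the
first-order interactions of $X_m$ with every other covariate, and the
extracted signal keeps only the $X_m$-involving terms:

$$\hat Y^{(p)} = \hat\beta^{(p)} X_m + \sum_{j \ne m} \hat\eta_j^{(p)}\,
  X_m \circ X_j .$$

Because the full design has about $2M$ columns (at $M = 101$ covariates, over
200) against cohorts of a few hundred subjects, ordinary least squares is
near- or under-determined. Estimation therefore uses lasso-penalized least
squares with the penalty chosen by 10-fold cross-validation
(`glmnet::cv.glmnet`, folds fixed by the seed); an unpenalized mode exists
for small well-determined problems and refuses rank-deficient designs.
Interactions are restricted to first order with the target covariate only;
covariates are z-scored before forming products, and constant design columns
are dropped. Extraction is run within group (sex), since every downstream
network is group-specific.

Repeating the extraction over all $M$ covariates yields $M$ signal matrices
per group — each an $n \times P$ data set carrying the part of the
concentrations associated with one clinical variable.

## PCLRC network inference

Association is measured by Spearman correlation (Pearson on average ranks;
constant columns yield zero correlations with a warning). The probabilistic
context likelihood of relatedness on correlation (PCLRC) turns a correlation
matrix into per-edge retention probabilities:

* for each of `nIterations` (default 1000) iterations, draw
  `subsampleFraction` (default 0.75) of the samples without replacement;
* compute the Spearman matrix and its CLR scores: with $s = |R|$ and zero
  diagonal, each edge gets $z_i = \max\{0, (s_{ij} - \mu_i)/\sigma_i\}$
  against the mean and SD of row $i$'s off-diagonal background, symmetrised
  as $\sqrt{z_i^2 + z_j^2}$ (the population SD is used; a zero background SD
  maps to a zero score);
* mark the top `keepFraction` (default 0.30) of edges by CLR score, ties at
  the cutoff included;
* the retention probability of an edge is the fraction of iterations in
  which it was marked.

The filtered network keeps the *signed* correlation of edges whose
probability reaches `probabilityThreshold` (default 0.90, ties retained):

$$ a_{ij} = \begin{cases} r_{ij} & p_{ij} \ge 0.90 \\ 0 & p_{ij} < 0.90.
\end{cases}$$

The defaults above are the published defaults of the PCLRC algorithm; all are
exposed in `pclrcConfig()`. The per-iteration kernel is implemented in C++
for speed; subsample indices are drawn in R, so results are reproducible from
the R random number generator, and the test suite asserts exact agreement
between the C++ kernel and the plain-R reference path
(`spearmanMatrix()`, `clrScores()`).

Exports (GraphML via igraph, three-column edge lists) accept a display
threshold on $|r|$ (conventionally 0.6) that restricts what is drawn without
altering the stored network.

## Differential connectivity

The connectivity of node $i$ in a weighted network is
$\chi_i = \sum_{j \ne i} |a_{ij}|$, which for absolute-correlation weights
ranges between 0 and $P - 1$. (An equivalent convention sums the full row of
the unfiltered unit-diagonal matrix and subtracts one; the full-row form is
used throughout since the downstream statistics build on it.) The
differential connectivity between group networks $A$ and $B$ is
$\Delta_i = \chi_i^A - \chi_i^B$.

Significance is assessed by a column-permutation test: in each of $k$
(default 100) replicates, every column of each group's data matrix is
independently permuted — preserving column means and variances while
destroying all between-column association — both networks are rebuilt with
the same inference settings, and the permuted $\Delta_{i,k}$ recorded. The
P-value is the strict exceedance rate

$$P_i = \frac{1 + \#\left(|D_i| > |\Delta_i|\right)}{k},$$

so the smallest attainable value is $1/k$ and ties count as non-exceedance.
Benjamini–Hochberg adjustment is applied across the $P$ features
(`stats::p.adjust`; the test suite checks it against a brute-force step-up
oracle). Permutation replicates may rebuild networks with a reduced PCLRC
iteration count (`permIterations`) for tractability; the observed networks
always use the full configured settings.

For a *category* of networks (e.g. all disease-specific networks),
`pairwiseSignificanceFrequency()` runs the permutation test on every
unordered pair and retains the features significant (adjusted $P \le 0.05$)
in strictly more than 70% of the comparisons. Both thresholds are arguments.

### What the permutation null does and does not control

The column permutation tests the null hypothesis of *no association among
features*. On data that satisfy it, the observed and permuted statistics are
exchangeable and the test is calibrated — the acceptance suite verifies that
the raw type-I rate on null cohorts stays inside the 95% binomial band
around 0.05. On data containing strong persistent correlation blocks,
however, the permutation null is *narrower* than the sampling distribution
of $\chi$ (the null destroys the blocks entirely), and nodes inside stable
blocks can reach small P-values from sampling noise alone: in pilot runs
with all features in blocks at $\rho = 0.85$, most unperturbed block members
were flagged. This anti-conservativeness is a property of the published
permutation scheme, and users comparing two groups whose *shared* structure
is strong should read per-node P-values as measures of departure from
feature independence, not from equality of the two networks. Accordingly,
the package's calibration experiment uses independent features, and the
recovery experiment plants its rewired block against an otherwise
unstructured background.

## COVSCA

A set of $K$ association matrices (filtered adjacencies with the unit
diagonal restored; a raw-correlation mode exists) is modeled as

$$ S_k \approx \sum_{l=1}^{L} c_{kl}\, z_l z_l^{\mathsf T}, \qquad
   c_{kl} \ge 0,\ \|z_l\| = 1, $$

with $L = 3$ rank-1 prototypes by default (higher prototype ranks are out of
scope). Fitting alternates two exact subproblem solutions, so the loss is
non-increasing (asserted by the class validity on every fit):

* **weights**: per matrix, nonnegative least squares on the vectorised
  prototypes (`pracma::lsqnonneg`);
* **loadings**: each $z_l$ is the dominant eigenvector of the weighted
  residual $\sum_k c_{kl} (S_k - \sum_{m \ne l} c_{km} z_m z_m^{\mathsf T})$.

The first start takes the top eigenvectors of the mean matrix; the remaining
of `nRestarts` (default 10) starts are random orthonormal bases, and the best
run is kept. Convergence is declared when the relative loss change falls
below `tol` (default 1e-9) within `maxIter` (default 500) iterations;
otherwise the best iterate is returned with a warning — ALS converges only
linearly when prototypes are nearly collinear. Loadings have a sign
indeterminacy ($z_l$ and $-z_l$ fit identically); each is normalised so its
largest-magnitude entry is positive, and comparisons use absolute Tucker
congruence after the best component matching (`tuckerCongruence()`).
Goodness-of-fit is $100\,(1 - \sum_k \|S_k - \hat S_k\|_F^2 / \sum_k
\|S_k\|_F^2)$, overall and per matrix. The diagonal of $S_k$ is included in
the fit.

Each network becomes a point in the $L$-dimensional score space; row norms of
the loading matrix rank features by their importance in shaping network
differences. For visualisation, an exact t-SNE (per-point bandwidths
calibrated to the target perplexity by bisection, Student-t low-dimensional
kernel, gradient descent with momentum and early exaggeration) embeds the
scores in 2-D; it is deterministic given the seed and suits the small number
of networks involved ($K$ of order $10^2$, so the exact $O(K^2)$ algorithm
is appropriate). The perplexity must satisfy perplexity $< (K-1)/3$
(default 15; reduced problems need smaller values, and the pipeline picks
$\min(15, (K-1)/3 - 0.01)$ when unset).

## Preprocessing

Mirroring standard practice for clinical covariate batteries:

* covariates with 25% or more missing data are dropped (strictly less than
  25% missing is required to retain a column);
* remaining missing covariate values are imputed by iterative random forests
  (missForest-style): mean/mode initialisation, columns visited in order of
  increasing missingness, each incomplete column regressed (continuous) or
  classified (dichotomous) on all others with 100 trees (`ranger`), sweeps
  repeated until the change in imputed values stops decreasing or 10
  iterations; observed entries are never modified; deterministic given the
  seed. Imputation runs on the pooled cohort by default (the group split is
  applied afterwards), since missingness patterns in clinical covariates are
  rarely group-specific; per-group imputation simply means running the
  function per group.
* all continuous variables are natural-log transformed (an offset handles
  zeros; nonpositive values with a zero offset are an error naming the
  column). Dichotomous 0/1 covariates are exempt — a log of a 0/1 indicator
  is undefined at 0 and a monotone transform of the two values carries no
  information. Since the log is strictly monotone, Spearman-based networks
  are unaffected by this choice; it matters only for the regression stage.
* flagged samples (e.g. failed spectral quality control) are excluded by an
  explicit ID list.

## The synthetic cohort generator

`generateCohort()` emulates the statistical structure this analysis assumes,
with defaults matching the targeted study conditions: two groups of 259 and
96 subjects, $P = 134$ features (20 metabolites + 114 lipid fractions),
$M = 101$ covariates split 20/5/13/12/51 across the five categories
(diseases, familiarity, drugs, risk factors, bio-humoral), and under-25%
covariate missingness.

* **Features**: a Gaussian copula with block covariance — features split
  into blocks with a common within-block association given on the Spearman
  scale and mapped to the latent Pearson scale via
  $\rho_{latent} = 2 \sin(\pi \rho_S / 6)$ — exponentiated to log-normal
  margins so that the pipeline's log transform is exercised nontrivially.
* **Rewiring**: rewired features are singletons in group A and form one new
  common block in group B. This makes the set of features whose connectivity
  truly differs exactly equal to `rewiredNodes`: moving nodes between two
  equal-sized existing blocks would leave their connectivity unchanged
  (undetectable by construction) while changing the connectivity of
  non-rewired block members, corrupting the ground truth.
* **Covariates**: dichotomous columns are thresholded latent Gaussians with
  prevalences drawn once per covariate (shared across groups); continuous
  columns are log-normal. Planted covariate effects add
  $\beta \times$ (standardized covariate) to the latent log-concentrations
  of the chosen features. Missingness is injected completely at random into
  the covariates only.

The generator does **not** simulate NMR spectra, quantification error,
realistic lipoprotein sub-fraction physiology, heavy-tailed or skewed
clinical distributions, informative missingness, or covariate-covariate
dependence beyond chance. Passing tests therefore demonstrate that the
algorithms recover the structure they model under clean conditions — not
that any particular biological cohort satisfies those conditions.

`generateCovscaSet()` builds exact low-rank symmetric matrix sets (plus
optional symmetric Gaussian noise) for validating the COVSCA fitter against
known weights and loadings.

## The pipeline

`runPipeline()` executes simulate (or input validation) → preprocess →
extract → infer → diffnet → covsca → embed. Stages exchange data through CSV
files in the output directory, so runs are resumable (`resume = TRUE` skips
stages whose outputs exist) and byte-reproducible: every stage seed derives
deterministically from the global seed, and a JSON manifest records the
stage list, seeds, and MD5 hashes of all outputs. Two runs with the same
configuration and seed produce byte-identical CSV/JSON outputs, which the
test suite asserts at the byte level. All analysis constants (25%
missingness limit, 0.90 probability threshold, $k = 100$, $\alpha = 0.05$,
70% retention, $L = 3$) are pre-filled in `pipelineConfig()` and
overridable; configurations can be read from YAML.

## Validation experiments and problem sizes

The test suite validates each stage against independent oracles (brute-force
CLR, connectivity and BH implementations; hand-computed Spearman and
permutation-arithmetic cases) and runs four statistical experiments sized
for a single CPU:

* **Calibration**: 20 null cohorts (150 samples/group, 30 independent
  features), $k = 100$ permutations, 100 PCLRC iterations; the fraction of
  raw $P \le 0.05$ must lie in the 95% binomial band around 0.05.
* **Recovery**: 10 cohorts with a planted 4-node rewired block at
  $\rho = 0.85$ (250 samples/group, 20 features); at least 80% of rewired
  nodes must reach adjusted $P \le 0.05$ and at most 10% of unperturbed
  nodes may.
* **Edge fidelity**: 10 cohorts with a 4-feature block at $\rho = 0.9$ among
  20 features (n = 300), 1000 PCLRC iterations; every true edge must reach
  probability 0.90 and on average at least 95% of null edges must fall
  below. (Averaging across cohorts is part of the experiment's definition:
  with only 6 true edges among 190, the 30% keep-fraction guarantees that
  some null edges are marked every iteration, so the null-edge rate
  fluctuates a few percent from cohort to cohort.)
* **COVSCA recovery**: noiseless sets ($K = 30$, $J = 20$, $L = 3$) must be
  fit to GoF $\ge 99.9\%$ with per-component absolute congruence
  $\ge 0.99$.

`scripts/acceptance.R` re-runs these experiments from scratch against the
installed package and writes the measured quantities as JSON.

## Known limitations

* The permutation null is anti-conservative for nodes inside strong shared
  correlation blocks (see above).
* With the 30% keep-fraction, sparse true networks leave many per-iteration
  marks to background edges; a few percent of null edges can exceed the 0.90
  probability threshold, with weights typically below 0.2. The conventional
  $|r| \ge 0.6$ display threshold hides these in visualisations.
* COVSCA ALS finds local optima; restarts mitigate but do not guarantee the
  global solution, and convergence is slow for nearly collinear prototypes.
* The lasso stage biases coefficients toward zero; extracted signals are
  reliable in direction and correlation structure, not in absolute effect
  size.
* The generator's Gaussian-copula blocks are an idealisation of metabolite
  covariance; real panels show overlapping pathway structure and
  heteroscedastic technical noise.
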