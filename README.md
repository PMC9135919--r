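# MetLipNet

Covariate-specific metabolite–lipid association networks: PCLRC inference,
differential connectivity, and COVSCA multi-network decomposition.

## What this package is for

NMR serum panels in clinical cohorts quantify small metabolites (amino
acids, ketone bodies, glucose, ...) alongside lipoprotein main parameters
and sub-fractions. How these concentrations *correlate* — the association
network — often carries more information about metabolic re-modulation
between groups (women vs men, diseased vs healthy) than the individual
levels do. MetLipNet is for analysts who want to:

- extract, per feature, the part of a concentration profile associated with
  one clinical covariate while adjusting for the remaining covariates
  (lasso-penalized regression with main effects plus first-order
  interactions of the target covariate);
- infer robust association networks with **PCLRC** (probabilistic context
  likelihood of relatedness on correlation): resampled Spearman correlation,
  CLR background correction, per-edge retention probabilities, and
  probability-thresholded filtering

  ```
  a_ij = r_ij  if p_ij >= 0.90,   a_ij = 0  otherwise;
  ```

- compare two group-specific networks by node **differential connectivity**
  χᵢ = Σ_{j≠i} |a_ij|, Δᵢ = χᵢᴬ − χᵢᴮ, with a column-permutation null,
  P = (1 + #(|Dᵢ| > |Δᵢ|))/k, and Benjamini–Hochberg adjustment;
- summarise a large collection of networks with **COVSCA**:
  S_k ≈ Σ_l c_kl z_l z_lᵀ with nonnegative weights and L shared rank-1
  prototypes, fitted by alternating least squares, plus a t-SNE embedding of
  the K×L scores for cluster visualisation.

A seeded synthetic cohort generator with planted ground truth (correlated
feature blocks, between-group rewiring, covariate effects, covariate
missingness) makes the whole workflow testable end to end; `runPipeline()`
chains everything reproducibly. The methods vignette
(`vignettes/metlipnet-methods.Rmd`) documents the models, defaults, and
design decisions.

## Worked example

Simulate a two-group cohort in which features 17–20 are unconnected in group
A but form a correlated block (Spearman ρ = 0.85) in group B, infer the
group-B network, and test for differentially connected nodes:

```r
library(MetLipNet)

spec <- cohortSpec(nPerGroup = c(150, 150), P = 20, M = 6, nBlocks = 0,
                   withinBlockRho = 0.85, rewiredNodes = 17:20,
                   missingRate = 0.1, seed = 7)
cohort <- generateCohort(spec)
yA <- log(cohort$concentrations$A)
yB <- log(cohort$concentrations$B)

net <- buildNetwork(yB, pclrcConfig(nIterations = 500, seed = 1))
net
#> InferredNetwork: 20 nodes, 14 edges (of 190 possible)
#>   PCLRC: 500 iterations, subsample 0.75, keep 0.3, threshold 0.9

res <- permutationTest(yA, yB, cfg = pclrcConfig(nIterations = 500, seed = 1),
                       k = 100, seed = 2, permIterations = 100)
subset(summary(res), pAdj <= 0.05)
#>    feature      chiA      chiB      delta pRaw pAdj
#> 2  feat002 0.9941028 0.1604889  0.8336139 0.01 0.04
#> 17 feat017 0.0000000 2.5861825 -2.5861825 0.01 0.04
#> 18 feat018 0.1844189 2.7400898 -2.5556709 0.01 0.04
#> 19 feat019 0.4685257 2.6962087 -2.2276830 0.01 0.04
#> 20 feat020 0.5223432 2.5671168 -2.0447735 0.01 0.04
```

All four rewired features are recovered at the permutation floor
(raw P = 1/k = 0.01): each gains roughly (4−1) × 0.85 ≈ 2.5 units of
connectivity in group B, far outside the permutation null. One background
feature (`feat002`) is also flagged at this cohort size — by construction
the raw test has a ~5% type-I rate per feature, and with 16 background
features the occasional borderline call survives BH at small P.

The full chain (simulate → preprocess → extract → infer → diffnet → covsca
→ embed) runs from one configuration:

```r
cfg <- pipelineConfig(outdir = "run", seed = 11,
                      simulation = list(nPerGroup = c(120, 80), P = 15,
                                        M = 5, nBlocks = 3,
                                        withinBlockRho = 0.7,
                                        missingRate = 0.1))
manifest <- runPipeline(cfg)
```

which writes per-stage CSV outputs plus `manifest.json` (stage seeds and MD5
hashes of every file); rerunning with the same config and seed reproduces
every output byte for byte.

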