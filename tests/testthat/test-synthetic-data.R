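test_that("cohort generation is reproducible from the seed", {
  spec <- cohortSpec(nPerGroup = c(40, 30), P = 10, M = 5, nBlocks = 2,
                     withinBlockRho = 0.6, missingRate = 0.1, seed = 42)
  ch1 <- generateCohort(spec)
  ch2 <- generateCohort(spec)
  expect_identical(ch1, ch2)
  ch3 <- generateCohort(cohortSpec(nPerGroup = c(40, 30), P = 10, M = 5,
                                   nBlocks = 2, withinBlockRho = 0.6,
                                   missingRate = 0.1, seed = 43))
  expect_false(identical(ch1$concentrations$A, ch3$concentrations$A))
})

test_that("cohort spec validation rejects inconsistent fields", {
  expect_error(cohortSpec(P = 10, rewiredNodes = c(3, 12)), "rewiredNodes")
  expect_error(cohortSpec(missingRate = 0.3), "missingRate")
  expect_error(cohortSpec(withinBlockRho = 1.0), "withinBlockRho")
  expect_error(
    cohortSpec(P = 10, M = 5,
               covariateEffects = list(list(covariate = 9, features = 1,
                                            beta = 1))),
    "covariate effect")
})

test_that("without rewiring the two groups share the generating structure", {
  dist_at <- function(n) {
    spec <- cohortSpec(nPerGroup = c(n, n), P = 8, M = 4, nBlocks = 2,
                       withinBlockRho = 0.6, missingRate = 0, seed = 5)
    ch <- generateCohort(spec)
    expect_identical(ch$groundTruth$blockAssignment$A,
                     ch$groundTruth$blockAssignment$B)
    rA <- spearmanMatrix(ch$concentrations$A)
    rB <- spearmanMatrix(ch$concentrations$B)
    sqrt(sum((rA - rB)^2))
  }
  # sample correlation matrices converge to each other as n grows
  expect_lt(dist_at(1200), dist_at(80))
})

test_that("a planted block produces the intended Spearman structure", {
  spec <- cohortSpec(nPerGroup = c(500, 10), P = 20, M = 4, blockSizes = 4L,
                     withinBlockRho = 0.9, missingRate = 0, seed = 9)
  ch <- generateCohort(spec)
  R <- spearmanMatrix(ch$concentrations$A)
  within <- R[1:4, 1:4][upper.tri(diag(4))]
  outside <- R[upper.tri(R) & !(row(R) <= 4 & col(R) <= 4)]
  expect_true(all(within > 0.6))
  expect_true(all(abs(outside) < 0.2))
})

test_that("within-block association increases with the requested strength", {
  meanAbs <- function(rho) {
    mean(sapply(1:3, function(s) {
      spec <- cohortSpec(nPerGroup = c(150, 10), P = 8, M = 4,
                         blockSizes = 4L, withinBlockRho = rho,
                         missingRate = 0, seed = s)
      ch <- generateCohort(spec)
      R <- spearmanMatrix(ch$concentrations$A)
      mean(abs(R[1:4, 1:4][upper.tri(diag(4))]))
    }))
  }
  v <- c(meanAbs(0.2), meanAbs(0.5), meanAbs(0.8))
  expect_true(all(diff(v) > 0))
})

test_that("rewired nodes change block membership only in group B", {
  spec <- cohortSpec(nPerGroup = c(50, 50), P = 12, M = 4, nBlocks = 2,
                     withinBlockRho = 0.7, rewiredNodes = c(11, 12),
                     missingRate = 0, seed = 3)
  ch <- generateCohort(spec)
  gt <- ch$groundTruth
  expect_identical(gt$differentialNodes, c(11L, 12L))
  expect_identical(gt$blockAssignment$A[11:12], c(0L, 0L))
  expect_identical(gt$blockAssignment$B[11:12], c(3L, 3L))
  expect_identical(gt$blockAssignment$A[1:10], gt$blockAssignment$B[1:10])
})

test_that("planted covariate effects shift the affected features", {
  eff <- list(list(covariate = 1, features = 1:2, beta = 1.5))
  spec <- cohortSpec(nPerGroup = c(400, 10), P = 6, M = 4, nBlocks = 0,
                     withinBlockRho = 0, covariateEffects = eff,
                     missingRate = 0, seed = 21)
  ch <- generateCohort(spec)
  x <- covariateValues(ch$covariates$A)[, 1]
  y <- log(ch$concentrations$A)
  expect_gt(abs(cor(y[, 1], x)), 0.5)
  expect_lt(abs(cor(y[, 5], x)), 0.2)
})

test_that("covariate table has declared types, categories and missingness", {
  spec <- cohortSpec(nPerGroup = c(200, 100), P = 6, M = 20,
                     missingRate = 0.15, nBlocks = 1, seed = 8)
  ch <- generateCohort(spec)
  cv <- ch$covariates$A
  expect_s4_class(cv, "CovariateTable")
  expect_setequal(unique(varCategory(cv)),
                  c("diseases", "familiarity", "drugs", "risk", "biohumoral"))
  v <- covariateValues(cv)
  expect_equal(mean(is.na(v)), 0.15, tolerance = 0.02)
  dich <- v[, varType(cv) == "dichotomous"]
  expect_true(all(dich %in% c(0, 1) | is.na(dich)))
  cont <- v[, varType(cv) == "continuous"]
  expect_true(all(cont[!is.na(cont)] > 0))  # log-normal margins
})

test_that("covsca set construction matches its algebraic definition", {
  # noiseless matrices have rank <= L
  set <- generateCovscaSet(K = 6, L = 2, J = 10, noiseSd = 0, seed = 4)
  for (S in set$S) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_lt(sum(abs(ev) > 1e-10), 3)
  }
  expect_true(all(set$C >= 0))
  expect_equal(colSums(set$Z^2), rep(1, 2), tolerance = 1e-12)
  # K = 1, L = 1: largest eigenvalue is the weight
  one <- generateCovscaSet(K = 1, L = 1, J = 7, noiseSd = 0, seed = 5)
  ev <- eigen(one$S[[1]], symmetric = TRUE)
  expect_equal(max(ev$values), one$C[1, 1], tolerance = 1e-10)
  expect_equal(abs(sum(ev$vectors[, 1] * one$Z[, 1])), 1, tolerance = 1e-10)
  # seeded determinism
  expect_identical(generateCovscaSet(5, 2, 6, 0.1, seed = 2),
                   generateCovscaSet(5, 2, 6, 0.1, seed = 2))
})

test_that("cohort round-trips through the standard pipeline input files", {
  dir <- withr::local_tempdir()
  spec <- cohortSpec(nPerGroup = c(20, 15), P = 5, M = 4, nBlocks = 1,
                     missingRate = 0.1, seed = 2)
  ch <- generateCohort(spec)
  writeCohort(ch, dir)
  conc <- readConcentrations(file.path(dir, "concentrations_A.csv"))
  expect_equal(conc, ch$concentrations$A, tolerance = 1e-12)
  cov <- readCovariates(file.path(dir, "covariates_B.csv"))
  expect_equal(covariateValues(cov), covariateValues(ch$covariates$B),
               tolerance = 1e-12)
  expect_identical(unname(varType(cov)), unname(varType(ch$covariates$B)))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$seed, 2)
})

test_that("cohort spec reads from YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_per_group: [30, 20]", "P: 8", "M: 4", "n_blocks: 2",
               "within_block_rho: 0.5", "rewired_nodes: [7, 8]",
               "missing_rate: 0.05", "seed: 12"), f)
  spec <- cohortSpecFromYaml(f)
  expect_identical(spec@nPerGroup, c(30L, 20L))
  expect_identical(spec@rewiredNodes, c(7L, 8L))
  expect_equal(spec@withinBlockRho, 0.5)
})
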