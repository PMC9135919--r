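test_that("connectivity equals the absolute-row-sum definition", {
  # hand case: 3 nodes, a12 = 0.5, a13 = -0.8, a23 = 0
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 0.5
  A[1, 3] <- A[3, 1] <- -0.8
  expect_equal(connectivity(A), c(1.3, 0.5, 0.8))
  # empty network
  expect_equal(connectivity(matrix(0, 4, 4)), rep(0, 4))
  # fully connected unweighted network attains the upper bound P - 1
  P <- 6
  full <- matrix(1, P, P)
  expect_equal(connectivity(full), rep(P - 1, P))
  # unit diagonal (correlation-matrix convention) is ignored
  expect_equal(connectivity(diag(P)), rep(0, P))
})

test_that("connectivity matches a brute-force oracle on random networks", {
  set.seed(20)
  for (rep in 1:50) {
    A <- randomAdjacency(sample(3:12, 1))
    expect_equal(unname(connectivity(A)), bruteConnectivity(A),
                 tolerance = 1e-12)
  }
})

test_that("differential connectivity is an antisymmetric difference", {
  chiA <- c(2.0, 0.5)
  chiB <- c(0.5, 0.5)
  expect_equal(differentialConnectivity(chiA, chiB), c(1.5, 0))
  expect_equal(differentialConnectivity(chiB, chiA), -c(1.5, 0))
  expect_equal(differentialConnectivity(chiA, chiA), c(0, 0))
  expect_error(
    differentialConnectivity(c(a = 1, b = 2), c(b = 2, a = 1)),
    "feature set")
})

test_that("permutation P-values follow the exceedance formula", {
  k <- 100
  nullMat <- rbind(seq(0.001, 0.1, length.out = k),   # all below |delta| = 2
                   seq(0.001, 0.1, length.out = k))
  nullMat[2, 1:4] <- 5                                 # 4 exceedances
  p <- permutationPvalues(c(2, 1), nullMat)
  expect_equal(p[1], 1 / k)            # floor
  expect_equal(p[2], (1 + 4) / 100)    # (1 + #exceed)/k = 0.05
  # ties count as non-exceedance
  pt <- permutationPvalues(1, matrix(rep(1, 10), 1))
  expect_equal(pt, 1 / 10)
  # exceedances are capped so P <= 1
  pmax <- permutationPvalues(0, matrix(rep(1, 10), 1))
  expect_equal(pmax, 1)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.3), 0.3)
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(33)
  for (rep in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bhAdjust(p), bruteBH(p), tolerance = 1e-12)
  }
})

test_that("permutation test is reproducible and structurally sound", {
  co <- nullCohortPair(n = 60, P = 8, seed = 44)
  cfg <- pclrcConfig(nIterations = 30, seed = 5)
  res <- permutationTest(co$A, co$B, cfg = cfg, k = 10, seed = 9)
  expect_s4_class(res, "DiffConnectivityResult")
  expect_equal(res@delta, res@chiA - res@chiB)
  expect_true(all(res@pRaw >= 1 / 10 & res@pRaw <= 1))
  expect_true(all(res@pAdj >= res@pRaw))
  expect_equal(dim(res@null), c(8L, 10L))
  res2 <- permutationTest(co$A, co$B, cfg = cfg, k = 10, seed = 9)
  expect_identical(summary(res), summary(res2))
  expect_error(permutationTest(co$A, co$B[, 1:5], cfg = cfg), "features")
})

test_that("pairwise significance frequency applies the strict 70% rule", {
  # counting: 5 networks -> 10 unordered pairs
  expect_equal(ncol(utils::combn(5, 2)), 10)
  # boundary arithmetic on the retention rule, on a synthetic frequency
  freq <- c(f1 = 8, f2 = 7) / 10
  retained <- names(freq)[freq > 0.70]
  expect_identical(retained, "f1")  # 80% retained, exactly 70% not

  # end-to-end on three small data sets: one contains a strong block that
  # the other two lack, so its members recur as significant
  spec <- cohortSpec(nPerGroup = c(80, 80), P = 6, M = 4, blockSizes = 3L,
                     withinBlockRho = 0.9, missingRate = 0, seed = 3)
  withBlock <- log(generateCohort(spec)$concentrations$A)
  flat <- nullCohortPair(n = 80, P = 6, seed = 4)
  cfg <- pclrcConfig(nIterations = 50, seed = 2)
  out <- pairwiseSignificanceFrequency(
    list(a = withBlock, b = flat$A, c = flat$B),
    cfg = cfg, k = 20, seed = 5)
  expect_equal(out$nPairs, 3)
  expect_true(all(out$frequency >= 0 & out$frequency <= 1))
  expect_true(all(out$frequency[out$retained] > 0.70))
  expect_error(pairwiseSignificanceFrequency(list(flat$A), cfg = cfg),
               "at least 2")
})
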