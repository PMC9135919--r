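test_that("spearman matrix matches hand-computed and rank-invariance cases", {
  # Pearson on ranks of x=(1,2,3), y=(3,1,2) is -0.5
  expect_equal(spearmanMatrix(cbind(c(1, 2, 3), c(3, 1, 2)))[1, 2], -0.5)
  # monotone transforms leave ranks unchanged
  x <- rnorm(50)
  expect_equal(spearmanMatrix(cbind(x, exp(x)))[1, 2], 1)
  # duplicated column
  m <- cbind(a = rnorm(30), b = rnorm(30))
  expect_equal(spearmanMatrix(cbind(m, a2 = m[, "a"]))[1, 3], 1)
  # constant column warns and zeroes
  expect_warning(R <- spearmanMatrix(cbind(rnorm(10), rep(2, 10))),
                 "constant")
  expect_equal(R[1, 2], 0)
  expect_equal(diag(R), c(1, 1))
  expect_error(spearmanMatrix(matrix(1:4, 2, 2)), "3 samples")
})

test_that("CLR scores match a brute-force oracle", {
  set.seed(3)
  for (rep in 1:5) {
    R <- randomAdjacency(6)
    diag(R) <- 1
    expect_equal(clrScores(R), bruteCLR(R), tolerance = 1e-12)
  }
  # all equal off-diagonal similarities give all-zero scores
  R0 <- matrix(0.4, 5, 5); diag(R0) <- 1
  expect_true(all(clrScores(R0) == 0))
  # one outstanding edge in a flat background is the strict maximum
  R1 <- matrix(0.2, 4, 4); diag(R1) <- 1
  R1[1, 2] <- R1[2, 1] <- 0.9
  Z <- clrScores(R1)
  expect_true(Z[1, 2] > max(Z[upper.tri(Z)][-1]))
  # relabeling equivariance
  set.seed(4)
  R <- randomAdjacency(7); diag(R) <- 1
  p <- sample(7)
  expect_equal(clrScores(R[p, p]), clrScores(R)[p, p], tolerance = 1e-12)
})

test_that("resampling kernel agrees exactly with the plain-R reference", {
  set.seed(8)
  y <- matrix(rnorm(45 * 9), 45, 9)
  # single full-sample iteration: probabilities are the indicator of the
  # top-edge set computed by the R path
  Pm <- pclrcProbabilities(y, pclrcConfig(nIterations = 1,
                                          subsampleFraction = 1, seed = 2))
  sel <- MetLipNet:::markTopEdges(clrScores(spearmanMatrix(y)), 0.30)
  expect_identical(Pm == 1, sel | t(sel))
  expect_true(all(Pm %in% c(0, 1)))
})

test_that("edge probabilities are empirical frequencies with the keep rate", {
  set.seed(2)
  x <- matrix(rnorm(60 * 10), 60, 10)
  cfg <- pclrcConfig(nIterations = 40, seed = 6)
  Pm <- pclrcProbabilities(x, cfg)
  expect_true(all(abs(Pm * 40 - round(Pm * 40)) < 1e-9))  # k/nIterations
  expect_equal(Pm, t(Pm))
  # expected per-iteration mark rate equals keepFraction (top-quantile)
  expect_equal(mean(Pm[upper.tri(Pm)]), ceiling(0.30 * 45) / 45,
               tolerance = 0.02)
  # determinism from the seed
  expect_identical(Pm, pclrcProbabilities(x, cfg))
})

test_that("duplicated features are retained with near-certain probability", {
  set.seed(9)
  x <- matrix(rnorm(200 * 19), 200, 19)
  x <- cbind(x, x[, 1])  # feature 20 duplicates feature 1
  Pm <- pclrcProbabilities(x, pclrcConfig(nIterations = 200, seed = 3))
  expect_gte(Pm[1, 20], 0.99)
})

test_that("probability filtering implements the thresholding rule", {
  R <- matrix(c(1, 0.7, 0.99, 0.7, 1, 0.5, 0.99, 0.5, 1), 3, 3)
  Pmat <- matrix(c(0, 0.95, 0.89, 0.95, 0, 0.90, 0.89, 0.90, 0), 3, 3)
  A <- filterNetwork(R, Pmat, 0.90)
  expect_equal(A[1, 2], 0.7)   # p = 0.95 -> kept
  expect_equal(A[1, 3], 0)     # p = 0.89 -> dropped despite r = 0.99
  expect_equal(A[2, 3], 0.5)   # p = 0.90 exactly -> kept
  expect_equal(diag(A), rep(0, 3))
  # raising the threshold never adds edges
  A99 <- filterNetwork(R, Pmat, 0.99)
  expect_true(all(A99[A == 0] == 0))
  expect_lte(sum(A99 != 0), sum(A != 0))
})

test_that("a planted correlated block is recovered in the filtered network", {
  spec <- cohortSpec(nPerGroup = c(300, 10), P = 20, M = 4, blockSizes = 4L,
                     withinBlockRho = 0.9, missingRate = 0, seed = 31)
  ch <- generateCohort(spec)
  net <- buildNetwork(log(ch$concentrations$A),
                      pclrcConfig(nIterations = 300, seed = 7))
  A <- adjacency(net)
  within <- A[1:4, 1:4][upper.tri(diag(4))]
  expect_true(all(within != 0))
  nullEdges <- A[upper.tri(A) & !(row(A) <= 4 & col(A) <= 4)]
  expect_gte(mean(nullEdges == 0), 0.90)
  expect_s4_class(net, "InferredNetwork")
})

test_that("with resampling disabled the network ignores sample order", {
  set.seed(12)
  x <- matrix(rnorm(40 * 6), 40, 6)
  cfg <- pclrcConfig(nIterations = 1, subsampleFraction = 1, seed = 1)
  n1 <- buildNetwork(x, cfg)
  n2 <- buildNetwork(x[sample(40), ], cfg)
  expect_equal(adjacency(n1), adjacency(n2), tolerance = 1e-12)
  # threshold 1.0 with one iteration: A is nonzero exactly on the kept set
  cfg1 <- pclrcConfig(nIterations = 1, subsampleFraction = 1,
                      probabilityThreshold = 1, seed = 1)
  n3 <- buildNetwork(x, cfg1)
  expect_identical(unname(adjacency(n3) != 0),
                   unname(edgeProbabilities(n3) == 1))
})

test_that("network export produces consistent edge lists and GraphML", {
  spec <- cohortSpec(nPerGroup = c(100, 10), P = 8, M = 4, blockSizes = 3L,
                     withinBlockRho = 0.9, missingRate = 0, seed = 14)
  ch <- generateCohort(spec)
  net <- buildNetwork(log(ch$concentrations$A),
                      pclrcConfig(nIterations = 100, seed = 2))
  el <- edgeList(net)
  expect_true(all(abs(el$weight) <= 1))
  expect_equal(nrow(el), sum(adjacency(net)[upper.tri(adjacency(net))] != 0))
  elDisp <- edgeList(net, displayThreshold = 0.6)
  expect_true(all(abs(elDisp$weight) >= 0.6))
  f <- withr::local_tempfile(fileext = ".graphml")
  writeGraphml(net, f, displayThreshold = 0.6)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g), 8)
  expect_equal(igraph::ecount(g), nrow(elDisp))
})
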