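test_that("design has the target main effect plus its interactions", {
  set.seed(1)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
  d <- buildDesign(X, 1)
  expect_equal(ncol(d$design), 3)           # X1, X1*X2, X1*X3
  expect_identical(d$terms, c("main", "x2", "x3"))
  # columns are products of standardized covariates
  zs <- scale(X)
  expect_equal(unname(d$design[, 2]), unname(zs[, 1] * zs[, 2]),
               tolerance = 1e-12)
  # a constant covariate produces a constant interaction that is dropped
  Xc <- cbind(X[, 1:2], x3 = rep(2, 20))
  expect_warning(dc <- buildDesign(Xc, 1), "constant")
  expect_equal(ncol(dc$design), 2)
  expect_error(buildDesign(X, "nope"), "not found")
  # design width is 1 + (M - 1) = M
  X10 <- matrix(rnorm(300), 30, 10)
  expect_equal(ncol(buildDesign(X10, 4)$design), 10)
})

test_that("a single planted effect is recovered with unit correlation", {
  set.seed(2)
  n <- 300; M <- 6
  X <- matrix(rnorm(n * M), n, M)
  Y <- cbind(f = 2 * X[, 3])
  for (pen in c("lasso", "none")) {
    sig <- extractSignal(Y, X, m = 3, penalty = pen, seed = 5)
    v <- signalValues(sig)
    expect_equal(abs(cor(v[, 1], X[, 3])), 1, tolerance = 1e-6)
    # slope recovered up to shrinkage: standardized main coefficient ~ 2*sd(X3)
    slope <- sig@coefficients["cov003", 1] / sd(X[, 3])
    expect_equal(slope, 2, tolerance = 0.1)
  }
})

test_that("effects of other covariates do not leak into the signal", {
  set.seed(3)
  n <- 400; M <- 6
  X <- matrix(rnorm(n * M), n, M)
  Y <- cbind(f = 1.5 * X[, 2])        # depends only on a nuisance covariate
  sig <- extractSignal(Y, X, m = 1, penalty = "lasso", seed = 5)
  v <- signalValues(sig)[, 1]
  leak <- if (sd(v) > 0) abs(cor(v, X[, 2])) else 0
  expect_lte(leak, 0.1)
})

test_that("pure interactions with the target covariate are recovered", {
  set.seed(4)
  n <- 500; M <- 5
  X <- matrix(rnorm(n * M), n, M)
  Y <- cbind(f = X[, 1] * X[, 4])
  sig <- extractSignal(Y, X, m = 1, penalty = "lasso", seed = 6)
  expect_gt(cor(signalValues(sig)[, 1], X[, 1] * X[, 4]), 0.9)
})

test_that("the extracted signal lies in the span of the target design", {
  set.seed(5)
  n <- 150; M <- 4
  X <- matrix(rnorm(n * M), n, M)
  Y <- matrix(rnorm(n * 3) + X[, 2], n, 3)
  sig <- extractSignal(Y, X, m = 2, penalty = "lasso", seed = 2)
  D <- buildDesign(X, 2)$design
  v <- signalValues(sig)
  refit <- D %*% qr.solve(crossprod(D), crossprod(D, v))
  expect_equal(unname(refit), unname(v), tolerance = 1e-8)
})

test_that("scaling the response scales the extracted signal", {
  set.seed(6)
  n <- 120
  X <- matrix(rnorm(n * 4), n, 4)
  Y <- cbind(f = 3 * X[, 1] + rnorm(n, sd = 0.2))
  s1 <- signalValues(extractSignal(Y, X, 1, seed = 3))
  s10 <- signalValues(extractSignal(10 * Y, X, 1, seed = 3))
  expect_equal(s10, 10 * s1, tolerance = 1e-6)
})

test_that("extraction is invariant to the ordering of other covariates", {
  set.seed(7)
  n <- 100
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("c", 1:5)))
  Y <- cbind(f = X[, 2] + 0.5 * X[, 2] * X[, 4] + rnorm(n, sd = 0.1))
  v1 <- signalValues(extractSignal(Y, X, "c2", seed = 4))
  perm <- c(3, 1, 2, 5, 4)
  v2 <- signalValues(extractSignal(Y, X[, perm], "c2", seed = 4))
  expect_equal(v1, v2, tolerance = 1e-4)
})

test_that("extractAll returns one signal matrix per covariate", {
  set.seed(8)
  n <- 80
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("c", 1:4)))
  Y <- matrix(rnorm(n * 2), n, 2)
  out <- extractAll(Y, X, seed = 2)
  expect_length(out, 4)
  expect_identical(names(out), paste0("c", 1:4))
  # a single feature still yields n x 1 matrices
  out1 <- extractAll(Y[, 1, drop = FALSE], X, covariates = c("c1", "c3"),
                     seed = 2)
  expect_length(out1, 2)
  expect_equal(dim(signalValues(out1$c1)), c(n, 1L))
})

test_that("unpenalized mode refuses rank-deficient designs", {
  set.seed(9)
  n <- 10; M <- 8                      # 2M - 1 columns > n
  X <- matrix(rnorm(n * M), n, M)
  Y <- cbind(f = rnorm(n))
  expect_error(extractSignal(Y, X, 1, penalty = "none"), "lasso")
})
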