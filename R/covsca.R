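# Covariance simultaneous component analysis (COVSCA): approximate K
# symmetric association matrices by nonnegative combinations of L shared
# rank-1 prototypes, fitted by alternating least squares (nonnegative least
# squares for the weights, a dominant-eigenvector step for each loading
# vector).

#' Association matrices of a set of networks
#'
#' Converts inferred networks into the symmetric matrices modeled by COVSCA:
#' the filtered signed adjacency with the unit diagonal restored.
#'
#' @param networks list of [InferredNetwork-class] over identical feature
#'   sets.
#' @param useRaw if TRUE, use the full Spearman correlation matrix instead of
#'   the filtered adjacency (default FALSE).
#' @return list of symmetric J x J matrices with entries in [-1, 1].
#' @export
associationMatrices <- function(networks, useRaw = FALSE) {
  feats <- networks[[1]]@features
  lapply(networks, function(nt) {
    if (!identical(nt@features, feats))
      stop("networks must share the same ordered feature set")
    S <- if (useRaw) nt@R else nt@A
    diag(S) <- 1
    S
  })
}

covscaLoss <- function(S, C, Z) {
  sum(vapply(seq_along(S), function(k) {
    Rk <- S[[k]] - Z %*% (t(Z) * C[k, ])
    sum(Rk^2)
  }, numeric(1)))
}

# One ALS run from a given starting Z (J x L, unit-norm columns).
covscaAls <- function(S, Z, tol, maxIter) {
  K <- length(S); J <- nrow(Z); L <- ncol(Z)
  X <- matrix(0, J * J, L)
  C <- matrix(0, K, L)
  loss <- numeric()
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    # C-step: per-matrix nonnegative least squares on vectorised prototypes
    for (l in seq_len(L)) X[, l] <- as.vector(tcrossprod(Z[, l]))
    for (k in seq_len(K))
      C[k, ] <- pracma::lsqnonneg(X, as.vector(S[[k]]))$x
    # Z-step: each z_l is the dominant eigenvector of the weighted residual
    for (l in seq_len(L)) {
      W <- matrix(0, J, J)
      for (k in seq_len(K)) {
        if (C[k, l] == 0) next
        Rk <- S[[k]] - Z[, -l, drop = FALSE] %*%
          (t(Z[, -l, drop = FALSE]) * C[k, -l])
        W <- W + C[k, l] * Rk
      }
      if (any(W != 0)) {
        e <- eigen((W + t(W)) / 2, symmetric = TRUE)
        z <- e$vectors[, 1]
        # sign convention: largest-magnitude entry positive
        if (z[which.max(abs(z))] < 0) z <- -z
        Z[, l] <- z
      }
    }
    cur <- covscaLoss(S, C, Z)
    loss <- c(loss, cur)
    if (is.finite(prev) && prev - cur <= tol * (1 + abs(prev))) {
      converged <- TRUE
      break
    }
    prev <- cur
  }
  list(Z = Z, C = C, loss = loss, converged = converged)
}

#' Fit a COVSCA model by alternating least squares
#'
#' Minimises \eqn{\sum_k \|S_k - \sum_l c_{kl} z_l z_l^T\|_F^2} subject to
#' \eqn{c_{kl} \ge 0} and \eqn{\|z_l\| = 1}. Both alternating steps solve
#' their subproblem exactly, so the loss is non-increasing. The first start
#' initialises Z from the top eigenvectors of the mean matrix; remaining
#' restarts use random orthonormal loadings. The best restart is kept.
#'
#' @param S list of K symmetric J x J matrices (K >= L).
#' @param L number of rank-1 prototypes (default 3).
#' @param tol relative loss-change convergence tolerance (default 1e-9).
#' @param maxIter maximum ALS iterations per restart (default 500).
#' @param nRestarts number of starts (default 10; the first is
#'   eigen-initialised).
#' @param seed integer RNG seed for the random restarts.
#' @param warmStarts optional list of J x L matrices used as additional
#'   starting points (e.g. a lower-order solution padded with a random
#'   column, to enforce nestedness of the fits).
#' @return a [CovscaModel-class]. Goodness-of-fit is
#'   \eqn{100 (1 - \sum_k \|residual_k\|_F^2 / \sum_k \|S_k\|_F^2)}.
#' @examples
#' set <- generateCovscaSet(K = 8, L = 2, J = 10, noiseSd = 0, seed = 1)
#' fit <- fitCovsca(set$S, L = 2, nRestarts = 3, seed = 1)
#' gof(fit)
#' @export
fitCovsca <- function(S, L = 3L, tol = 1e-9, maxIter = 500L, nRestarts = 10L,
                      seed = 1L, warmStarts = NULL) {
  K <- length(S)
  stopifnot(K >= L, L >= 1)
  J <- nrow(S[[1]])
  for (Sk in S)
    if (!identical(dim(Sk), c(J, J)) || max(abs(Sk - t(Sk))) > 1e-8)
      stop("all matrices must be symmetric and of the same dimension")
  feats <- rownames(S[[1]])
  Sbar <- Reduce(`+`, S) / K
  eig <- eigen((Sbar + t(Sbar)) / 2, symmetric = TRUE)
  ord <- order(abs(eig$values), decreasing = TRUE)
  Z0 <- eig$vectors[, ord[seq_len(L)], drop = FALSE]

  starts <- c(list(Z0), warmStarts %||% list())
  best <- NULL
  withSeed(seed, {
    nRandom <- max(0L, nRestarts - length(starts))
    for (r in seq_len(nRandom)) {
      Zr <- qr.Q(qr(matrix(stats::rnorm(J * L), J, L)))
      starts[[length(starts) + 1L]] <- Zr
    }
    for (Zs in starts) {
      Zs <- sweep(Zs, 2, sqrt(colSums(Zs^2)), "/")
      fit <- covscaAls(S, Zs, tol, maxIter)
      if (is.null(best) || min(fit$loss) < min(best$loss)) best <- fit
    }
  })
  if (!best$converged)
    warning("ALS did not converge within maxIter; returning best iterate")
  total <- sum(vapply(S, function(Sk) sum(Sk^2), numeric(1)))
  resid <- vapply(seq_len(K), function(k) {
    Rk <- S[[k]] - best$Z %*% (t(best$Z) * best$C[k, ])
    sum(Rk^2)
  }, numeric(1))
  gofPer <- 100 * (1 - resid / vapply(S, function(Sk) sum(Sk^2), numeric(1)))
  new("CovscaModel", Z = best$Z, weights = best$C,
      gof = 100 * (1 - sum(resid) / total),
      gofPerMatrix = gofPer, loss = best$loss,
      converged = best$converged,
      nRestarts = as.integer(length(starts)), seed = as.integer(seed),
      features = if (is.null(feats)) character() else feats)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tucker congruence between two loading matrices
#'
#' Absolute cosine similarity per component after the best matching of
#' components (all permutations are scanned), so the comparison is invariant
#' to sign flips and component reordering.
#'
#' @param Zhat,Ztrue J x L loading matrices.
#' @return numeric vector of length L: matched absolute congruences.
#' @export
tuckerCongruence <- function(Zhat, Ztrue) {
  stopifnot(identical(dim(Zhat), dim(Ztrue)))
  L <- ncol(Zhat)
  cn <- function(M) sweep(M, 2, sqrt(colSums(M^2)), "/")
  G <- abs(crossprod(cn(Zhat), cn(Ztrue)))  # L x L |cosine| matrix
  perms <- permutationsOf(L)
  best <- NULL; bestSum <- -Inf
  for (p in perms) {
    v <- G[cbind(p, seq_len(L))]
    if (sum(v) > bestSum) { bestSum <- sum(v); best <- v }
  }
  best
}

permutationsOf <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in permutationsOf(n - 1L)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}
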