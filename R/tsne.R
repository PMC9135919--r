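# Exact t-SNE for small point sets (hundreds of networks), used to embed
# COVSCA scores in 2-D. Standard formulation: per-point Gaussian bandwidths
# calibrated to the target perplexity by bisection, symmetrised affinities,
# Student-t low-dimensional kernel, gradient descent with momentum and early
# exaggeration.

tsnePerplexityP <- function(D2, perplexity, tolLogU = 1e-5, maxBisect = 50) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (b in seq_len(maxBisect)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { H <- 0; p <- w }
      else {
        p <- w / sw
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      diff <- H - logU
      if (abs(diff) < tolLogU) break
      if (diff > 0) {      # entropy too high -> sharpen
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P
}

tsneExact <- function(X, perplexity, seed, nIter = 1000, eta = 100,
                      exaggeration = 4, exaggerateUntil = 100) {
  X <- as.matrix(X)
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  P <- tsnePerplexityP(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P[P < .Machine$double.eps] <- .Machine$double.eps
  withSeed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    dY <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    for (it in seq_len(nIter)) {
      Pe <- if (it <= exaggerateUntil) P * exaggeration else P
      num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
      diag(num) <- 0
      Q <- num / sum(num)
      Q[Q < .Machine$double.eps] <- .Machine$double.eps
      L <- (Pe - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      momentum <- if (it < 250) 0.5 else 0.8
      gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      dY <- momentum * dY - eta * gains * grad
      Y <- Y + dY
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}

#' Embed a set of networks in 2-D via t-SNE on their COVSCA scores
#'
#' @param scores K x L score matrix (e.g. [covscaScores()]) or a
#'   [CovscaModel-class].
#' @param perplexity t-SNE perplexity; must satisfy
#'   \code{perplexity < (K - 1) / 3} (default 15, reduced problems need
#'   smaller values).
#' @param seed integer RNG seed; the embedding is deterministic given the
#'   seed.
#' @param labels optional per-network category labels carried through for
#'   plotting.
#' @param nIter gradient-descent iterations (default 1000).
#' @return a [NetworkEmbedding-class].
#' @export
embedNetworks <- function(scores, perplexity = 15, seed = 1L,
                          labels = character(), nIter = 1000) {
  if (is(scores, "CovscaModel")) scores <- covscaScores(scores)
  scores <- as.matrix(scores)
  K <- nrow(scores)
  if (K < 4) stop("need at least 4 networks to embed")
  if (perplexity >= (K - 1) / 3)
    stop(sprintf(
      "perplexity %.1f too large for K = %d networks; use a value below %.1f",
      perplexity, K, (K - 1) / 3))
  Y <- tsneExact(scores, perplexity, seed, nIter = nIter)
  rownames(Y) <- rownames(scores)
  new("NetworkEmbedding", coords = Y, perplexity = as.numeric(perplexity),
      seed = as.integer(seed), labels = as.character(labels))
}
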