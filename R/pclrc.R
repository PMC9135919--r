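# PCLRC network inference: resampled Spearman correlation with CLR background
# correction yields per-edge retention probabilities; the final weighted
# network keeps the signed correlation of edges whose probability reaches the
# threshold.

#' PCLRC inference settings
#'
#' @param nIterations resampling iterations (default 1000).
#' @param subsampleFraction fraction of samples drawn (without replacement)
#'   per iteration (default 0.75).
#' @param keepFraction fraction of top CLR-scored edges marked per iteration
#'   (default 0.30); ties at the cutoff are all included.
#' @param probabilityThreshold minimum edge retention probability for an edge
#'   to enter the filtered network (default 0.90).
#' @param seed integer RNG seed.
#' @return list of validated settings.
#' @export
pclrcConfig <- function(nIterations = 1000L, subsampleFraction = 0.75,
                        keepFraction = 0.30, probabilityThreshold = 0.90,
                        seed = 1L) {
  stopifnot(nIterations >= 1,
            subsampleFraction > 0, subsampleFraction <= 1,
            keepFraction > 0, keepFraction <= 1,
            probabilityThreshold >= 0, probabilityThreshold <= 1)
  list(nIterations = as.integer(nIterations),
       subsampleFraction = subsampleFraction,
       keepFraction = keepFraction,
       probabilityThreshold = probabilityThreshold,
       seed = as.integer(seed))
}

#' Spearman correlation matrix
#'
#' Pearson correlation of average ranks (ties get average ranks). Constant
#' columns get zero correlations, with a warning.
#'
#' @param data samples x features numeric matrix, no missing entries,
#'   at least 3 rows.
#' @param warn warn on constant columns (default TRUE).
#' @return symmetric P x P matrix with unit diagonal, entries in [-1, 1].
#' @export
spearmanMatrix <- function(data, warn = TRUE) {
  data <- as.matrix(data)
  if (nrow(data) < 3) stop("need at least 3 samples")
  if (anyNA(data)) stop("missing entries not allowed")
  P <- ncol(data)
  rk <- matrix(0, nrow(data), P)
  for (j in seq_len(P)) rk[, j] <- rank(data[, j])
  sds <- apply(rk, 2, stats::sd)
  const <- sds == 0
  R <- suppressWarnings(stats::cor(rk))
  if (any(const)) {
    if (warn) warning("constant column(s): ",
                      paste(which(const), collapse = ", "),
                      "; correlations set to 0")
    R[const, ] <- 0
    R[, const] <- 0
  }
  diag(R) <- 1
  R[!is.finite(R)] <- 0
  dimnames(R) <- list(colnames(data), colnames(data))
  R
}

#' CLR background-corrected edge scores
#'
#' Context-likelihood-of-relatedness scores on a correlation matrix: with
#' \eqn{s = |R|} (zero diagonal), each edge gets the row-wise z-score
#' \eqn{z_i = \max(0, (s_{ij} - \mu_i)/\sigma_i)} against the background
#' mean/SD of row i, symmetrised as \eqn{\sqrt{z_i^2 + z_j^2}}. A zero
#' background SD yields a zero z-score.
#'
#' @param R symmetric similarity (correlation) matrix.
#' @return symmetric nonnegative score matrix with zero diagonal.
#' @export
clrScores <- function(R) {
  R <- as.matrix(R)
  if (max(abs(R - t(R))) > 1e-8) stop("input must be symmetric")
  P <- ncol(R)
  s <- abs(R)
  diag(s) <- 0
  mu <- rowSums(s) / (P - 1)
  ex2 <- rowSums(s^2) / (P - 1)
  sd <- sqrt(pmax(ex2 - mu^2, 0))
  z <- (s - mu) / ifelse(sd > 0, sd, Inf)  # sigma = 0 -> z = 0
  z[z < 0] <- 0
  diag(z) <- 0
  out <- sqrt(z^2 + t(z)^2)
  dimnames(out) <- dimnames(R)
  out
}

# One PCLRC pass: mark the top keepFraction of edges by CLR score
# (ties at the cutoff included). Returns a logical P x P matrix.
markTopEdges <- function(Z, keepFraction) {
  ut <- Z[upper.tri(Z)]
  nKeep <- max(1L, ceiling(keepFraction * length(ut)))
  cut <- sort(ut, decreasing = TRUE)[nKeep]
  sel <- Z >= cut
  diag(sel) <- FALSE
  sel
}

#' PCLRC edge retention probabilities
#'
#' For each iteration, a random subsample of the rows is drawn without
#' replacement, the Spearman matrix and its CLR scores computed, and the top
#' \code{keepFraction} of edges marked. The retention probability of an edge
#' is the fraction of iterations in which it was marked.
#'
#' @param data samples x features matrix.
#' @param cfg settings from [pclrcConfig()].
#' @return symmetric P x P probability matrix (zero diagonal); each entry is
#'   an empirical frequency k/nIterations.
#' @export
pclrcProbabilities <- function(data, cfg = pclrcConfig()) {
  data <- as.matrix(data)
  n <- nrow(data)
  m <- max(3L, floor(cfg$subsampleFraction * n))
  if (m < 10 && cfg$subsampleFraction < 1)
    stop("subsample size below 10; increase n or subsampleFraction")
  P <- ncol(data)
  idx <- withSeed(cfg$seed, {
    vapply(seq_len(cfg$nIterations),
           function(i) if (m >= n) seq_len(n) else sample.int(n, m),
           integer(min(m, n)))
  })
  counts <- .pclrcCounts(data, idx, cfg$keepFraction)
  Pm <- (counts + t(counts)) / cfg$nIterations
  diag(Pm) <- 0
  dimnames(Pm) <- list(colnames(data), colnames(data))
  Pm
}

#' Probability-filter a correlation matrix into a weighted adjacency
#'
#' Keeps the signed correlation \eqn{r_{ij}} where the edge probability
#' \eqn{p_{ij} \ge} \code{threshold} and sets it to 0 otherwise; the diagonal
#' is zeroed.
#'
#' @param R correlation matrix.
#' @param Pmat edge probability matrix of the same shape.
#' @param threshold retention probability cutoff (default 0.90; ties
#'   retained).
#' @return weighted signed adjacency matrix.
#' @export
filterNetwork <- function(R, Pmat, threshold = 0.90) {
  stopifnot(identical(dim(R), dim(Pmat)))
  A <- ifelse(Pmat >= threshold, R, 0)
  diag(A) <- 0
  dimnames(A) <- dimnames(R)
  A
}

#' Infer a PCLRC association network
#'
#' Composition of [spearmanMatrix()], [pclrcProbabilities()] and
#' [filterNetwork()], returning the full correlation matrix, the edge
#' probabilities, and the filtered signed weighted adjacency together with a
#' snapshot of the settings.
#'
#' @param data samples x features matrix (typically log-transformed
#'   concentrations or a covariate-specific signal matrix).
#' @param cfg settings from [pclrcConfig()].
#' @return an [InferredNetwork-class].
#' @examples
#' x <- matrix(rnorm(200), 20, 10)
#' net <- buildNetwork(x, pclrcConfig(nIterations = 20, seed = 1))
#' connectivity(net)
#' @export
buildNetwork <- function(data, cfg = pclrcConfig()) {
  data <- as.matrix(data)
  feats <- colnames(data)
  if (is.null(feats)) feats <- sprintf("feat%03d", seq_len(ncol(data)))
  R <- spearmanMatrix(data, warn = FALSE)
  Pm <- pclrcProbabilities(data, cfg)
  A <- filterNetwork(R, Pm, cfg$probabilityThreshold)
  new("InferredNetwork", R = unname(R), Pmat = unname(Pm), A = unname(A),
      features = feats, settings = cfg)
}
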