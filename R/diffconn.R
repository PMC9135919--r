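# Differential node connectivity between two group-specific networks, with a
# column-permutation null, Benjamini-Hochberg adjustment, and the pairwise
# comparison frequency summary across a category of networks.

#' @describeIn connectivity on an inferred network (filtered adjacency).
#' @export
setMethod("connectivity", "InferredNetwork", function(object) {
  chi <- rowSums(abs(object@A))
  names(chi) <- object@features
  chi
})

#' @describeIn connectivity on a symmetric weighted adjacency matrix; a unit
#'   diagonal (full correlation matrix convention) is ignored.
#' @export
setMethod("connectivity", "matrix", function(object) {
  if (nrow(object) != ncol(object)) stop("adjacency must be square")
  A <- abs(object)
  diag(A) <- 0
  rowSums(A)
})

#' Differential node connectivity between two networks
#'
#' \eqn{\Delta_i = \chi_i^A - \chi_i^B}; antisymmetric in its arguments.
#'
#' @param netA,netB two [InferredNetwork-class] objects (or connectivity
#'   vectors) over the identical ordered feature set.
#' @return named numeric vector of per-feature connectivity differences.
#' @export
differentialConnectivity <- function(netA, netB) {
  chiA <- if (is(netA, "InferredNetwork")) connectivity(netA) else netA
  chiB <- if (is(netB, "InferredNetwork")) connectivity(netB) else netB
  if (length(chiA) != length(chiB) ||
      (!is.null(names(chiA)) && !is.null(names(chiB)) &&
       !identical(names(chiA), names(chiB))))
    stop("networks must share the same ordered feature set")
  chiA - chiB
}

#' Permutation P-values for differential connectivity
#'
#' \eqn{P_i = (1 + \#(|D_i| > |\Delta_i|)) / k}: strict exceedance count of
#' the null values over the observed absolute differential connectivity, so
#' the smallest attainable P-value is 1/k and ties count as non-exceedance.
#'
#' @param delta observed differential connectivity (length P).
#' @param nullMat P x k matrix of permuted differential connectivities.
#' @return numeric P-values in [1/k, 1].
#' @export
permutationPvalues <- function(delta, nullMat) {
  nullMat <- as.matrix(nullMat)
  if (nrow(nullMat) != length(delta))
    stop("nullMat must have one row per feature")
  k <- ncol(nullMat)
  exceed <- rowSums(abs(nullMat) > abs(delta))
  pmin((1 + exceed) / k, 1)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH with monotonicity enforcement; output is elementwise at least
#' the input and capped at 1.
#'
#' @param pvalues numeric vector of raw P-values in [0, 1].
#' @return adjusted P-values.
#' @export
bhAdjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("P-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Permutation test for differential connectivity between two groups
#'
#' Builds PCLRC networks from the two data matrices and computes the observed
#' per-feature differential connectivity. Then, for each of k replicates, the
#' columns of each data matrix are independently permuted (destroying the
#' association between features while preserving column means and variances),
#' both networks are rebuilt with the same inference settings, and the
#' permuted differential connectivity recorded as the null distribution.
#' Raw P-values follow [permutationPvalues()]; BH adjustment is applied
#' across the P features.
#'
#' @param dataA,dataB samples x features matrices for the two groups, with
#'   identical ordered feature sets.
#' @param cfg PCLRC settings used for the observed networks
#'   ([pclrcConfig()]).
#' @param k number of permutation replicates (default 100).
#' @param seed integer RNG seed for the permutations.
#' @param permIterations PCLRC iterations used when rebuilding networks from
#'   permuted data; \code{NULL} (default) reuses \code{cfg$nIterations}, a
#'   smaller value trades null-resolution for speed.
#' @return a [DiffConnectivityResult-class].
#' @export
permutationTest <- function(dataA, dataB, cfg = pclrcConfig(), k = 100L,
                            seed = 1L, permIterations = NULL) {
  dataA <- as.matrix(dataA); dataB <- as.matrix(dataB)
  if (ncol(dataA) != ncol(dataB))
    stop("groups must have the same features")
  if (!is.null(colnames(dataA)) && !is.null(colnames(dataB)) &&
      !identical(colnames(dataA), colnames(dataB)))
    stop("feature labels differ between groups")
  stopifnot(k >= 1)
  P <- ncol(dataA)
  feats <- colnames(dataA)
  if (is.null(feats)) feats <- sprintf("feat%03d", seq_len(P))

  netA <- buildNetwork(dataA, cfg)
  netB <- buildNetwork(dataB, cfg)
  delta <- unname(differentialConnectivity(netA, netB))

  permCfg <- cfg
  if (!is.null(permIterations))
    permCfg$nIterations <- as.integer(permIterations)

  nullMat <- matrix(NA_real_, P, k)
  withSeed(seed, {
    for (r in seq_len(k)) {
      pA <- apply(dataA, 2, sample)
      pB <- apply(dataB, 2, sample)
      permCfg$seed <- sample.int(.Machine$integer.max, 1)
      na <- buildNetwork(pA, permCfg)
      permCfg$seed <- sample.int(.Machine$integer.max, 1)
      nb <- buildNetwork(pB, permCfg)
      nullMat[, r] <- unname(connectivity(na) - connectivity(nb))
    }
  })
  if (!all(is.finite(nullMat))) stop("non-finite null values")
  pRaw <- permutationPvalues(delta, nullMat)
  new("DiffConnectivityResult", features = feats,
      chiA = unname(connectivity(netA)), chiB = unname(connectivity(netB)),
      delta = delta, null = nullMat, pRaw = pRaw, pAdj = bhAdjust(pRaw),
      k = as.integer(k), seed = as.integer(seed))
}

#' Pairwise differential-connectivity frequency within a network category
#'
#' Runs [permutationTest()] for every unordered pair of data sets in one
#' covariate category, records per feature the share of pairs in which it is
#' significantly differentially connected (BH-adjusted P below \code{alpha}),
#' and retains the features significant in strictly more than
#' \code{retainFrac} of the comparisons.
#'
#' @param dataList named list (length >= 2) of samples x features matrices,
#'   one per covariate-specific signal set, identical feature sets.
#' @param cfg PCLRC settings ([pclrcConfig()]).
#' @param alpha per-pair significance level on adjusted P-values
#'   (default 0.05).
#' @param retainFrac strict retention threshold on the significance frequency
#'   (default 0.70).
#' @param k permutation replicates per pair.
#' @param seed integer RNG seed.
#' @param permIterations see [permutationTest()].
#' @return list with \code{frequency} (named per-feature fraction of
#'   significant pairs), \code{retained} (character vector of features with
#'   frequency strictly above \code{retainFrac}), and \code{nPairs}.
#' @export
pairwiseSignificanceFrequency <- function(dataList, cfg = pclrcConfig(),
                                          alpha = 0.05, retainFrac = 0.70,
                                          k = 100L, seed = 1L,
                                          permIterations = NULL) {
  if (length(dataList) < 2)
    stop("need at least 2 networks in the category")
  P <- ncol(dataList[[1]])
  feats <- colnames(dataList[[1]])
  if (is.null(feats)) feats <- sprintf("feat%03d", seq_len(P))
  pairs <- utils::combn(length(dataList), 2)
  sig <- matrix(0, P, ncol(pairs))
  for (q in seq_len(ncol(pairs))) {
    res <- permutationTest(dataList[[pairs[1, q]]], dataList[[pairs[2, q]]],
                           cfg = cfg, k = k, seed = seed + q,
                           permIterations = permIterations)
    sig[, q] <- as.numeric(res@pAdj <= alpha)
  }
  freq <- rowMeans(sig)
  names(freq) <- feats
  list(frequency = freq,
       retained = feats[freq > retainFrac],
       nPairs = ncol(pairs))
}
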