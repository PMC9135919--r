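#' @describeIn InferredNetwork-class filtered signed weighted adjacency.
#' @export
setMethod("adjacency", "InferredNetwork", function(object) {
  a <- object@A
  dimnames(a) <- list(object@features, object@features)
  a
})

#' @describeIn InferredNetwork-class PCLRC edge retention probabilities.
#' @export
setMethod("edgeProbabilities", "InferredNetwork", function(object) {
  p <- object@Pmat
  dimnames(p) <- list(object@features, object@features)
  p
})

#' @describeIn InferredNetwork-class full Spearman correlation matrix.
#' @export
setMethod("corMatrix", "InferredNetwork", function(object) {
  r <- object@R
  dimnames(r) <- list(object@features, object@features)
  r
})

#' @describeIn CovscaModel-class K x L nonnegative network scores; each row
#'   places one network in the L-dimensional prototype space.
#' @export
setMethod("covscaScores", "CovscaModel", function(object) object@weights)

#' @describeIn CovscaModel-class J x L unit-norm prototype loadings; row norms
#'   rank features by their importance in shaping network differences.
#' @export
setMethod("covscaLoadings", "CovscaModel", function(object) {
  z <- object@Z
  if (length(object@features)) rownames(z) <- object@features
  z
})

#' @describeIn CovscaModel-class overall goodness-of-fit (percent of the total
#'   squared Frobenius norm of the matrix set explained by the model).
#' @export
setMethod("gof", "CovscaModel", function(object) object@gof)

#' @describeIn CovariateTable-class numeric samples x covariates matrix.
#' @export
setMethod("covariateValues", "CovariateTable", function(object) object@values)

#' @describeIn CovariateTable-class per-column variable type.
#' @export
setMethod("varType", "CovariateTable", function(object) {
  stats::setNames(object@type, colnames(object@values))
})

#' @describeIn CovariateTable-class per-column category label.
#' @export
setMethod("varCategory", "CovariateTable", function(object) {
  stats::setNames(object@category, colnames(object@values))
})

#' @rdname CovariateTable-class
#' @param x,i,j,drop matrix-style subsetting of samples (i) and covariates (j).
#' @param ... ignored.
#' @export
setMethod("[", "CovariateTable", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@values))
  if (missing(j)) j <- seq_len(ncol(x@values))
  if (is.character(j)) j <- match(j, colnames(x@values))
  new("CovariateTable",
      values = x@values[i, j, drop = FALSE],
      type = x@type[j], category = x@category[j])
})

setMethod("dim", "CovariateTable", function(x) dim(x@values))

setMethod("show", "CovariateTable", function(object) {
  cat(sprintf("CovariateTable: %d samples x %d covariates\n",
              nrow(object@values), ncol(object@values)))
  cat(sprintf("  types: %d continuous, %d dichotomous\n",
              sum(object@type == "continuous"),
              sum(object@type == "dichotomous")))
  cat(sprintf("  categories: %s\n",
              paste(unique(object@category), collapse = ", ")))
  nmiss <- sum(is.na(object@values))
  cat(sprintf("  missing entries: %d (%.1f%%)\n", nmiss,
              100 * nmiss / length(object@values)))
})

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec\n")
  cat(sprintf("  groups: n = %d / %d; P = %d features; M = %d covariates\n",
              object@nPerGroup[1], object@nPerGroup[2], object@P, object@M))
  cat(sprintf("  blocks: %d at Spearman rho = %.2f; rewired nodes: %s\n",
              object@nBlocks, object@withinBlockRho,
              if (length(object@rewiredNodes))
                paste(object@rewiredNodes, collapse = ", ") else "none"))
  cat(sprintf("  covariate effects: %d; missing rate: %.2f; seed: %d\n",
              length(object@covariateEffects), object@missingRate,
              object@seed))
})

setMethod("show", "InferredNetwork", function(object) {
  P <- length(object@features)
  ne <- sum(object@A[upper.tri(object@A)] != 0)
  cat(sprintf("InferredNetwork: %d nodes, %d edges (of %d possible)\n",
              P, ne, P * (P - 1) / 2))
  s <- object@settings
  if (length(s))
    cat(sprintf(
      "  PCLRC: %s iterations, subsample %s, keep %s, threshold %s\n",
      s$nIterations, s$subsampleFraction, s$keepFraction,
      s$probabilityThreshold))
})

setMethod("show", "DiffConnectivityResult", function(object) {
  cat(sprintf(
    "DiffConnectivityResult: %d features, k = %d permutations\n",
    length(object@features), object@k))
  cat(sprintf("  features with adjusted P <= 0.05: %d\n",
              sum(object@pAdj <= 0.05)))
})

setMethod("show", "CovscaModel", function(object) {
  cat(sprintf("CovscaModel: K = %d matrices, L = %d rank-1 prototypes\n",
              nrow(object@weights), ncol(object@weights)))
  cat(sprintf("  goodness-of-fit: %.2f%% (%s, %d restarts)\n", object@gof,
              if (object@converged) "converged" else "not converged",
              object@nRestarts))
})

setMethod("show", "NetworkEmbedding", function(object) {
  cat(sprintf("NetworkEmbedding: %d networks in 2-D (perplexity %.1f)\n",
              nrow(object@coords), object@perplexity))
})

#' Tidy per-feature summary of a differential connectivity test
#'
#' @param object a [DiffConnectivityResult-class].
#' @param ... ignored.
#' @return data.frame with feature, chiA, chiB, delta, pRaw, pAdj.
#' @export
setMethod("summary", "DiffConnectivityResult", function(object, ...) {
  data.frame(feature = object@features, chiA = object@chiA,
             chiB = object@chiB, delta = object@delta,
             pRaw = object@pRaw, pAdj = object@pAdj,
             stringsAsFactors = FALSE)
})
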