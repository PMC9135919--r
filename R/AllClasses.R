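#' @import methods
NULL

#' Cohort simulation specification
#'
#' Describes a two-group synthetic cohort: group sizes, feature and covariate
#' counts, the block-correlation structure of the features, which features are
#' rewired (change block membership) between the two groups, planted linear
#' covariate effects, and the covariate missingness rate.
#'
#' Features are organised into \code{nBlocks} correlated blocks (Gaussian
#' copula with a common within-block association strength on the Spearman
#' scale). Rewired features are singletons (block-free) in group A and form
#' one additional common block in group B, so that the set of features whose
#' connectivity genuinely differs between the groups is exactly
#' \code{rewiredNodes}.
#'
#' @slot nPerGroup integer(2), samples per group (A, B).
#' @slot P integer, number of features (metabolites + lipid fractions).
#' @slot M integer, number of clinical covariates.
#' @slot nBlocks integer, number of correlated feature blocks.
#' @slot blockSizes integer vector; when non-empty, explicit block sizes
#'   assigned to the first features (remaining features stay independent),
#'   overriding the equal split implied by \code{nBlocks}.
#' @slot withinBlockRho numeric in [0, 1), within-block Spearman association.
#' @slot rewiredNodes integer vector, indices of features rewired in group B.
#' @slot covariateEffects list of lists with elements \code{covariate}
#'   (index), \code{features} (integer vector) and \code{beta} (effect size on
#'   the log-concentration scale).
#' @slot missingRate numeric in [0, 0.25), MCAR missingness rate injected into
#'   the covariate table.
#' @slot seed integer RNG seed.
#'
#' @seealso [cohortSpec()], [generateCohort()]
#' @export
setClass("CohortSpec",
  representation(
    nPerGroup = "integer",
    P = "integer",
    M = "integer",
    nBlocks = "integer",
    blockSizes = "integer",
    withinBlockRho = "numeric",
    rewiredNodes = "integer",
    covariateEffects = "list",
    missingRate = "numeric",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (length(object@nPerGroup) != 2L || any(object@nPerGroup < 2L))
    msg <- c(msg, "nPerGroup must be two integers >= 2")
  if (length(object@P) != 1L || object@P < 2L)
    msg <- c(msg, "P must be a single integer >= 2")
  if (length(object@M) != 1L || object@M < 1L)
    msg <- c(msg, "M must be a single integer >= 1")
  if (object@nBlocks < 0L || object@nBlocks > object@P)
    msg <- c(msg, "nBlocks must lie in [0, P]")
  if (length(object@blockSizes) &&
      sum(object@blockSizes) + length(object@rewiredNodes) > object@P)
    msg <- c(msg, "blockSizes plus rewiredNodes exceed P features")
  if (object@withinBlockRho < 0 || object@withinBlockRho >= 1)
    msg <- c(msg, "withinBlockRho must lie in [0, 1)")
  if (length(object@rewiredNodes) &&
      (any(object@rewiredNodes < 1L) || any(object@rewiredNodes > object@P)))
    msg <- c(msg, "rewiredNodes must be indices in 1..P")
  if (anyDuplicated(object@rewiredNodes))
    msg <- c(msg, "rewiredNodes must be unique")
  if (object@missingRate < 0 || object@missingRate >= 0.25)
    msg <- c(msg, "missingRate must lie in [0, 0.25)")
  for (eff in object@covariateEffects) {
    if (!all(c("covariate", "features", "beta") %in% names(eff))) {
      msg <- c(msg, "each covariate effect needs covariate, features, beta")
      break
    }
    if (eff$covariate < 1 || eff$covariate > object@M ||
        any(eff$features < 1) || any(eff$features > object@P) ||
        !all(is.finite(eff$beta))) {
      msg <- c(msg, "covariate effect indices out of range or beta not finite")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Clinical covariate table
#'
#' A samples-by-covariates numeric matrix with per-column variable types
#' (\code{"continuous"} or \code{"dichotomous"}) and category labels (e.g.
#' diseases, bio-humoral, drugs, risk, familiarity). Missing values are
#' allowed; dichotomous columns are coded 0/1.
#'
#' @slot values numeric matrix, samples x covariates, NAs allowed.
#' @slot type character vector, one of "continuous"/"dichotomous" per column.
#' @slot category character vector, one category label per column.
#'
#' @seealso [covariateTable()], [filterMissingCovariates()],
#'   [imputeCovariates()]
#' @export
setClass("CovariateTable",
  representation(values = "matrix", type = "character", category = "character")
)

setValidity("CovariateTable", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if (length(object@type) != ncol(v))
    msg <- c(msg, "type must have one entry per column")
  if (length(object@category) != ncol(v))
    msg <- c(msg, "category must have one entry per column")
  if (!all(object@type %in% c("continuous", "dichotomous")))
    msg <- c(msg, "type entries must be 'continuous' or 'dichotomous'")
  dich <- which(object@type == "dichotomous")
  if (length(dich)) {
    vals <- v[, dich, drop = FALSE]
    if (!all(vals %in% c(0, 1) | is.na(vals)))
      msg <- c(msg, "dichotomous columns must be coded 0/1 (NA allowed)")
  }
  if (length(msg)) msg else TRUE
})

#' Inferred association network
#'
#' Result of PCLRC network inference on one data matrix: the full Spearman
#' correlation matrix \code{R}, the per-edge retention probability matrix
#' \code{Pmat} estimated by resampled CLR filtering, and the filtered signed
#' weighted adjacency \code{A} (equal to \code{R} where the edge probability
#' reaches the threshold, 0 elsewhere; zero diagonal).
#'
#' @slot R P x P Spearman correlation matrix.
#' @slot Pmat P x P edge retention probability matrix (entries in [0, 1]).
#' @slot A P x P filtered signed weighted adjacency.
#' @slot features character vector of feature labels.
#' @slot settings list snapshot of the inference settings used.
#'
#' @seealso [buildNetwork()], [filterNetwork()], [connectivity()]
#' @export
setClass("InferredNetwork",
  representation(R = "matrix", Pmat = "matrix", A = "matrix",
                 features = "character", settings = "list")
)

setValidity("InferredNetwork", function(object) {
  msg <- character()
  P <- length(object@features)
  for (nm in c("R", "Pmat", "A")) {
    m <- slot(object, nm)
    if (!identical(dim(m), c(P, P)))
      msg <- c(msg, sprintf("%s must be %d x %d", nm, P, P))
    else if (max(abs(m - t(m))) > 1e-8)
      msg <- c(msg, sprintf("%s must be symmetric", nm))
  }
  if (!length(msg)) {
    if (any(object@Pmat < -1e-12) || any(object@Pmat > 1 + 1e-12))
      msg <- c(msg, "Pmat entries must lie in [0, 1]")
    if (any(abs(object@A) > 1 + 1e-8))
      msg <- c(msg, "|A| entries must be <= 1")
    if (any(diag(object@A) != 0))
      msg <- c(msg, "diag(A) must be zero")
  }
  if (length(msg)) msg else TRUE
})

#' Differential connectivity test result
#'
#' Per-feature node connectivity in two group-specific networks, their
#' difference, the column-permutation null distribution, and raw plus
#' Benjamini-Hochberg adjusted P-values.
#'
#' @slot features character feature labels.
#' @slot chiA,chiB numeric connectivity per feature in networks A and B.
#' @slot delta numeric, chiA - chiB.
#' @slot null P x k matrix of permuted differential connectivities.
#' @slot pRaw,pAdj numeric raw and BH-adjusted permutation P-values.
#' @slot k integer number of permutation replicates.
#' @slot seed integer RNG seed used.
#'
#' @seealso [permutationTest()], [differentialConnectivity()]
#' @export
setClass("DiffConnectivityResult",
  representation(features = "character", chiA = "numeric", chiB = "numeric",
                 delta = "numeric", null = "matrix", pRaw = "numeric",
                 pAdj = "numeric", k = "integer", seed = "integer")
)

setValidity("DiffConnectivityResult", function(object) {
  msg <- character()
  P <- length(object@features)
  k <- object@k
  lens <- c(chiA = length(object@chiA), chiB = length(object@chiB),
            delta = length(object@delta), pRaw = length(object@pRaw),
            pAdj = length(object@pAdj))
  if (any(lens != P)) msg <- c(msg, "per-feature vectors must have length P")
  if (!identical(dim(object@null), c(P, k)))
    msg <- c(msg, "null must be a P x k matrix")
  if (any(object@pRaw < 1 / k - 1e-12) || any(object@pRaw > 1 + 1e-12))
    msg <- c(msg, "raw P-values must lie in [1/k, 1]")
  if (any(object@pAdj + 1e-12 < object@pRaw))
    msg <- c(msg, "adjusted P-values must be >= raw P-values")
  if (any(abs(object@delta) > P - 1 + 1e-8))
    msg <- c(msg, "|delta| must be <= P - 1")
  if (length(msg)) msg else TRUE
})

#' COVSCA model of a set of association matrices
#'
#' Approximates K symmetric association matrices S_k as nonnegative
#' combinations of L shared rank-1 prototypes: S_k ~ sum_l c_kl z_l z_l'.
#'
#' @slot Z J x L loading matrix, unit-norm columns.
#' @slot C K x L nonnegative weight (score) matrix.
#' @slot gof overall goodness-of-fit in percent.
#' @slot gofPerMatrix per-matrix goodness-of-fit in percent.
#' @slot loss alternating-least-squares loss trajectory of the best restart.
#' @slot converged logical convergence flag.
#' @slot nRestarts integer number of restarts tried.
#' @slot seed integer RNG seed.
#' @slot features character feature labels (rows of Z).
#'
#' @seealso [fitCovsca()], [covscaScores()], [covscaLoadings()]
#' @export
setClass("CovscaModel",
  representation(Z = "matrix", weights = "matrix", gof = "numeric",
                 gofPerMatrix = "numeric", loss = "numeric",
                 converged = "logical", nRestarts = "integer",
                 seed = "integer", features = "character")
)

setValidity("CovscaModel", function(object) {
  msg <- character()
  if (ncol(object@Z) != ncol(object@weights))
    msg <- c(msg, "Z and C must agree on the number of components")
  if (any(object@weights < -1e-10))
    msg <- c(msg, "weights C must be nonnegative")
  nrm <- sqrt(colSums(object@Z^2))
  if (any(abs(nrm - 1) > 1e-6))
    msg <- c(msg, "columns of Z must have unit norm")
  if (object@gof < -1e-8 || object@gof > 100 + 1e-8)
    msg <- c(msg, "gof must lie in [0, 100]")
  if (length(object@loss) > 1 &&
      any(diff(object@loss) > 1e-8 * (1 + object@loss[1])))
    msg <- c(msg, "loss trajectory must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' 2-D embedding of a set of networks
#'
#' t-SNE embedding of COVSCA scores: each row is one network.
#'
#' @slot coords K x 2 matrix of embedding coordinates.
#' @slot perplexity numeric t-SNE perplexity.
#' @slot seed integer RNG seed.
#' @slot labels character category label per network (may be empty).
#'
#' @seealso [embedNetworks()]
#' @export
setClass("NetworkEmbedding",
  representation(coords = "matrix", perplexity = "numeric",
                 seed = "integer", labels = "character")
)

setValidity("NetworkEmbedding", function(object) {
  msg <- character()
  if (ncol(object@coords) != 2L) msg <- c(msg, "coords must have 2 columns")
  if (!all(is.finite(object@coords))) msg <- c(msg, "coords must be finite")
  if (length(object@labels) &&
      length(object@labels) != nrow(object@coords))
    msg <- c(msg, "labels must have one entry per embedded network")
  if (length(msg)) msg else TRUE
})
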