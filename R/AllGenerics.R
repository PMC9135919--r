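#' Node connectivity of a weighted network
#'
#' The connectivity of node i is the sum of the absolute weights of its
#' incident edges, \eqn{\chi_i = \sum_{j \ne i} |a_{ij}|}. For a network whose
#' weights are absolute correlations, \eqn{0 \le \chi_i \le P - 1}.
#'
#' @param object an [InferredNetwork-class] or a symmetric weighted adjacency
#'   matrix with zero (or unit, which is ignored) diagonal.
#' @return named numeric vector of node connectivities.
#' @examples
#' A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 0.5; A[1, 3] <- A[3, 1] <- -0.8
#' connectivity(A)
#' @export
setGeneric("connectivity", function(object) standardGeneric("connectivity"))

#' @rdname InferredNetwork-class
#' @param object object to extract from.
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))

#' @rdname InferredNetwork-class
#' @export
setGeneric("edgeProbabilities",
           function(object) standardGeneric("edgeProbabilities"))

#' @rdname InferredNetwork-class
#' @export
setGeneric("corMatrix", function(object) standardGeneric("corMatrix"))

#' @rdname CovscaModel-class
#' @param object object to extract from.
#' @export
setGeneric("covscaScores", function(object) standardGeneric("covscaScores"))

#' @rdname CovscaModel-class
#' @export
setGeneric("covscaLoadings",
           function(object) standardGeneric("covscaLoadings"))

#' @rdname CovscaModel-class
#' @export
setGeneric("gof", function(object) standardGeneric("gof"))

#' @rdname CovariateTable-class
#' @param object object to extract from.
#' @export
setGeneric("covariateValues",
           function(object) standardGeneric("covariateValues"))

#' @rdname CovariateTable-class
#' @export
setGeneric("varType", function(object) standardGeneric("varType"))

#' @rdname CovariateTable-class
#' @export
setGeneric("varCategory", function(object) standardGeneric("varCategory"))
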