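# Data preparation: missingness filter on the clinical covariates, iterative
# random-forest imputation (missForest-style), log transformation, and
# explicit sample exclusion.

#' Drop covariates with too much missing data
#'
#' Retains exactly the covariate columns whose missing fraction is strictly
#' below \code{maxMissingFraction} (default: less than 25\% missing data),
#' preserving column order.
#'
#' @param covariates a [CovariateTable-class].
#' @param maxMissingFraction strict upper bound on the per-column missing
#'   fraction, in (0, 1].
#' @return the filtered [CovariateTable-class] with attribute
#'   \code{"dropped"}: a character vector of removed column names.
#' @export
filterMissingCovariates <- function(covariates, maxMissingFraction = 0.25) {
  stopifnot(is(covariates, "CovariateTable"),
            maxMissingFraction > 0, maxMissingFraction <= 1)
  frac <- colMeans(is.na(covariates@values))
  keep <- frac < maxMissingFraction
  if (!any(keep))
    stop("all covariates exceed the missingness limit of ",
         maxMissingFraction)
  out <- covariates[, which(keep)]
  attr(out, "dropped") <- colnames(covariates@values)[!keep]
  out
}

#' Impute missing covariate values with iterative random forests
#'
#' missForest-style imputation: missing entries are initialised with the
#' column mean (continuous) or mode (dichotomous); then, visiting columns in
#' order of increasing missingness, each incomplete column is regressed
#' (continuous) or classified (dichotomous) on all other columns with a
#' random forest and its missing entries replaced by the forest predictions.
#' The sweep is repeated until the change in imputed values stops decreasing
#' or \code{maxIter} is reached. Observed entries are never modified.
#'
#' @param covariates a [CovariateTable-class] whose columns all satisfy the
#'   missingness filter.
#' @param nTrees trees per forest (default 100).
#' @param maxIter maximum sweeps (default 10).
#' @param seed integer RNG seed; imputation is deterministic given the seed.
#' @return a complete [CovariateTable-class] with attribute
#'   \code{"iterations"}: the number of sweeps performed.
#' @export
imputeCovariates <- function(covariates, nTrees = 100L, maxIter = 10L,
                             seed = 1L) {
  stopifnot(is(covariates, "CovariateTable"))
  X <- covariates@values
  if (!is.numeric(X)) stop("covariate values must be numeric")
  miss <- is.na(X)
  if (!any(miss)) {
    attr(covariates, "iterations") <- 0L
    return(covariates)
  }
  type <- covariates@type
  nmissCol <- colSums(miss)
  visit <- order(nmissCol)
  visit <- visit[nmissCol[visit] > 0]
  # initial fill: mean / mode
  Ximp <- X
  for (j in which(nmissCol > 0)) {
    obs <- X[!miss[, j], j]
    fill <- if (type[j] == "dichotomous") {
      as.numeric(mean(obs) >= 0.5)
    } else mean(obs)
    Ximp[miss[, j], j] <- fill
  }
  colnames(Ximp) <- sprintf("V%d", seq_len(ncol(Ximp)))  # syntactic names
  prevDiff <- Inf
  iter <- 0L
  withSeed(seed, {
    repeat {
      iter <- iter + 1L
      Xold <- Ximp
      for (j in visit) {
        obsIdx <- which(!miss[, j])
        misIdx <- which(miss[, j])
        df <- as.data.frame(Ximp[, -j, drop = FALSE])
        y <- Ximp[obsIdx, j]
        if (type[j] == "dichotomous") y <- factor(y, levels = c(0, 1))
        if (length(unique(y)) < 2) {
          # degenerate column: constant observed values
          pred <- rep(if (is.factor(y)) as.numeric(as.character(y[1]))
                      else y[1], length(misIdx))
        } else {
          fit <- ranger::ranger(
            x = df[obsIdx, , drop = FALSE], y = y,
            num.trees = nTrees, seed = seed + iter, num.threads = 1)
          pred <- stats::predict(fit, df[misIdx, , drop = FALSE],
                                 num.threads = 1)$predictions
          if (is.factor(pred)) pred <- as.numeric(as.character(pred))
        }
        Ximp[misIdx, j] <- pred
      }
      d <- sum((Ximp[miss] - Xold[miss])^2) / max(sum(Ximp[miss]^2), 1e-12)
      if (d >= prevDiff || iter >= maxIter) {
        if (d >= prevDiff) Ximp <- Xold  # keep the last improving iterate
        break
      }
      prevDiff <- d
    }
  })
  out <- covariates
  out@values[] <- Ximp
  out@values[!miss] <- X[!miss]  # observed entries unchanged, by construction
  dimnames(out@values) <- dimnames(X)
  validObject(out)
  attr(out, "iterations") <- iter
  out
}

#' Log-transform continuous variables
#'
#' Replaces continuous columns by \code{log(value + offset)}; dichotomous
#' columns pass through unchanged (a 0/1 indicator cannot be log-transformed).
#' Being strictly monotone per column, the transform leaves Spearman
#' correlations among continuous features unchanged.
#'
#' @param data a numeric concentration matrix (all columns treated as
#'   continuous) or a [CovariateTable-class].
#' @param offset nonnegative value added before taking the natural log
#'   (for zero handling); default 0.
#' @return the same type and shape as \code{data}.
#' @export
logTransform <- function(data, offset = 0) {
  stopifnot(offset >= 0)
  if (is(data, "CovariateTable")) {
    out <- data
    for (j in which(data@type == "continuous")) {
      v <- data@values[, j] + offset
      if (any(v[!is.na(v)] <= 0))
        stop("nonpositive values in continuous column '",
             colnames(data@values)[j], "'; use a positive offset")
      out@values[, j] <- log(v)
    }
    return(out)
  }
  m <- as.matrix(data)
  v <- m + offset
  bad <- which(apply(v, 2, function(col) any(col[!is.na(col)] <= 0)))
  if (length(bad))
    stop("nonpositive values in column(s) ",
         paste(colnames(m)[bad], collapse = ", "),
         "; use a positive offset")
  log(v)
}

#' Exclude flagged samples by ID
#'
#' @param data a matrix with sample-ID rownames or a [CovariateTable-class].
#' @param ids character vector of sample IDs to remove.
#' @return \code{data} without the excluded rows.
#' @export
excludeSamples <- function(data, ids) {
  if (!length(ids)) return(data)
  if (is(data, "CovariateTable")) {
    keep <- !(rownames(data@values) %in% ids)
    return(data[which(keep), ])
  }
  data[!(rownames(data) %in% ids), , drop = FALSE]
}
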