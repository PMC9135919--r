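# Covariate signal extraction: for each feature, isolate the part of its
# concentration associated with one chosen clinical covariate (main effect
# plus first-order interactions of that covariate), while adjusting for the
# remaining covariates, via penalized least squares.

#' Covariate-specific signal matrix
#'
#' For one target covariate m: the n x P matrix of extracted signals (the part
#' of each feature's concentration associated with m), the fitted
#' coefficients of the m-involving terms, and per-feature R-squared of the
#' full regression.
#'
#' @slot values n x P extracted signal matrix.
#' @slot covariate name of the target covariate.
#' @slot coefficients (1 + (M-1)) x P matrix: rows are the m-involving design
#'   terms (main effect, then interactions), columns are features.
#' @slot r2 per-feature R-squared of the full fit.
#' @seealso [extractSignal()], [extractAll()]
#' @export
setClass("CovariateSignalMatrix",
  representation(values = "matrix", covariate = "character",
                 coefficients = "matrix", r2 = "numeric")
)

setValidity("CovariateSignalMatrix", function(object) {
  msg <- character()
  if (!all(is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (ncol(object@values) != ncol(object@coefficients))
    msg <- c(msg, "coefficients must have one column per feature")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CovariateSignalMatrix", function(object) {
  cat(sprintf(
    "CovariateSignalMatrix for '%s': %d samples x %d features (mean R2 %.3f)\n",
    object@covariate, nrow(object@values), ncol(object@values),
    mean(object@r2)))
})

#' @describeIn CovariateSignalMatrix-class the n x P extracted signal matrix.
#' @param object a CovariateSignalMatrix.
#' @export
signalValues <- function(object) object@values

standardizeColumns <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  Xs <- sweep(X, 2, mu)
  ok <- sd > 0
  Xs[, ok] <- sweep(Xs[, ok, drop = FALSE], 2, sd[ok], "/")
  list(X = Xs, constant = !ok)
}

#' Build the target-covariate design block
#'
#' Columns are the standardized target covariate \eqn{X_m} followed by its
#' pairwise products with every other standardized covariate
#' (\eqn{X_m \circ X_j}, j != m): 1 + (M - 1) columns. Constant columns
#' (including interactions that become constant) are dropped with a warning.
#'
#' @param X a complete [CovariateTable-class] or numeric matrix.
#' @param m target covariate: name or column index.
#' @return list with \code{design} (n x width matrix, named columns),
#'   \code{terms} (character: "main" or the interacting covariate name) and
#'   \code{m} (the target covariate name).
#' @export
buildDesign <- function(X, m) {
  Xv <- if (is(X, "CovariateTable")) covariateValues(X) else as.matrix(X)
  if (anyNA(Xv)) stop("covariates must be complete (impute first)")
  if (is.null(colnames(Xv))) colnames(Xv) <- sprintf("cov%03d", seq_len(ncol(Xv)))
  if (is.character(m)) {
    mi <- match(m, colnames(Xv))
    if (is.na(mi)) stop("covariate '", m, "' not found")
  } else {
    mi <- as.integer(m)
    if (mi < 1 || mi > ncol(Xv)) stop("covariate index out of range")
  }
  mName <- colnames(Xv)[mi]
  st <- standardizeColumns(Xv)
  Xs <- st$X
  xm <- Xs[, mi]
  others <- setdiff(seq_len(ncol(Xv)), mi)
  D <- cbind(xm, xm * Xs[, others, drop = FALSE])
  colnames(D) <- c(mName, paste0(mName, ":", colnames(Xv)[others]))
  terms <- c("main", colnames(Xv)[others])
  const <- apply(D, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning("dropping constant design column(s): ",
            paste(colnames(D)[const], collapse = ", "))
    D <- D[, !const, drop = FALSE]
    terms <- terms[!const]
  }
  list(design = D, terms = terms, m = mName)
}

#' Extract the covariate-specific part of each feature
#'
#' Each feature (column of \code{Y}) is regressed on all standardized
#' covariate main effects plus the first-order interactions of the target
#' covariate m, by lasso-penalized least squares with the penalty chosen by
#' cross-validation (the full model has ~2M columns and is near/under-
#' determined at typical cohort sizes). The extracted signal
#' \eqn{\hat Y^{(p)}} is then reconstructed from the m-involving terms only
#' (main effect plus interactions), which implicitly adjusts for the
#' remaining M - 1 covariates.
#'
#' @param Y n x P concentration (or log-concentration) matrix, row-aligned
#'   with \code{X}.
#' @param X a complete [CovariateTable-class] or covariate matrix.
#' @param m target covariate name or index.
#' @param penalty "lasso" (default; cross-validated) or "none" (ordinary
#'   least squares, for small well-determined problems).
#' @param nfolds cross-validation folds for the lasso penalty (default 10).
#' @param seed integer RNG seed (fixes the CV fold assignment).
#' @return a [CovariateSignalMatrix-class].
#' @export
extractSignal <- function(Y, X, m, penalty = c("lasso", "none"),
                          nfolds = 10L, seed = 1L) {
  penalty <- match.arg(penalty)
  Y <- as.matrix(Y)
  Xv <- if (is(X, "CovariateTable")) covariateValues(X) else as.matrix(X)
  if (is.null(colnames(Xv)))
    colnames(Xv) <- sprintf("cov%03d", seq_len(ncol(Xv)))
  if (nrow(Y) != nrow(Xv)) stop("Y and X must be row-aligned")
  des <- withCallingHandlers(
    buildDesign(Xv, m),
    warning = function(w) invokeRestart("muffleWarning"))
  mName <- des$m
  st <- standardizeColumns(Xv)
  mi <- match(mName, colnames(Xv))
  others <- setdiff(seq_len(ncol(st$X)), mi)
  mains <- st$X[, others, drop = FALSE]
  mains <- mains[, apply(mains, 2, function(v) stats::sd(v) > 0),
                 drop = FALSE]
  full <- cbind(des$design, mains)
  nTarget <- ncol(des$design)
  n <- nrow(full)
  P <- ncol(Y)
  feats <- colnames(Y)
  if (is.null(feats)) feats <- sprintf("feat%03d", seq_len(P))

  coefs <- matrix(0, nTarget, P,
                  dimnames = list(colnames(des$design), feats))
  values <- matrix(0, n, P, dimnames = list(rownames(Y), feats))
  r2 <- numeric(P)

  if (penalty == "none") {
    if (qr(cbind(1, full))$rank < ncol(full) + 1)
      stop("design is rank-deficient; use penalty = \"lasso\"")
    for (p in seq_len(P)) {
      fit <- stats::lm.fit(cbind(`(Intercept)` = 1, full), Y[, p])
      b <- fit$coefficients[-1]
      coefs[, p] <- b[seq_len(nTarget)]
      values[, p] <- des$design %*% coefs[, p]
      r2[p] <- 1 - sum(fit$residuals^2) /
        max(sum((Y[, p] - mean(Y[, p]))^2), 1e-300)
    }
  } else {
    foldid <- withSeed(seed, sample(rep_len(seq_len(nfolds), n)))
    for (p in seq_len(P)) {
      cv <- glmnet::cv.glmnet(full, Y[, p], alpha = 1, foldid = foldid,
                              standardize = TRUE)
      b <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
      coefs[, p] <- b[seq_len(nTarget)]
      values[, p] <- des$design %*% coefs[, p]
      yhat <- as.numeric(stats::predict(cv, newx = full, s = "lambda.min"))
      r2[p] <- 1 - sum((Y[, p] - yhat)^2) /
        max(sum((Y[, p] - mean(Y[, p]))^2), 1e-300)
    }
  }
  new("CovariateSignalMatrix", values = values, covariate = mName,
      coefficients = coefs, r2 = r2)
}

#' Extract signal matrices for every covariate
#'
#' Runs [extractSignal()] for each retained covariate, producing one n x P
#' signal matrix per covariate. Results are independent across covariates.
#'
#' @inheritParams extractSignal
#' @param covariates covariate names or indices (default: all columns of X).
#' @param verbose log progress with message() (default FALSE).
#' @return named list of [CovariateSignalMatrix-class], one per covariate.
#' @export
extractAll <- function(Y, X, covariates = NULL, penalty = "lasso",
                       nfolds = 10L, seed = 1L, verbose = FALSE) {
  Xv <- if (is(X, "CovariateTable")) covariateValues(X) else as.matrix(X)
  if (is.null(covariates)) covariates <- colnames(Xv) %||% seq_len(ncol(Xv))
  out <- vector("list", length(covariates))
  nms <- character(length(covariates))
  for (i in seq_along(covariates)) {
    if (verbose) message("extracting covariate ", covariates[[i]])
    sig <- extractSignal(Y, X, covariates[[i]], penalty = penalty,
                         nfolds = nfolds, seed = seed)
    out[[i]] <- sig
    nms[i] <- sig@covariate
  }
  names(out) <- nms
  out
}
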