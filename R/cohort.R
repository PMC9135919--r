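# Synthetic two-group cohort generator. Emulates an NMR metabolomics aging
# cohort: two groups of unequal size, block-correlated metabolite/lipid
# concentrations (Gaussian copula, log-normal margins), a mixed
# continuous/dichotomous clinical covariate table in five categories, planted
# linear covariate effects, planted between-group network rewiring, and MCAR
# missingness restricted to the covariates.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded package internals do
#' not perturb the user's random stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Construct a cohort simulation specification
#'
#' Defaults emulate the study conditions the package targets: two groups of
#' 259 and 96 subjects, P = 134 features (20 metabolites + 114 lipoprotein
#' fractions and sub-fractions), M = 101 clinical covariates in five
#' categories, block-correlated features, and under 25\% covariate
#' missingness.
#'
#' @param nPerGroup integer(2) samples per group.
#' @param P number of features.
#' @param M number of covariates.
#' @param nBlocks number of correlated feature blocks (equal split of the
#'   non-rewired features).
#' @param blockSizes optional explicit block sizes assigned to the first
#'   non-rewired features (remaining features stay independent); overrides
#'   \code{nBlocks}.
#' @param withinBlockRho within-block association strength (Spearman scale),
#'   in [0, 1).
#' @param rewiredNodes integer indices of features whose block membership
#'   differs between the groups (singletons in group A, one common new block
#'   in group B).
#' @param covariateEffects list of \code{list(covariate=, features=, beta=)}
#'   planted linear effects on the log-concentration scale.
#' @param missingRate MCAR missingness rate for covariates, in [0, 0.25).
#' @param seed integer RNG seed.
#' @return a validated [CohortSpec-class].
#' @examples
#' spec <- cohortSpec(nPerGroup = c(60, 40), P = 20, M = 6, seed = 1)
#' spec
#' @export
cohortSpec <- function(nPerGroup = c(259L, 96L), P = 134L, M = 101L,
                       nBlocks = 8L, blockSizes = integer(),
                       withinBlockRho = 0.7,
                       rewiredNodes = integer(),
                       covariateEffects = list(),
                       missingRate = 0.1, seed = 1L) {
  if (length(blockSizes)) nBlocks <- length(blockSizes)
  new("CohortSpec",
      nPerGroup = as.integer(nPerGroup), P = as.integer(P), M = as.integer(M),
      nBlocks = as.integer(nBlocks), blockSizes = as.integer(blockSizes),
      withinBlockRho = as.numeric(withinBlockRho),
      rewiredNodes = as.integer(sort(rewiredNodes)),
      covariateEffects = covariateEffects,
      missingRate = as.numeric(missingRate), seed = as.integer(seed))
}

#' Read a cohort specification from a YAML file
#'
#' @param path YAML file with the fields of [cohortSpec()] (snake_case or
#'   camelCase keys accepted).
#' @return a [CohortSpec-class].
#' @export
cohortSpecFromYaml <- function(path) {
  y <- yaml::read_yaml(path)
  names(y) <- gsub("_(\\w)", "\\U\\1", names(y), perl = TRUE)
  eff <- y$covariateEffects
  if (!is.null(eff))
    eff <- lapply(eff, function(e) {
      names(e) <- gsub("_(\\w)", "\\U\\1", names(e), perl = TRUE)
      list(covariate = e$covariate, features = unlist(e$features),
           beta = e$beta)
    })
  do.call(cohortSpec, c(
    y[intersect(names(y), c("nPerGroup", "P", "M", "nBlocks", "blockSizes",
                            "withinBlockRho", "rewiredNodes", "missingRate",
                            "seed"))],
    if (!is.null(eff)) list(covariateEffects = eff)))
}

# Spearman -> latent Pearson correlation for a Gaussian copula.
spearmanToLatent <- function(rho) 2 * sin(pi * rho / 6)

# Block assignment: non-rewired features are split contiguously into blocks
# (equal split into nBlocks, or explicit blockSizes with any remainder left
# independent); rewired nodes are singletons (0) in group A and form one
# extra common block in group B.
blockAssignments <- function(P, nBlocks, rewired, blockSizes = integer()) {
  base <- integer(P)
  free <- setdiff(seq_len(P), rewired)
  if (length(blockSizes)) {
    lab <- rep(seq_along(blockSizes), blockSizes)
    base[free[seq_along(lab)]] <- lab
    nBlocks <- length(blockSizes)
  } else if (nBlocks > 0L && length(free)) {
    base[free] <- as.integer(ceiling(seq_along(free) * nBlocks /
                                       length(free)))
  }
  a <- base
  b <- base
  if (length(rewired)) b[rewired] <- nBlocks + 1L
  list(A = a, B = b)
}

blockCovariance <- function(assignment, rho) {
  P <- length(assignment)
  S <- diag(P)
  if (rho > 0) {
    for (blk in setdiff(unique(assignment), 0L)) {
      idx <- which(assignment == blk)
      if (length(idx) > 1) {
        S[idx, idx] <- rho
        diag(S)[idx] <- 1
      }
    }
  }
  S
}

# Category plan mirroring a typical clinical covariate battery: diseases,
# familiarity and drug treatments are dichotomous; risk factors and
# bio-humoral parameters continuous. Proportions follow the 20/5/13/12/51
# split of the emulated covariate battery.
covariatePlan <- function(M) {
  cats <- c("diseases", "familiarity", "drugs", "risk", "biohumoral")
  prop <- c(20, 5, 13, 12, 51) / 101
  counts <- floor(prop * M)
  rem <- M - sum(counts)
  if (rem > 0) {
    extra <- order(prop * M - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  category <- rep(cats, counts)
  type <- ifelse(category %in% c("diseases", "familiarity", "drugs"),
                 "dichotomous", "continuous")
  list(category = category, type = type)
}

#' Generate a seeded synthetic two-group cohort
#'
#' Draws, for each group, latent multivariate Gaussian features with the
#' block covariance implied by the spec (rewired nodes move to a new block in
#' group B), adds the planted linear covariate effects on the latent (log)
#' scale, exponentiates to log-normal concentrations, draws the covariate
#' table (Bernoulli via thresholded latent Gaussians for dichotomous columns,
#' log-normal for continuous ones), and injects MCAR missingness into the
#' covariates only. Fully reproducible from \code{spec@seed}.
#'
#' @param spec a [CohortSpec-class].
#' @return list with elements \code{concentrations} (list \code{A}, \code{B}
#'   of samples x P matrices), \code{covariates} (list \code{A}, \code{B} of
#'   [CovariateTable-class]), and \code{groundTruth} (block assignments per
#'   group, the true differential-connectivity node set, the planted
#'   covariate effects and the seed).
#' @examples
#' ch <- generateCohort(cohortSpec(nPerGroup = c(50, 40), P = 12, M = 5,
#'                                 nBlocks = 2, seed = 7))
#' dim(ch$concentrations$A)
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  P <- spec@P; M <- spec@M
  asg <- blockAssignments(P, spec@nBlocks, spec@rewiredNodes,
                          spec@blockSizes)
  rhoL <- spearmanToLatent(spec@withinBlockRho)
  SigA <- blockCovariance(asg$A, rhoL)
  SigB <- blockCovariance(asg$B, rhoL)
  plan <- covariatePlan(M)
  featNames <- sprintf("feat%03d", seq_len(P))
  covNames <- sprintf("cov%03d_%s", seq_len(M), plan$category)

  out <- withSeed(spec@seed, {
    # shared feature/covariate parameters (identical across groups)
    mu <- stats::runif(P, log(10), log(200))
    sigma <- stats::runif(P, 0.2, 0.4)
    prevalence <- stats::runif(M, 0.1, 0.5)
    covMeanLog <- stats::runif(M, 0, 2)

    drawGroup <- function(n, Sigma, grp) {
      Z <- MASS::mvrnorm(n, mu = rep(0, P), Sigma = Sigma)
      # covariates
      X <- matrix(NA_real_, n, M, dimnames = list(NULL, covNames))
      for (m in seq_len(M)) {
        if (plan$type[m] == "dichotomous") {
          X[, m] <- as.numeric(stats::rnorm(n) <
                                 stats::qnorm(prevalence[m]))
        } else {
          X[, m] <- exp(covMeanLog[m] + 0.5 * stats::rnorm(n))
        }
      }
      # planted linear covariate effects, on the latent (log) scale
      for (eff in spec@covariateEffects) {
        x <- X[, eff$covariate]
        xs <- if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
        Z[, eff$features] <- Z[, eff$features] + eff$beta * xs
      }
      Y <- exp(sweep(sweep(Z, 2, sigma, "*"), 2, mu, "+"))
      dimnames(Y) <- list(sprintf("%s_%04d", grp, seq_len(n)), featNames)
      rownames(X) <- rownames(Y)
      # MCAR missingness, covariates only
      if (spec@missingRate > 0) {
        nmiss <- round(spec@missingRate * length(X))
        X[sample.int(length(X), nmiss)] <- NA_real_
      }
      list(Y = Y, X = X)
    }

    gA <- drawGroup(spec@nPerGroup[1], SigA, "A")
    gB <- drawGroup(spec@nPerGroup[2], SigB, "B")
    list(gA = gA, gB = gB)
  })

  mkCov <- function(X) new("CovariateTable", values = X,
                           type = plan$type, category = plan$category)
  list(
    concentrations = list(A = out$gA$Y, B = out$gB$Y),
    covariates = list(A = mkCov(out$gA$X), B = mkCov(out$gB$X)),
    groundTruth = list(
      blockAssignment = list(A = asg$A, B = asg$B),
      differentialNodes = spec@rewiredNodes,
      covariateEffects = spec@covariateEffects,
      seed = spec@seed))
}

#' Generate a synthetic set of low-rank symmetric matrices
#'
#' Builds K symmetric J x J matrices \eqn{S_k = \sum_l c_{kl} z_l z_l^T + E_k}
#' with nonnegative weights, unit-norm loading vectors and symmetric Gaussian
#' noise, for validating the COVSCA fitting routine.
#'
#' @param K number of matrices (K >= L).
#' @param L number of rank-1 prototypes (L <= J).
#' @param J matrix dimension.
#' @param noiseSd standard deviation of the symmetric Gaussian noise.
#' @param seed integer RNG seed.
#' @return list with \code{S} (list of K matrices), \code{C} (true K x L
#'   weights), \code{Z} (true J x L unit-norm loadings).
#' @examples
#' set <- generateCovscaSet(K = 5, L = 2, J = 8, noiseSd = 0, seed = 3)
#' length(set$S)
#' @export
generateCovscaSet <- function(K, L, J, noiseSd = 0, seed = 1L) {
  stopifnot(L <= J, K >= L, noiseSd >= 0)
  withSeed(seed, {
    Z <- matrix(stats::rnorm(J * L), J, L)
    Z <- sweep(Z, 2, sqrt(colSums(Z^2)), "/")
    C <- matrix(stats::runif(K * L, 0.2, 2), K, L)
    S <- lapply(seq_len(K), function(k) {
      Sk <- Z %*% diag(C[k, ], L, L) %*% t(Z)
      if (noiseSd > 0) {
        E <- matrix(stats::rnorm(J * J, sd = noiseSd), J, J)
        Sk <- Sk + (E + t(E)) / 2
      }
      Sk
    })
    list(S = S, C = C, Z = Z)
  })
}

#' Write a synthetic cohort to the standard pipeline input files
#'
#' Writes \code{concentrations_A.csv}, \code{concentrations_B.csv},
#' \code{covariates_A.csv}, \code{covariates_B.csv} (each with a sample-ID
#' first column; covariate files carry \code{#type} and \code{#category}
#' header comment lines) and \code{ground_truth.json}.
#'
#' @param cohort result of [generateCohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (g in c("A", "B")) {
    pc <- file.path(dir, sprintf("concentrations_%s.csv", g))
    writeMatrixCsv(cohort$concentrations[[g]], pc)
    pv <- file.path(dir, sprintf("covariates_%s.csv", g))
    writeCovariateCsv(cohort$covariates[[g]], pv)
    paths <- c(paths, pc, pv)
  }
  pg <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(cohort$groundTruth, pg, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, pg))
}
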