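# End-to-end orchestration: simulate -> preprocess -> extract -> infer ->
# diffnet -> covsca -> embed. All stages exchange data through CSV files in
# the output directory, so runs are resumable and byte-reproducible from the
# configuration and the global seed.

#' Assemble a pipeline configuration
#'
#' Per-stage settings with defaults sized for a desk-scale demonstration run;
#' every analysis constant (25\% covariate missingness limit, 0.90 edge
#' probability threshold, k = 100 permutations, alpha = 0.05, 70\% retention,
#' L = 3 prototypes) is pre-filled and overridable. Exactly one of
#' \code{simulation} (a [CohortSpec-class] or argument list for
#' [cohortSpec()]) or \code{inputs} (named paths \code{concA}, \code{covA},
#' \code{concB}, \code{covB}) must be provided.
#'
#' @param outdir output directory.
#' @param seed global seed; all stage seeds derive deterministically from it.
#' @param simulation simulation spec ([cohortSpec()] arguments or object).
#' @param inputs named list of input file paths (alternative to simulation).
#' @param preprocess,extract,infer,diffnet,covsca,embed per-stage overrides.
#' @return nested configuration list.
#' @export
pipelineConfig <- function(outdir, seed = 1L, simulation = NULL,
                           inputs = NULL, preprocess = list(),
                           extract = list(), infer = list(),
                           diffnet = list(), covsca = list(),
                           embed = list()) {
  if (is.null(simulation) == is.null(inputs))
    stop("provide exactly one of 'simulation' or 'inputs'")
  merge <- function(defaults, user) utils::modifyList(defaults, user)
  list(
    outdir = outdir, seed = as.integer(seed),
    simulation = simulation, inputs = inputs,
    preprocess = merge(list(maxMissingFraction = 0.25, logOffset = 0,
                            excludedSampleIds = character(),
                            imputeNTrees = 100L, imputeMaxIter = 10L),
                       preprocess),
    extract = merge(list(covariates = NULL, penalty = "lasso",
                         nfolds = 10L), extract),
    infer = merge(list(nIterations = 200L, subsampleFraction = 0.75,
                       keepFraction = 0.30, probabilityThreshold = 0.90,
                       displayThreshold = 0.6), infer),
    diffnet = merge(list(k = 100L, alpha = 0.05, retainFrac = 0.70,
                         permIterations = 100L), diffnet),
    covsca = merge(list(L = 3L, nRestarts = 10L, maxIter = 500L,
                        tol = 1e-9, useRaw = FALSE), covsca),
    embed = merge(list(perplexity = NULL, nIter = 1000L), embed))
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match the arguments of
#'   [pipelineConfig()].
#' @return configuration list.
#' @export
pipelineConfigFromYaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) y$simulation <- as.list(y$simulation)
  do.call(pipelineConfig, y)
}

stageSeed <- function(seed, stage, item = 0L) {
  as.integer((seed %% 100000L) * 10000L + stage * 211L + item)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: \code{simulate} (or input validation), covariate
#' \code{preprocess} (missingness filter, random-forest imputation, log
#' transform), covariate-signal \code{extract}, PCLRC network \code{infer}
#' per group and covariate, differential-connectivity \code{diffnet} per
#' covariate (group A vs group B), \code{covsca} decomposition per group, and
#' 2-D \code{embed}ding of the scores. Writes a JSON manifest with the stage
#' list, derived seeds and MD5 hashes of every output, and returns it.
#'
#' @param config configuration from [pipelineConfig()].
#' @param resume skip stages whose outputs already exist (default FALSE).
#' @param verbose log stage progress via message() (default TRUE).
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config, resume = FALSE, verbose = TRUE) {
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  groups <- c("A", "B")
  manifest <- list(package = "MetLipNet",
                   version = as.character(utils::packageVersion("MetLipNet")),
                   seed = config$seed, stages = list())
  files <- list()
  note <- function(...) if (verbose) message(sprintf(...))
  stageDir <- function(s) {
    d <- file.path(out, s)
    dir.create(d, showWarnings = FALSE)
    d
  }
  done <- function(s, outputs) {
    manifest$stages[[s]] <<- list(
      stage = s, seed = stageSeed(config$seed, match(s, stageNames)),
      outputs = as.list(tools::md5sum(outputs)))
    files[[s]] <<- outputs
    note("stage %s: %d output file(s)", s, length(outputs))
  }
  skip <- function(s, outputs) resume && all(file.exists(outputs))
  stageNames <- c("simulate", "preprocess", "extract", "infer", "diffnet",
                  "covsca", "embed")
  runStage <- function(s, outputs, body) {
    if (skip(s, outputs)) note("stage %s: resumed (outputs exist)", s)
    else tryCatch(body(), error = function(e)
      stop("pipeline stage '", s, "' failed: ", conditionMessage(e),
           call. = FALSE))
    done(s, outputs)
  }

  ## 1. simulate (or stage the provided inputs)
  d1 <- stageDir("simulate")
  p1 <- file.path(d1, c("concentrations_A.csv", "covariates_A.csv",
                        "concentrations_B.csv", "covariates_B.csv"))
  runStage("simulate", p1, function() {
    if (!is.null(config$simulation)) {
      spec <- config$simulation
      if (!is(spec, "CohortSpec")) {
        spec$seed <- spec$seed %||% stageSeed(config$seed, 1L)
        spec <- do.call(cohortSpec, spec)
      }
      writeCohort(generateCohort(spec), d1)
    } else {
      v <- validateInputs(config$inputs$concA, config$inputs$covA)
      v2 <- validateInputs(config$inputs$concB, config$inputs$covB)
      if (!v$ok || !v2$ok)
        stop("input validation failed: ",
             paste(c(v$violations, v2$violations), collapse = "; "))
      file.copy(unlist(config$inputs[c("concA", "covA", "concB", "covB")]),
                p1, overwrite = TRUE)
    }
  })

  ## 2. preprocess: exclusion, pooled missingness filter + imputation, log
  d2 <- stageDir("preprocess")
  p2 <- file.path(d2, c("logconc_A.csv", "logconc_B.csv",
                        "covariates_A.csv", "covariates_B.csv",
                        "report.json"))
  runStage("preprocess", p2, function() {
    pp <- config$preprocess
    conc <- lapply(seq_along(groups), function(i)
      excludeSamples(readConcentrations(p1[2 * i - 1]),
                     pp$excludedSampleIds))
    cov <- lapply(seq_along(groups), function(i)
      excludeSamples(readCovariates(p1[2 * i]), pp$excludedSampleIds))
    pooled <- new("CovariateTable",
                  values = rbind(cov[[1]]@values, cov[[2]]@values),
                  type = cov[[1]]@type, category = cov[[1]]@category)
    filt <- filterMissingCovariates(pooled, pp$maxMissingFraction)
    imp <- imputeCovariates(filt, nTrees = pp$imputeNTrees,
                            maxIter = pp$imputeMaxIter,
                            seed = stageSeed(config$seed, 2L))
    nA <- nrow(cov[[1]]@values)
    for (i in seq_along(groups)) {
      rows <- if (i == 1) seq_len(nA) else nA + seq_len(nrow(cov[[2]]@values))
      covg <- logTransform(imp[rows, ], offset = pp$logOffset)
      writeCovariateCsv(covg, p2[2 + i])
      writeMatrixCsv(logTransform(conc[[i]], offset = pp$logOffset), p2[i])
    }
    report <- list(
      droppedCovariates = as.list(attr(filt, "dropped") %||% character()),
      imputationIterations = attr(imp, "iterations"),
      excludedSamples = as.list(pp$excludedSampleIds))
    jsonlite::write_json(report, p2[5], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })

  covNamesOf <- function() {
    cv <- readCovariates(p2[3])
    config$extract$covariates %||% colnames(covariateValues(cv))
  }
  covNames <- covNamesOf()

  ## 3. extract covariate-specific signal matrices, within group
  d3 <- stageDir("extract")
  p3 <- as.vector(outer(covNames, groups, function(m, g)
    file.path(d3, sprintf("signal_%s_%s.csv", m, g))))
  runStage("extract", p3, function() {
    for (gi in seq_along(groups)) {
      Y <- readConcentrations(p2[gi])
      Xg <- readCovariates(p2[2 + gi])
      sigs <- extractAll(Y, Xg, covariates = covNames,
                         penalty = config$extract$penalty,
                         nfolds = config$extract$nfolds,
                         seed = stageSeed(config$seed, 3L, gi))
      for (m in names(sigs))
        writeMatrixCsv(signalValues(sigs[[m]]),
                       file.path(d3, sprintf("signal_%s_%s.csv", m,
                                             groups[gi])))
    }
  })

  ## 4. infer one PCLRC network per (group, covariate)
  d4 <- stageDir("infer")
  p4 <- character()
  for (g in groups)
    for (m in covNames)
      p4 <- c(p4, file.path(d4, sprintf(
        c("adj_%s_%s.csv", "cor_%s_%s.csv", "prob_%s_%s.csv",
          "edges_%s_%s.csv"), m, g)))
  runStage("infer", p4, function() {
    inf <- config$infer
    for (gi in seq_along(groups)) {
      g <- groups[gi]
      for (mi in seq_along(covNames)) {
        m <- covNames[mi]
        sig <- readConcentrations(
          file.path(d3, sprintf("signal_%s_%s.csv", m, g)))
        cfg <- pclrcConfig(inf$nIterations, inf$subsampleFraction,
                           inf$keepFraction, inf$probabilityThreshold,
                           seed = stageSeed(config$seed, 4L,
                                            gi * 1000L + mi))
        net <- buildNetwork(sig, cfg)
        writeMatrixCsv(adjacency(net),
                       file.path(d4, sprintf("adj_%s_%s.csv", m, g)))
        writeMatrixCsv(corMatrix(net),
                       file.path(d4, sprintf("cor_%s_%s.csv", m, g)))
        writeMatrixCsv(edgeProbabilities(net),
                       file.path(d4, sprintf("prob_%s_%s.csv", m, g)))
        utils::write.csv(edgeList(net),
                         file.path(d4, sprintf("edges_%s_%s.csv", m, g)),
                         row.names = FALSE, quote = FALSE)
      }
    }
  })

  ## 5. differential connectivity, group A vs group B, per covariate
  d5 <- stageDir("diffnet")
  p5 <- file.path(d5, sprintf("diffconn_%s.csv", covNames))
  runStage("diffnet", p5, function() {
    df <- config$diffnet
    inf <- config$infer
    for (mi in seq_along(covNames)) {
      m <- covNames[mi]
      sigA <- readConcentrations(file.path(d3, sprintf("signal_%s_A.csv", m)))
      sigB <- readConcentrations(file.path(d3, sprintf("signal_%s_B.csv", m)))
      cfg <- pclrcConfig(inf$nIterations, inf$subsampleFraction,
                         inf$keepFraction, inf$probabilityThreshold,
                         seed = stageSeed(config$seed, 5L, mi))
      res <- permutationTest(sigA, sigB, cfg = cfg, k = df$k,
                             seed = stageSeed(config$seed, 5L, 5000L + mi),
                             permIterations = df$permIterations)
      utils::write.csv(summary(res), p5[mi], row.names = FALSE, quote = FALSE)
    }
  })

  ## 6. COVSCA decomposition per group over its covariate networks
  d6 <- stageDir("covsca")
  p6 <- as.vector(vapply(groups, function(g)
    file.path(d6, sprintf(c("scores_%s.csv", "loadings_%s.csv",
                            "model_%s.json"), g)), character(3)))
  runStage("covsca", p6, function() {
    cs <- config$covsca
    for (gi in seq_along(groups)) {
      g <- groups[gi]
      nets <- lapply(covNames, function(m) {
        src <- if (cs$useRaw) sprintf("cor_%s_%s.csv", m, g)
               else sprintf("adj_%s_%s.csv", m, g)
        A <- readConcentrations(file.path(d4, src))
        S <- unname(A)
        diag(S) <- 1
        S
      })
      fit <- fitCovsca(nets, L = cs$L, tol = cs$tol, maxIter = cs$maxIter,
                       nRestarts = cs$nRestarts,
                       seed = stageSeed(config$seed, 6L, gi))
      sc <- covscaScores(fit)
      rownames(sc) <- covNames
      colnames(sc) <- sprintf("comp%d", seq_len(ncol(sc)))
      writeMatrixCsv(sc, file.path(d6, sprintf("scores_%s.csv", g)))
      ld <- fit@Z
      rownames(ld) <- colnames(readConcentrations(
        file.path(d3, sprintf("signal_%s_%s.csv", covNames[1], g))))
      colnames(ld) <- sprintf("comp%d", seq_len(ncol(ld)))
      writeMatrixCsv(ld, file.path(d6, sprintf("loadings_%s.csv", g)))
      jsonlite::write_json(
        list(L = cs$L, gof = gof(fit), gofPerMatrix = fit@gofPerMatrix,
             converged = fit@converged, nRestarts = fit@nRestarts),
        file.path(d6, sprintf("model_%s.json", g)),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  })

  ## 7. t-SNE embedding of the COVSCA scores per group
  d7 <- stageDir("embed")
  p7 <- file.path(d7, sprintf("embedding_%s.csv", groups))
  runStage("embed", p7, function() {
    em <- config$embed
    for (gi in seq_along(groups)) {
      sc <- readConcentrations(file.path(d6, sprintf("scores_%s.csv",
                                                     groups[gi])))
      K <- nrow(sc)
      perp <- em$perplexity %||% min(15, (K - 1) / 3 - 0.01)
      emb <- embedNetworks(sc, perplexity = perp,
                           seed = stageSeed(config$seed, 7L, gi),
                           nIter = em$nIter)
      co <- emb@coords
      colnames(co) <- c("tsne1", "tsne2")
      writeMatrixCsv(co, p7[gi])
    }
  })

  manifest$stages <- manifest$stages[stageNames]
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
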