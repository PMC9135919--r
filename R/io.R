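# CSV / GraphML / JSON interfaces.

#' Construct a clinical covariate table
#'
#' @param values numeric samples x covariates matrix (NAs allowed; rownames
#'   are sample IDs).
#' @param type per-column variable type, "continuous" or "dichotomous";
#'   if missing, columns whose non-missing values are all in \{0, 1\} are
#'   declared dichotomous.
#' @param category per-column category label (default "unknown").
#' @return a validated [CovariateTable-class].
#' @export
covariateTable <- function(values, type = NULL, category = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(type))
    type <- ifelse(apply(values, 2, function(v)
      all(v[!is.na(v)] %in% c(0, 1))), "dichotomous", "continuous")
  if (is.null(category)) category <- rep("unknown", ncol(values))
  if (length(category) == 1L) category <- rep(category, ncol(values))
  new("CovariateTable", values = values, type = as.character(type),
      category = as.character(category))
}

writeMatrixCsv <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read a samples x features concentration matrix from CSV/TSV
#'
#' Expects a header row and a first column of sample IDs.
#' @param path file path; the delimiter is inferred from the extension
#'   (".tsv" for tab, comma otherwise).
#' @return numeric matrix with sample-ID rownames.
#' @export
readConcentrations <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          comment.char = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

writeCovariateCsv <- function(cov, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#type,", paste(cov@type, collapse = ",")), con)
  writeLines(paste0("#category,", paste(cov@category, collapse = ",")), con)
  df <- data.frame(sample_id = rownames(cov@values), cov@values,
                   check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
}

#' Read a clinical covariate table from CSV/TSV
#'
#' Accepts the files written by [writeCohort()] (with \code{#type} /
#' \code{#category} comment lines) or any plain table with a sample-ID first
#' column, in which case types are inferred as in [covariateTable()].
#' @param path file path.
#' @return a [CovariateTable-class].
#' @export
readCovariates <- function(path) {
  raw <- readCovariateRaw(path)
  covariateTable(raw$values, type = raw$type, category = raw$category)
}

# raw covariate file contents, without class validation (used by
# validateInputs so that coding violations are reported, not thrown)
readCovariateRaw <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  head2 <- readLines(path, n = 2)
  type <- category <- NULL
  if (startsWith(head2[1], "#type"))
    type <- strsplit(head2[1], sep, fixed = TRUE)[[1]][-1]
  if (length(head2) > 1 && startsWith(head2[2], "#category"))
    category <- strsplit(head2[2], sep, fixed = TRUE)[[1]][-1]
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          comment.char = "#", na.strings = c("NA", ""))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  list(values = m, type = type, category = category)
}

#' Three-column edge list of a filtered network
#'
#' @param network an [InferredNetwork-class].
#' @param displayThreshold optional minimum |weight| for inclusion (e.g. 0.6
#'   for visualization); default 0 exports all retained edges.
#' @return data.frame with columns \code{from}, \code{to}, \code{weight}.
#' @export
edgeList <- function(network, displayThreshold = 0) {
  A <- adjacency(network)
  idx <- which(upper.tri(A) & A != 0 & abs(A) >= displayThreshold,
               arr.ind = TRUE)
  data.frame(from = rownames(A)[idx[, 1]], to = colnames(A)[idx[, 2]],
             weight = A[idx], stringsAsFactors = FALSE)
}

#' Export a network as GraphML
#'
#' Writes the filtered, signed, weighted network; edge probabilities are
#' attached as an edge attribute. A display threshold on |weight| restricts
#' the export for visualization without altering the underlying network.
#'
#' @param network an [InferredNetwork-class].
#' @param path output file path.
#' @param displayThreshold minimum |weight| for exported edges (default 0.6,
#'   the conventional display cutoff).
#' @return invisibly, \code{path}.
#' @export
writeGraphml <- function(network, path, displayThreshold = 0.6) {
  el <- edgeList(network, displayThreshold)
  g <- igraph::graph_from_data_frame(
    el, directed = FALSE,
    vertices = data.frame(name = network@features))
  Pm <- edgeProbabilities(network)
  if (nrow(el))
    igraph::E(g)$probability <- Pm[cbind(match(el$from, network@features),
                                         match(el$to, network@features))]
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Validate a pair of pipeline input files
#'
#' Checks that the concentration and covariate tables parse as numeric, share
#' exactly the same sample IDs in the same order, have no duplicated IDs, and
#' that declared dichotomous covariates are coded 0/1.
#'
#' @param concPath path to the concentration CSV/TSV.
#' @param covPath path to the covariate CSV/TSV.
#' @return list with \code{ok} (logical) and \code{violations}
#'   (character vector, empty when valid).
#' @export
validateInputs <- function(concPath, covPath) {
  violations <- character()
  conc <- tryCatch(readConcentrations(concPath), error = function(e)
    stop("cannot read concentrations: ", conditionMessage(e)))
  cov <- tryCatch(readCovariateRaw(covPath), error = function(e)
    stop("cannot read covariates: ", conditionMessage(e)))
  if (is.null(cov$type))
    cov$type <- ifelse(apply(cov$values, 2, function(v)
      all(v[!is.na(v)] %in% c(0, 1))), "dichotomous", "continuous")
  if (anyDuplicated(rownames(conc)))
    violations <- c(violations, "duplicated sample IDs in concentrations")
  if (anyDuplicated(rownames(cov$values)))
    violations <- c(violations, "duplicated sample IDs in covariates")
  missing <- setdiff(rownames(conc), rownames(cov$values))
  extra <- setdiff(rownames(cov$values), rownames(conc))
  if (length(missing))
    violations <- c(violations, sprintf(
      "sample IDs missing from covariates: %s",
      paste(missing, collapse = ", ")))
  if (length(extra))
    violations <- c(violations, sprintf(
      "sample IDs missing from concentrations: %s",
      paste(extra, collapse = ", ")))
  if (anyNA(conc))
    violations <- c(violations, "missing values in concentrations")
  dich <- which(cov$type == "dichotomous")
  for (j in dich) {
    v <- cov$values[, j]
    if (!all(v[!is.na(v)] %in% c(0, 1)))
      violations <- c(violations, sprintf(
        "dichotomous covariate '%s' has values outside {0,1}",
        colnames(cov$values)[j]))
  }
  list(ok = length(violations) == 0L, violations = violations)
}
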