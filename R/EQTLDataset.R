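#' Construct an EQTLDataset from in-memory matrices
#'
#' @param expression N x T numeric matrix of expression values, samples in
#'   rows, one column per test (variant-gene pair). Row names are sample ids;
#'   column names are test ids.
#' @param dosage N x T numeric matrix of genotype dosages aligned to
#'   `expression` (same samples in the same order, same tests).
#' @param covariates optional N x L numeric matrix of per-sample covariates;
#'   `NULL` means no covariates.
#' @param individual character or factor of length N mapping each sample to
#'   its individual; samples sharing a level share a genotype donor.
#' @param testMeta optional data.frame with one row per test; columns `gene`
#'   and `variant` are filled in from column names when absent.
#' @param preprocessed logical; set by [preprocessDataset()], rarely by hand.
#'
#' @return An [EQTLDataset-class] object.
#' @examples
#' sim <- simulateEqtlData(simConfig(N = 20, T = 5, K = 1, seed = 1))
#' sim$dataset
#' @export
EQTLDataset <- function(expression, dosage, covariates = NULL, individual,
                        testMeta = NULL, preprocessed = FALSE) {
  expression <- as.matrix(expression)
  dosage <- as.matrix(dosage)
  if (!all(dim(expression) == dim(dosage)))
    stop("expression and dosage must have identical dimensions")
  N <- nrow(expression); T <- ncol(expression)
  if (length(individual) != N)
    stop("individual map must have one entry per sample")
  if (is.null(rownames(expression)))
    rownames(expression) <- paste0("sample", seq_len(N))
  if (is.null(colnames(expression)))
    colnames(expression) <- paste0("test", seq_len(T))
  dimnames(dosage) <- dimnames(expression)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != N)
      stop("covariates must have one row per sample")
    rownames(covariates) <- rownames(expression)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("covar", seq_len(ncol(covariates)))
    storage.mode(covariates) <- "double"
  }
  if (is.null(testMeta)) {
    testMeta <- S4Vectors::DataFrame(
      gene = paste0("gene", seq_len(T)),
      variant = paste0("variant", seq_len(T))
    )
  } else {
    testMeta <- S4Vectors::DataFrame(testMeta)
    if (!"gene" %in% colnames(testMeta)) testMeta$gene <- paste0("gene", seq_len(T))
    if (!"variant" %in% colnames(testMeta)) testMeta$variant <- paste0("variant", seq_len(T))
  }
  rownames(testMeta) <- colnames(expression)
  storage.mode(expression) <- "double"
  storage.mode(dosage) <- "double"
  if (anyNA(expression) || anyNA(dosage) || (!is.null(covariates) && anyNA(covariates)))
    stop("missing values are not supported; impute or drop before constructing the dataset")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expression = t(expression), dosage = t(dosage)),
    rowData = testMeta,
    colData = S4Vectors::DataFrame(
      sample_id = rownames(expression),
      individual = factor(as.character(individual)),
      row.names = rownames(expression)
    )
  )
  md <- list(covariates = covariates)
  S4Vectors::metadata(se) <- md
  new("EQTLDataset", se, preprocessed = preprocessed)
}

#' @rdname accessors
#' @export
setMethod("exprMatrix", "EQTLDataset", function(x)
  t(SummarizedExperiment::assay(x, "expression")))

#' @rdname accessors
#' @export
setMethod("dosageMatrix", "EQTLDataset", function(x)
  t(SummarizedExperiment::assay(x, "dosage")))

#' @rdname accessors
#' @export
setMethod("covariateMatrix", "EQTLDataset", function(x) {
  cov <- S4Vectors::metadata(x)$covariates
  if (is.null(cov))
    cov <- matrix(0, nrow = ncol(x), ncol = 0,
                  dimnames = list(colnames(x), NULL))
  cov
})

#' @rdname accessors
#' @export
setMethod("individualOf", "EQTLDataset", function(x)
  SummarizedExperiment::colData(x)$individual)

#' @rdname accessors
#' @export
setMethod("testMeta", "EQTLDataset", function(x)
  SummarizedExperiment::rowData(x))

setMethod("show", "EQTLDataset", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf(
    "EQTLDataset: %d tests x %d samples (%d individuals, %d covariates)%s\n",
    nrow(object), ncol(object), nlevels(cd$individual),
    ncol(covariateMatrix(object)),
    if (object@preprocessed) ", preprocessed" else ", raw"))
  methods::callNextMethod()
})

#' Read an aligned EQTLDataset from delimited text files
#'
#' All three matrix files are tab-delimited with a header row of sample ids
#' and one row per test; the first column holds the test id. The sample map
#' is a two-column tab-delimited file `sample_id`, `individual_id`. Sample id
#' sets must be identical across files; rows of the genotype and covariate
#' matrices are re-aligned to the expression file's sample order, so input
#' column order never silently changes the result.
#'
#' @param exprPath,genoPath path to the tests-in-rows expression / genotype
#'   dosage matrix (dosages on the raw 0-2 scale unless already preprocessed).
#' @param covarPath optional path to a covariates matrix (covariates in rows,
#'   samples in columns); `NULL` for no covariates.
#' @param sampleMapPath path to the sample-to-individual map.
#' @param testMetaPath optional path to a per-test metadata table (columns
#'   `test_id`, `gene`, `variant`, optionally `chromosome`, `position`).
#' @return An [EQTLDataset-class].
#' @export
readEQTLDataset <- function(exprPath, genoPath, covarPath = NULL,
                            sampleMapPath, testMetaPath = NULL) {
  expr <- .readMatrixTsv(exprPath)
  geno <- .readMatrixTsv(genoPath)
  samples <- colnames(expr)
  .checkSampleSet(samples, colnames(geno), "genotype")
  geno <- geno[, samples, drop = FALSE]
  if (!all(dim(expr) == dim(geno)) ||
      !identical(rownames(expr), rownames(geno)))
    stop("expression and genotype files disagree on the test set")
  map <- read.delim(sampleMapPath, header = TRUE, sep = "\t",
                    colClasses = "character")
  if (ncol(map) < 2)
    stop("sample map must have two columns: sample_id, individual_id")
  .checkSampleSet(samples, map[[1]], "sample map")
  individual <- map[[2]][match(samples, map[[1]])]
  cov <- NULL
  if (!is.null(covarPath)) {
    cov <- .readMatrixTsv(covarPath)
    .checkSampleSet(samples, colnames(cov), "covariate")
    cov <- t(cov[, samples, drop = FALSE])
  }
  tm <- NULL
  if (!is.null(testMetaPath)) {
    tm <- read.delim(testMetaPath, header = TRUE, sep = "\t")
    rn <- as.character(tm[[1]])
    if (!setequal(rn, rownames(expr)))
      stop("test metadata ids do not match the expression file's test ids")
    tm <- tm[match(rownames(expr), rn), -1, drop = FALSE]
  }
  EQTLDataset(expression = t(expr), dosage = t(geno), covariates = cov,
              individual = individual, testMeta = tm)
}

.readMatrixTsv <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = NA)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    col <- colnames(df)[-1][bad]
    row <- which(is.na(suppressWarnings(as.numeric(df[[bad + 1]]))))[1]
    stop(sprintf("non-numeric value in '%s' at row %s, column '%s'",
                 path, ifelse(is.na(row), "?", row), col))
  }
  rownames(m) <- ids
  m
}

.checkSampleSet <- function(ref, other, label) {
  missing <- setdiff(ref, other)
  extra <- setdiff(other, ref)
  if (length(missing) || length(extra))
    stop(sprintf(
      "%s file sample ids do not match the expression file (missing: %s; unexpected: %s)",
      label,
      if (length(missing)) paste(missing, collapse = ", ") else "none",
      if (length(extra)) paste(extra, collapse = ", ") else "none"))
  invisible(TRUE)
}
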