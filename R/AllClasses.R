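#' EQTLDataset: aligned expression, genotype and sample structure
#'
#' An `EQTLDataset` holds everything one latent-context eQTL analysis needs:
#' a tests-by-samples expression assay, a tests-by-samples genotype-dosage
#' assay, per-sample covariates, and the sample-to-individual map that encodes
#' repeat structure (multiple RNA samples, e.g. pseudocells, drawn from the
#' same genotyped individual). It extends
#' [SummarizedExperiment::SummarizedExperiment] with tests (variant-gene
#' pairs) as rows and samples as columns; per-test metadata (gene, variant,
#' chromosome, position) lives in `rowData`, the sample-to-individual map in
#' `colData$individual`, and the samples-by-covariates matrix in
#' `metadata(x)$covariates`.
#'
#' The model-facing accessors [exprMatrix()], [dosageMatrix()] and
#' [covariateMatrix()] return samples-in-rows orientation (N x T / N x L),
#' matching the model equations.
#'
#' @slot preprocessed logical scalar; `TRUE` once [preprocessDataset()] has
#'   standardized expression (mean 0, variance 1 per test) and centred/scaled
#'   genotype.
#'
#' @seealso [readEQTLDataset()], [preprocessDataset()], [simulateEqtlData()]
#' @export
setClass("EQTLDataset",
  contains = "SummarizedExperiment",
  representation(preprocessed = "logical"),
  prototype(preprocessed = FALSE)
)

setValidity("EQTLDataset", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("expression", "dosage") %in% an))
    msg <- c(msg, "assays must include 'expression' and 'dosage'")
  cd <- SummarizedExperiment::colData(object)
  if (!"individual" %in% colnames(cd))
    msg <- c(msg, "colData must contain an 'individual' column")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("gene", "variant") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'gene' and 'variant' columns")
  cov <- S4Vectors::metadata(object)$covariates
  if (!is.null(cov)) {
    if (!is.matrix(cov) || nrow(cov) != ncol(object))
      msg <- c(msg, "metadata(x)$covariates must be a samples x covariates matrix")
  }
  for (a in intersect(c("expression", "dosage"), an)) {
    if (anyNA(SummarizedExperiment::assay(object, a)))
      msg <- c(msg, sprintf("assay '%s' contains missing values", a))
  }
  if (length(msg)) msg else TRUE
})

#' SurgeFit: a converged latent-context model
#'
#' Returned by [fitSurge()]. Holds the winning restart's converged variational
#' state, posterior-mean factor matrices, the proportion of variance explained
#' (PVE) per latent context, and the ELBO trace. Contexts are ordered by
#' descending PVE; only contexts with PVE above the pruning threshold are
#' retained in the posterior-mean accessors. The full pre-pruning PVE vector
#' is kept in `pveAll` (in original context order) so the retained-context
#' count is always recoverable.
#'
#' @slot U N x K' matrix of posterior-mean latent-context loadings (retained
#'   contexts, descending PVE).
#' @slot V K' x T matrix of posterior-mean context-specific eQTL effects.
#' @slot F length-T posterior-mean shared eQTL effects.
#' @slot pve,psmve length-K' proportion of total / model-mediated variance
#'   per retained context.
#' @slot pveAll,psmveAll length-K vectors over all initialized contexts,
#'   original order.
#' @slot retained integer indices of retained contexts in the original order.
#' @slot sigmaSq length-T posterior-mean residual variances.
#' @slot state list of variational parameters (unpruned) for the winning
#'   restart.
#' @slot elbo final ELBO of the winning restart.
#' @slot elboTrace numeric vector of ELBO values per iteration.
#' @slot restart index of the winning random restart.
#' @slot converged logical; `FALSE` if the iteration cap was reached first.
#' @slot config the configuration list used for the fit.
#'
#' @seealso [fitSurge()], [contextLoadings()], [contextPve()],
#'   [countRecoveredContexts()]
#' @export
setClass("SurgeFit",
  representation(
    U = "matrix", V = "matrix", F = "numeric",
    pve = "numeric", psmve = "numeric",
    pveAll = "numeric", psmveAll = "numeric",
    retained = "integer", sigmaSq = "numeric",
    state = "list", elbo = "numeric", elboTrace = "numeric",
    restart = "integer", converged = "logical", config = "list"
  )
)

setValidity("SurgeFit", function(object) {
  msg <- character()
  if (ncol(object@U) != nrow(object@V))
    msg <- c(msg, "U and V disagree on the number of retained contexts")
  if (length(object@pve) != ncol(object@U))
    msg <- c(msg, "pve length must equal the retained context count")
  if (length(object@pve) > 1 && is.unsorted(rev(object@pve)))
    msg <- c(msg, "retained contexts must be ordered by descending PVE")
  if (any(object@sigmaSq <= 0))
    msg <- c(msg, "posterior-mean residual variances must be positive")
  if (length(msg)) msg else TRUE
})

#' EFDRResult: empirical-FDR calibration of interaction eQTLs
#'
#' Returned by [runEfdr()]. Pairs an observed gene-level p-value table with a
#' permutation-derived null table and records, per context (mode
#' `"per-context"`) or globally (mode `"all-context"`), the largest p-value
#' threshold at which the estimated empirical FDR stays at or below the
#' requested level, plus the resulting significance calls.
#'
#' @slot observed,permuted data.frames with columns `gene`, `context`, `p`.
#' @slot calls data.frame of observed rows with a logical `significant`
#'   column.
#' @slot thresholds data.frame with one row per context (or one row total in
#'   all-context mode): the chosen p-value threshold and its estimated eFDR;
#'   `NA` threshold means nothing passed.
#' @slot level target empirical FDR.
#' @slot mode `"per-context"` or `"all-context"`.
#'
#' @seealso [runEfdr()], [efdrPipeline()]
#' @export
setClass("EFDRResult",
  representation(
    observed = "data.frame", permuted = "data.frame",
    calls = "data.frame", thresholds = "data.frame",
    level = "numeric", mode = "character"
  )
)

setValidity("EFDRResult", function(object) {
  msg <- character()
  if (!all(c("gene", "context", "p") %in% colnames(object@observed)))
    msg <- c(msg, "observed table needs columns gene, context, p")
  if (object@level <= 0 || object@level >= 1)
    msg <- c(msg, "level must be in (0, 1)")
  if (!object@mode %in% c("per-context", "all-context"))
    msg <- c(msg, "mode must be 'per-context' or 'all-context'")
  if (length(msg)) msg else TRUE
})
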