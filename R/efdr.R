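#' Empirical-FDR significance calls from observed and permuted p-values
#'
#' At a candidate threshold p* the empirical FDR is estimated as the count of
#' permuted gene-level p-values at or below p* divided by the count of
#' observed gene-level p-values at or below p*. Candidate thresholds are the
#' observed p-values themselves (so the denominator is never zero); the eFDR
#' curve is made monotone non-decreasing in p* by taking, at each candidate,
#' the running minimum over all larger candidates; the significance threshold
#' is the largest candidate whose adjusted eFDR is at or below `level`.
#' In `"per-context"` mode the procedure runs independently per context,
#' pairing the j-th observed context with the j-th permuted context; in
#' `"all-context"` mode all (gene, context) pairs are pooled.
#'
#' @param observed,permuted data.frames with columns `gene`, `context`, `p`
#'   (gene-level p-values).
#' @param level target empirical FDR in (0, 1).
#' @param mode `"per-context"` or `"all-context"`.
#' @return an [EFDRResult-class].
#' @examples
#' obs <- data.frame(gene = paste0("g", 1:3), context = "context1",
#'                   p = c(0.001, 0.2, 0.5))
#' perm <- data.frame(gene = paste0("g", 1:3), context = "context1",
#'                    p = c(0.3, 0.6, 0.9))
#' runEfdr(obs, perm, level = 0.05)
#' @export
runEfdr <- function(observed, permuted, level = 0.05,
                    mode = c("per-context", "all-context")) {
  mode <- match.arg(mode)
  for (nm in c("gene", "context", "p")) {
    if (!nm %in% colnames(observed)) stop("observed table lacks column ", nm)
    if (!nm %in% colnames(permuted)) stop("permuted table lacks column ", nm)
  }
  if (nrow(permuted) == 0) stop("empty permuted table")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  observed$context <- as.character(observed$context)
  permuted$context <- as.character(permuted$context)

  if (mode == "per-context") {
    obsCtx <- sort(unique(observed$context))
    permCtx <- sort(unique(permuted$context))
    if (length(obsCtx) != length(permCtx))
      stop("per-context mode needs equal context counts in observed and permuted tables")
    pieces <- lapply(seq_along(obsCtx), function(j) {
      o <- observed[observed$context == obsCtx[j], , drop = FALSE]
      pm <- permuted[permuted$context == permCtx[j], , drop = FALSE]
      thr <- .efdrThreshold(o$p, pm$p, level)
      o$significant <- !is.na(thr$threshold) & o$p <= thr$threshold
      list(calls = o,
           thresholds = data.frame(context = obsCtx[j],
                                   threshold = thr$threshold,
                                   efdr = thr$efdr,
                                   n_significant = sum(o$significant)))
    })
    calls <- do.call(rbind, lapply(pieces, `[[`, "calls"))
    thresholds <- do.call(rbind, lapply(pieces, `[[`, "thresholds"))
  } else {
    thr <- .efdrThreshold(observed$p, permuted$p, level)
    calls <- observed
    calls$significant <- !is.na(thr$threshold) & calls$p <= thr$threshold
    thresholds <- data.frame(context = "all", threshold = thr$threshold,
                             efdr = thr$efdr,
                             n_significant = sum(calls$significant))
  }
  rownames(calls) <- NULL
  rownames(thresholds) <- NULL
  new("EFDRResult", observed = observed, permuted = permuted, calls = calls,
      thresholds = thresholds, level = level, mode = mode)
}

# largest observed p with monotone-adjusted eFDR <= level
.efdrThreshold <- function(obsP, permP, level) {
  cand <- sort(unique(obsP))
  if (length(cand) == 0) return(list(threshold = NA_real_, efdr = NA_real_))
  nObs <- vapply(cand, function(p) sum(obsP <= p), numeric(1))
  nPerm <- vapply(cand, function(p) sum(permP <= p), numeric(1))
  raw <- nPerm / nObs
  adj <- rev(cummin(rev(raw)))  # min over all larger candidates
  ok <- which(adj <= level)
  if (!length(ok)) return(list(threshold = NA_real_, efdr = NA_real_))
  i <- max(ok)
  list(threshold = cand[i], efdr = adj[i])
}

#' Significant (gene, context) calls of an EFDRResult
#'
#' @param x an [EFDRResult-class].
#' @return data.frame of the significant rows.
#' @export
significantCalls <- function(x) {
  stopifnot(is(x, "EFDRResult"))
  out <- x@calls[x@calls$significant, , drop = FALSE]
  rownames(out) <- NULL
  out
}

setMethod("show", "EFDRResult", function(object) {
  cat(sprintf("EFDRResult (%s, level %.3g): %d of %d (gene, context) pairs significant\n",
              object@mode, object@level,
              sum(object@calls$significant), nrow(object@calls)))
  if (nrow(object@thresholds)) print(object@thresholds)
})

#' Full permutation-calibrated interaction-eQTL pipeline
#'
#' Runs the complete calibration recipe: fit the latent-context model, test
#' interactions for every pair against the retained contexts, permute
#' genotype across individuals (a single permutation shared by all
#' variants), re-fit the model with the permuted genotype in the interaction
#' term (the genotype main effect stays un-permuted), test interactions
#' against the top-Z permuted contexts ranked by PVE (Z = number of retained
#' real contexts), and calibrate observed against permuted gene-level
#' p-values with [runEfdr()].
#'
#' @param dataset an [EQTLDataset-class] (preprocessed, or standardized on
#'   the fly).
#' @param config a [surgeConfig()] list; `efdrMode`, `efdrLevel` and `seed`
#'   are honoured. The permuted re-fit mirrors the real fit's configuration.
#' @param refit re-learn contexts on permuted data (the faithful procedure).
#'   `FALSE` reuses the real contexts for the permuted tests — cheaper, for
#'   unit testing only.
#' @param fit optionally, an existing [SurgeFit-class] for this dataset to
#'   skip the real fit.
#' @return list with `fit` (real [SurgeFit-class]), `observed` and
#'   `permuted` gene-level tables, `efdr` (an [EFDRResult-class]) and
#'   `perm` (the individual permutation), or a zero-context marker list
#'   (`efdr = NULL`) when no context survives pruning.
#' @export
efdrPipeline <- function(dataset, config = surgeConfig(), refit = TRUE,
                         fit = NULL) {
  stopifnot(is(dataset, "EQTLDataset"))
  if (!dataset@preprocessed) dataset <- preprocessDataset(dataset)
  if (is.null(fit)) fit <- fitSurge(dataset, config)
  Z <- ncol(contextLoadings(fit))
  if (Z == 0) {
    message("no latent contexts retained (all PVE <= threshold); nothing to test")
    return(list(fit = fit, observed = NULL, permuted = NULL, efdr = NULL,
                perm = NULL))
  }
  uri <- config$useRandomIntercept
  observed <- testInteractions(dataset, contextLoadings(fit),
                               useRandomIntercept = uri)
  permObj <- permuteGenotypeByIndividual(dataset, seed = config$seed + 1L)
  if (refit) {
    permFit <- fitSurge(dataset, config, gInteraction = permObj$Gint)
    ordAll <- order(permFit@pveAll, decreasing = TRUE)[seq_len(Z)]
    permContexts <- permFit@state$Umu[, ordAll, drop = FALSE]
  } else {
    permContexts <- contextLoadings(fit)
  }
  colnames(permContexts) <- paste0("context", seq_len(Z))
  permuted <- testInteractions(dataset, permContexts,
                               useRandomIntercept = uri,
                               gInteraction = permObj$Gint)
  obsGene <- unique(observed[, c("gene", "context", "gene_p")])
  names(obsGene)[3] <- "p"
  permGene <- unique(permuted[, c("gene", "context", "gene_p")])
  names(permGene)[3] <- "p"
  efdr <- runEfdr(obsGene, permGene, level = config$efdrLevel,
                  mode = config$efdrMode)
  list(fit = fit, observed = observed, permuted = permuted, efdr = efdr,
       perm = permObj$perm)
}
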