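#' Standardize an expression vector
#'
#' Centers to mean 0 and scales to variance 1, using the population
#' (divide-by-n) variance so "variance 1" holds exactly. An optional cap
#' clips extreme values after standardization to limit outlier leverage.
#'
#' @param x numeric vector, length at least 2, non-constant.
#' @param cap positive number or `NULL`; if given, values are clipped to
#'   `[-cap, cap]` after standardization.
#' @return standardized numeric vector.
#' @examples
#' standardizeExpression(c(1, 2, 3))
#' @export
standardizeExpression <- function(x, cap = NULL) {
  if (length(x) < 2) stop("need at least 2 observations")
  v <- .popVar(x)
  if (v <= 0) stop("zero variance test")
  z <- (x - mean(x)) / sqrt(v)
  if (!is.null(cap)) {
    if (cap <= 0) stop("cap must be positive")
    z <- pmin(pmax(z, -cap), cap)
  }
  z
}

.popVar <- function(x) mean((x - mean(x))^2)

#' Standardize a genotype vector against its expression vector
#'
#' Centers the dosage vector to mean 0, then scales it by the standard
#' deviation of the elementwise ratio of expression to (centred) genotype.
#' This scaling equalizes how much variance the low-rank interaction term can
#' explain across tests, instead of favouring tests where expression changes
#' steeply per unit genotype. Ratio entries where the centred genotype is
#' numerically zero (|g| <= 1e-8) are excluded; the scale is floored at 1e-6;
#' an exactly constant ratio (sd below 1e-12) is an error because the rule is
#' ill-defined there.
#'
#' @param g numeric dosage vector (non-constant).
#' @param yStd standardized expression vector for the same test.
#' @param ratioOnCentered use the centred genotype in the ratio denominator
#'   (default) or the raw dosage.
#' @return centred and scaled genotype vector.
#' @examples
#' set.seed(1)
#' g <- rbinom(100, 2, 0.4)
#' y <- standardizeExpression(0.3 * g + rnorm(100))
#' standardizeGenotype(g, y)[1:5]
#' @export
standardizeGenotype <- function(g, yStd, ratioOnCentered = TRUE) {
  if (length(g) != length(yStd)) stop("g and yStd must have equal length")
  if (.popVar(g) <= 0) stop("constant genotype vector")
  gc <- g - mean(g)
  denom <- if (ratioOnCentered) gc else g
  usable <- abs(denom) > 1e-8
  if (sum(usable) < 3) stop("degenerate scaling: fewer than 3 usable ratio entries")
  ratio <- yStd[usable] / denom[usable]
  s <- sqrt(.popVar(ratio))
  if (s < 1e-12) stop("degenerate scaling: expression/genotype ratio is constant")
  gc / max(s, 1e-6)
}

#' Standardize every test of a dataset for model fitting
#'
#' Applies [standardizeExpression()] to each expression column and
#' [standardizeGenotype()] to each dosage column, and marks the dataset
#' preprocessed. The model likelihood assumes exactly this scaling.
#'
#' @param dataset an [EQTLDataset-class] with raw values.
#' @param cap optional absolute cap on standardized expression (e.g. 10).
#' @param ratioOnCentered see [standardizeGenotype()].
#' @param dropDegenerate drop tests whose genotype is monomorphic or whose
#'   ratio scaling is ill-defined (with a message) instead of erroring; a
#'   monomorphic variant cannot be an eQTL test and would normally have been
#'   removed by a MAF filter.
#' @return a preprocessed [EQTLDataset-class].
#' @export
preprocessDataset <- function(dataset, cap = NULL, ratioOnCentered = TRUE,
                              dropDegenerate = TRUE) {
  stopifnot(is(dataset, "EQTLDataset"))
  if (dataset@preprocessed) return(dataset)
  Y <- exprMatrix(dataset)
  G <- dosageMatrix(dataset)
  keep <- rep(TRUE, ncol(Y))
  for (t in seq_len(ncol(Y))) {
    res <- tryCatch({
      y <- standardizeExpression(Y[, t], cap = cap)
      g <- standardizeGenotype(G[, t], y, ratioOnCentered = ratioOnCentered)
      list(y = y, g = g)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (!dropDegenerate) stop("test ", colnames(Y)[t], ": ",
                                conditionMessage(res))
      keep[t] <- FALSE
    } else {
      Y[, t] <- res$y
      G[, t] <- res$g
    }
  }
  if (!any(keep)) stop("no tests survive standardization")
  if (!all(keep))
    message(sum(!keep), " degenerate test(s) dropped during standardization")
  Y <- Y[, keep, drop = FALSE]
  G <- G[, keep, drop = FALSE]
  EQTLDataset(expression = Y, dosage = G,
              covariates = S4Vectors::metadata(dataset)$covariates,
              individual = individualOf(dataset),
              testMeta = testMeta(dataset)[keep, , drop = FALSE],
              preprocessed = TRUE)
}

#' Gene-level Bonferroni correction
#'
#' The gene-level p-value is the smallest nominal p-value among a gene's
#' tested variants multiplied by the number of variants, capped at 1.
#'
#' @param p numeric vector of nominal p-values for one gene's variants.
#' @return single corrected p-value.
#' @examples
#' bonferroniGeneLevel(c(0.001, rep(0.5, 9)))
#' @export
bonferroniGeneLevel <- function(p) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  min(1, length(p) * min(p))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH adjustment with enforced monotonicity, as used genome-wide on
#' gene-level p-values.
#'
#' @param p numeric vector of p-values.
#' @return vector of q-values, same order as `p`.
#' @examples
#' bhCorrect(c(0.01, 0.02, 0.03, 0.5))
#' @export
bhCorrect <- function(p) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call standard (non-interaction) eQTLs
#'
#' Per test, fits expression on covariates plus genotype — ordinary least
#' squares, or a linear mixed model with a per-individual random intercept
#' when repeat structure should be absorbed — and reports the two-sided
#' p-value for the genotype term, followed by gene-level Bonferroni and
#' genome-wide BH correction.
#'
#' @param dataset an [EQTLDataset-class] with raw dosages (MAF filtering
#'   needs the 0-2 scale; pass `mafMin = 0` for preprocessed data).
#' @param useRandomIntercept fit per-individual random intercepts via
#'   [lme4::lmer()]; automatically falls back to OLS when every individual
#'   contributes a single sample.
#' @param mafMin minimum minor-allele frequency; tests below it are dropped.
#' @return data.frame with columns `gene`, `variant`, `beta`, `se`,
#'   `p_nominal`, `gene_p` (gene-level Bonferroni, repeated within gene) and
#'   `q` (genome-wide BH across gene-level p-values).
#' @export
callStandardEqtls <- function(dataset, useRandomIntercept = FALSE,
                              mafMin = 0.05) {
  stopifnot(is(dataset, "EQTLDataset"))
  Y <- exprMatrix(dataset)
  G <- dosageMatrix(dataset)
  X <- covariateMatrix(dataset)
  ind <- individualOf(dataset)
  meta <- as.data.frame(testMeta(dataset))
  keep <- rep(TRUE, ncol(Y))
  if (mafMin > 0) {
    if (dataset@preprocessed)
      stop("MAF filtering needs raw dosages; preprocess after calling, or set mafMin = 0")
    af <- colMeans(G) / 2
    keep <- pmin(af, 1 - af) >= mafMin
  }
  if (!any(keep)) stop("no tests pass the MAF filter")
  .checkCovariateRank(X)
  reduceToOls <- !useRandomIntercept || nlevels(ind) == length(ind)
  rows <- lapply(which(keep), function(t) {
    fit <- .genotypeEffect(Y[, t], G[, t], X, ind, reduceToOls)
    data.frame(gene = meta$gene[t], variant = meta$variant[t],
               beta = fit$beta, se = fit$se, p_nominal = fit$p)
  })
  tbl <- do.call(rbind, rows)
  geneP <- tapply(tbl$p_nominal, tbl$gene, bonferroniGeneLevel)
  tbl$gene_p <- as.numeric(geneP[tbl$gene])
  qByGene <- setNames(bhCorrect(as.numeric(geneP)), names(geneP))
  tbl$q <- as.numeric(qByGene[tbl$gene])
  rownames(tbl) <- NULL
  tbl
}

.checkCovariateRank <- function(X) {
  if (ncol(X) == 0) return(invisible(TRUE))
  M <- cbind(`(Intercept)` = 1, X)
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    dropped <- colnames(M)[qrM$pivot[-seq_len(qrM$rank)]]
    stop(sprintf("collinear covariates: %s", paste(dropped, collapse = ", ")))
  }
  invisible(TRUE)
}

# single-test genotype effect: OLS t-test, or LMM Wald with a normal
# reference in the repeat-structure case
.genotypeEffect <- function(y, g, X, ind, reduceToOls) {
  df <- data.frame(y = y, g = g)
  covNames <- character()
  if (ncol(X) > 0) {
    covNames <- paste0("c", seq_len(ncol(X)))
    df[covNames] <- X
  }
  if (reduceToOls) {
    fml <- as.formula(paste("y ~", paste(c(covNames, "g"), collapse = " + ")))
    sm <- summary(lm(fml, data = df))$coefficients
    list(beta = sm["g", 1], se = sm["g", 2], p = sm["g", 4])
  } else {
    df$ind <- ind
    fml <- as.formula(paste("y ~", paste(c(covNames, "g"), collapse = " + "),
                            "+ (1 | ind)"))
    fit <- suppressMessages(lme4::lmer(fml, data = df, REML = TRUE,
                                       control = .lmerCtrl()))
    sm <- as.data.frame(coef(summary(fit)))
    z <- sm["g", "t value"]
    list(beta = sm["g", "Estimate"], se = sm["g", "Std. Error"],
         p = 2 * pnorm(-abs(z)))
  }
}

.lmerCtrl <- function() {
  lme4::lmerControl(check.conv.singular = "ignore",
                    check.conv.grad = "ignore",
                    check.conv.hess = "ignore",
                    calc.derivs = FALSE)
}

#' Select representative variant-gene pairs for model fitting
#'
#' Latent-context fitting wants genome-wide *independent* tests: at most one
#' variant per gene and one gene per variant. Genes significant at the given
#' FDR are ranked by gene-level p-value (ties broken lexicographically by
#' gene id), capped at `maxTests` genes; each gene contributes its most
#' significant variant, and a pair is dropped outright when its variant was
#' already claimed by a more significant gene (the gene is not given its
#' second-best variant).
#'
#' @param eqtlTable output of [callStandardEqtls()].
#' @param fdrCut BH q-value cutoff defining significant genes.
#' @param maxTests cap on the number of genes considered.
#' @return data.frame with columns `gene`, `variant`, one row per selected
#'   pair, in gene significance order.
#' @export
selectRepresentativeTests <- function(eqtlTable, fdrCut = 0.05,
                                      maxTests = 2000L) {
  need <- c("gene", "variant", "p_nominal", "gene_p", "q")
  if (!all(need %in% colnames(eqtlTable)))
    stop("eqtlTable must have columns ", paste(need, collapse = ", "))
  sig <- eqtlTable[eqtlTable$q <= fdrCut, , drop = FALSE]
  if (nrow(sig) == 0) stop("no representative tests: nothing significant at FDR ", fdrCut)
  genes <- unique(sig[order(sig$gene_p, sig$gene), "gene"])
  genes <- head(genes, maxTests)
  used <- character()
  out <- vector("list", length(genes))
  for (j in seq_along(genes)) {
    sub <- sig[sig$gene == genes[j], , drop = FALSE]
    sub <- sub[order(sub$p_nominal, sub$variant), , drop = FALSE]
    v <- sub$variant[1]
    if (v %in% used) next  # variant claimed by a more significant gene
    used <- c(used, v)
    out[[j]] <- data.frame(gene = genes[j], variant = v)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
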