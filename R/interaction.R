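#' Interaction-eQTL test for one variant-gene pair
#'
#' Fits
#' \deqn{y_n = \mu + \alpha_{i(n)} + \sum_l W_l X_{nl} + \beta_g g_n
#'       + \sum_k \beta_k \hat U_{nk} + \sum_k \beta_{g \times k} g^{int}_n \hat U_{nk}
#'       + \epsilon_n}
#' with a per-individual random intercept `alpha_i ~ N(0, psi^2)` (via
#' [lme4::lmer()], REML), treating the posterior-mean latent contexts as
#' observed. Each of the K interaction coefficients gets a two-sided Wald
#' p-value against a normal reference. With the random intercept disabled, or
#' when every individual contributes one sample, the model reduces to
#' ordinary least squares (p-values then from the exact t reference).
#'
#' @param y expression vector (length N).
#' @param g genotype vector entering the main effect.
#' @param X N x L covariate matrix (0 columns allowed).
#' @param contexts N x K matrix of latent-context values (K = 0 allowed).
#' @param individual factor of length N.
#' @param useRandomIntercept logical; `NA` enables the random intercept
#'   exactly when repeat structure exists.
#' @param gInteraction genotype vector entering the interaction terms only;
#'   defaults to `g`, differs under the individual-level permutation.
#' @return list of class `interactionFit`: `coefficients` (data.frame term,
#'   estimate, se, p), `interactions` (the K interaction rows), `psiSq`,
#'   `sigmaSq`, `method` ("lmm" or "ols").
#' @export
fitInteractionModel <- function(y, g, X = NULL, contexts = NULL, individual,
                                useRandomIntercept = NA, gInteraction = g) {
  N <- length(y)
  individual <- factor(individual)
  if (is.null(X)) X <- matrix(0, N, 0)
  X <- as.matrix(X)
  contexts <- if (is.null(contexts)) matrix(0, N, 0) else as.matrix(contexts)
  K <- ncol(contexts)
  if (length(g) != N || nrow(X) != N || nrow(contexts) != N ||
      length(individual) != N || length(gInteraction) != N)
    stop("all inputs must share the sample dimension")

  df <- data.frame(y = y, g = g)
  covNames <- if (ncol(X)) paste0("c", seq_len(ncol(X))) else character()
  if (length(covNames)) df[covNames] <- X
  ctxNames <- if (K) paste0("ctx", seq_len(K)) else character()
  gxNames <- if (K) paste0("gx", seq_len(K)) else character()
  for (k in seq_len(K)) {
    df[[ctxNames[k]]] <- contexts[, k]
    df[[gxNames[k]]] <- gInteraction * contexts[, k]
  }
  fixed <- c(covNames, "g", ctxNames, gxNames)
  M <- as.matrix(cbind(`(Intercept)` = 1, df[fixed]))
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    bad <- colnames(M)[qrM$pivot[-seq_len(qrM$rank)]]
    stop(sprintf("rank-deficient design: column(s) %s", paste(bad, collapse = ", ")))
  }

  reduceToOls <- if (is.na(useRandomIntercept)) {
    nlevels(droplevels(individual)) == N
  } else !isTRUE(useRandomIntercept)
  if (!reduceToOls && nlevels(droplevels(individual)) == N) reduceToOls <- TRUE

  if (reduceToOls) {
    fml <- as.formula(paste("y ~", paste(fixed, collapse = " + ")))
    fit <- lm(fml, data = df)
    sm <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(sm), estimate = sm[, 1],
                        se = sm[, 2], p = sm[, 4], row.names = NULL)
    psiSq <- 0
    sigmaSq <- summary(fit)$sigma^2
    method <- "ols"
  } else {
    df$ind <- droplevels(individual)
    fml <- as.formula(paste("y ~", paste(fixed, collapse = " + "),
                            "+ (1 | ind)"))
    fit <- suppressMessages(lme4::lmer(fml, data = df, REML = TRUE,
                                       control = .lmerCtrl()))
    sm <- as.data.frame(coef(summary(fit)))
    z <- sm[, "t value"]
    coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                        se = sm[, "Std. Error"], p = 2 * pnorm(-abs(z)),
                        row.names = NULL)
    vc <- as.data.frame(lme4::VarCorr(fit))
    psiSq <- vc$vcov[vc$grp == "ind"]
    sigmaSq <- vc$vcov[vc$grp == "Residual"]
    method <- "lmm"
  }
  structure(list(coefficients = coefs,
                 interactions = coefs[coefs$term %in% gxNames, , drop = FALSE],
                 psiSq = psiSq, sigmaSq = sigmaSq, method = method),
            class = "interactionFit")
}

#' Interaction-eQTL tests for every variant-gene pair
#'
#' Runs [fitInteractionModel()] for each test in the dataset against the
#' given contexts and summarizes per (gene, context): nominal interaction
#' p-values per variant plus the gene-level Bonferroni p over the gene's
#' variants. The latent contexts may come from a [SurgeFit-class]
#' ([contextLoadings()]) or from [expressionPcContexts()].
#'
#' @param dataset an [EQTLDataset-class].
#' @param contexts N x K matrix; K must be at least 1.
#' @param useRandomIntercept see [fitInteractionModel()].
#' @param gInteraction optional N x T permuted interaction genotype matrix.
#' @return data.frame with columns `gene`, `variant`, `context`,
#'   `beta_interaction`, `se`, `p`, `gene_p`, sorted by `gene_p`.
#' @export
testInteractions <- function(dataset, contexts, useRandomIntercept = NA,
                             gInteraction = NULL) {
  stopifnot(is(dataset, "EQTLDataset"))
  contexts <- as.matrix(contexts)
  if (ncol(contexts) == 0)
    stop("no latent contexts to test; the model retained zero contexts")
  Y <- exprMatrix(dataset)
  G <- dosageMatrix(dataset)
  X <- covariateMatrix(dataset)
  ind <- individualOf(dataset)
  meta <- as.data.frame(testMeta(dataset))
  if (nrow(Y) == 0 || ncol(Y) == 0) stop("empty test set")
  K <- ncol(contexts)
  ctxLabels <- colnames(contexts)
  if (is.null(ctxLabels)) ctxLabels <- paste0("context", seq_len(K))
  rows <- lapply(seq_len(ncol(Y)), function(t) {
    gi <- if (is.null(gInteraction)) G[, t] else gInteraction[, t]
    fit <- fitInteractionModel(Y[, t], G[, t], X, contexts, ind,
                               useRandomIntercept, gInteraction = gi)
    data.frame(gene = meta$gene[t], variant = meta$variant[t],
               context = ctxLabels,
               beta_interaction = fit$interactions$estimate,
               se = fit$interactions$se, p = fit$interactions$p)
  })
  tbl <- do.call(rbind, rows)
  gp <- tapply(tbl$p, list(tbl$gene, tbl$context), bonferroniGeneLevel)
  tbl$gene_p <- mapply(function(g, k) gp[g, k], tbl$gene, tbl$context)
  tbl <- tbl[order(tbl$gene_p, tbl$gene, tbl$context), , drop = FALSE]
  rownames(tbl) <- NULL
  tbl
}

#' Permute genotype across individuals
#'
#' Draws a single permutation of individual labels (once per seed) and maps
#' every sample's genotype to the genotype of the individual its individual
#' was permuted to — at every variant, so the correlation structure across
#' variant-gene pairs is preserved. Samples of one individual stay identical
#' to each other, preserving repeat structure. The permuted matrix is meant
#' for interaction terms only; the genotype main effect keeps the original
#' dosages.
#'
#' @param dataset an [EQTLDataset-class].
#' @param seed integer seed for the permutation draw.
#' @param perm optional explicit permutation of `1:I` (overrides `seed`);
#'   the identity permutation reproduces the original matrix.
#' @return list with `Gint` (N x T permuted genotype matrix) and `perm`
#'   (the individual-level permutation used).
#' @export
permuteGenotypeByIndividual <- function(dataset, seed = 1L, perm = NULL) {
  stopifnot(is(dataset, "EQTLDataset"))
  ind <- individualOf(dataset)
  I <- nlevels(ind)
  if (is.null(perm)) {
    set.seed(seed)
    perm <- sample.int(I)
  }
  if (length(perm) != I || !setequal(perm, seq_len(I)))
    stop("perm must be a permutation of 1:", I)
  G <- dosageMatrix(dataset)
  indIdx <- as.integer(ind)
  rep1 <- match(seq_len(I), indIdx)  # representative sample per individual
  Gint <- G[rep1[perm[indIdx]], , drop = FALSE]
  dimnames(Gint) <- dimnames(G)
  list(Gint = Gint, perm = perm)
}

#' Expression principal components as contexts
#'
#' The first K principal-component scores of the (standardized) expression
#' matrix, used as pre-specified contexts in the expression-PC interaction
#' benchmark. Deterministic up to column sign.
#'
#' @param Y N x T standardized expression matrix.
#' @param K number of components; must satisfy `K <= min(N - 1, T)`.
#' @return N x K matrix of PC scores (columns `PC1..PCK`).
#' @export
expressionPcContexts <- function(Y, K) {
  Y <- as.matrix(Y)
  if (K < 1) stop("K must be at least 1")
  if (K > min(nrow(Y) - 1, ncol(Y)))
    stop(sprintf("K = %d exceeds the available rank min(N - 1, T) = %d",
                 K, min(nrow(Y) - 1, ncol(Y))))
  pc <- prcomp(Y, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(K), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(K))
  scores
}
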