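#' Simulate genotype dosages
#'
#' One allele frequency per test drawn from `Uniform(afLow, afHigh)`, then N
#' independent `Binomial(2, af)` dosage draws per test. Bit-reproducible from
#' the seed.
#'
#' @param config a [simConfig()] list (uses `N`, `T`, `afLow`, `afHigh`,
#'   `seed`).
#' @return list with `G` (N x T dosage matrix, entries 0/1/2) and `af`
#'   (length-T allele frequencies).
#' @export
simulateGenotypes <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  .drawGenotypes(config)
}

.drawGenotypes <- function(config) {
  af <- runif(config$T, config$afLow, config$afHigh)
  G <- vapply(af, function(a) rbinom(config$N, 2L, a),
              numeric(config$N))
  list(G = matrix(G, nrow = config$N), af = af)
}

#' Simulate a latent-context eQTL dataset
#'
#' The generative process, per test t with simulated genotype `G_t`:
#' \deqn{y_n = \mu_t + \beta_t G_{nt} + \sum_k G_{nt} U_{nk} V_{kt} \theta_{kt} + \epsilon_n,
#'       \quad \epsilon_n \sim N(0, 1)}
#' with `mu_t, beta_t ~ N(0,1)`, sample contexts `U_nk ~ N(0,1)` shared
#' across tests, context effects `V_kt ~ N(0, gamma^2)` and activity
#' indicators `theta_kt ~ Bernoulli(p)`. Genotypes follow
#' [simulateGenotypes()]. When `nIndividuals < N`, samples are assigned to
#' individuals round-robin and samples of one individual share the
#' individual's genotype row (a fixture extension for the random-intercept
#' and permutation machinery; the generative description itself has one
#' sample per individual).
#'
#' @param config a [simConfig()] list.
#' @return list with `dataset` (a raw [EQTLDataset-class]) and `truth` (list
#'   with `U`, `V` (K x T), `theta` (K x T in 0/1), `mu`, `beta`, `af`,
#'   `G`).
#' @examples
#' sim <- simulateEqtlData(simConfig(N = 50, T = 20, K = 2, seed = 11))
#' dim(exprMatrix(sim$dataset))
#' @export
simulateEqtlData <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  N <- config$N; T <- config$T; K <- config$K
  ind <- rep_len(seq_len(config$nIndividuals), N)
  geno <- .drawGenotypes(modifyList(config, list(N = config$nIndividuals)))
  G <- geno$G[ind, , drop = FALSE]  # samples of an individual share dosages
  U <- matrix(rnorm(N * K), N, K)
  V <- matrix(rnorm(K * T, sd = config$gamma), K, T)
  theta <- matrix(rbinom(K * T, 1L, config$p), K, T)
  mu <- rnorm(T)
  beta <- rnorm(T)
  inter <- if (K > 0) U %*% (V * theta) else matrix(0, N, T)
  Y <- G * (inter + matrix(beta, N, T, byrow = TRUE))
  Y <- sweep(Y, 2, mu, "+") + matrix(rnorm(N * T), N, T)
  samples <- sprintf("sample%03d", seq_len(N))
  tests <- sprintf("test%04d", seq_len(T))
  dimnames(Y) <- list(samples, tests)
  dimnames(G) <- dimnames(Y)
  meta <- S4Vectors::DataFrame(
    gene = sprintf("gene%04d", seq_len(T)),
    variant = sprintf("variant%04d", seq_len(T)),
    chromosome = rep("chr1", T),
    position = seq_len(T) * 1000L
  )
  dataset <- EQTLDataset(
    expression = Y, dosage = G, covariates = NULL,
    individual = sprintf("ind%03d", ind), testMeta = meta
  )
  truth <- list(U = U, V = V, theta = theta, mu = mu, beta = beta,
                af = geno$af, G = G)
  list(dataset = dataset, truth = truth)
}

#' Variance of simulated contexts explained by learned contexts
#'
#' For each simulated context column, regresses it (with intercept) on all
#' learned context columns jointly and takes the R-squared; returns the mean
#' over simulated contexts. Invariant to permuting or sign-flipping learned
#' contexts; returns 0 when no contexts were learned.
#'
#' @param uSim N x K_sim matrix of true simulated contexts.
#' @param uLearned N x K' matrix of learned contexts (0 columns allowed).
#' @param perContextBest match each simulated context to its single
#'   best-explaining learned context (greedy, simple regression) instead of
#'   the joint multiple regression.
#' @return mean R-squared in `[0, 1]`.
#' @export
contextRecoveryScore <- function(uSim, uLearned, perContextBest = FALSE) {
  uSim <- as.matrix(uSim); uLearned <- as.matrix(uLearned)
  if (nrow(uSim) != nrow(uLearned))
    stop("uSim and uLearned must have the same number of samples")
  if (ncol(uLearned) == 0) return(0)
  r2one <- function(yv, Xm) {
    fit <- lm.fit(cbind(1, Xm), yv)
    1 - sum(fit$residuals^2) / sum((yv - mean(yv))^2)
  }
  scores <- apply(uSim, 2, function(u) {
    if (perContextBest) {
      max(apply(uLearned, 2, function(col) r2one(u, cbind(col))))
    } else {
      r2one(u, uLearned)
    }
  })
  mean(scores)
}

#' Write a simulated dataset and its generative truth as TSV
#'
#' Emits the four dataset files ([readEQTLDataset()]-compatible) plus truth
#' tables, so a simulation can be round-tripped through the file interface.
#'
#' @param sim output of [simulateEqtlData()].
#' @param dir output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
writeSimulatedData <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ds <- sim$dataset
  writeMatrixTsv(t(exprMatrix(ds)), file.path(dir, "expression.tsv"))
  writeMatrixTsv(t(dosageMatrix(ds)), file.path(dir, "genotype.tsv"))
  writeResultTable(
    data.frame(sample_id = colnames(ds),
               individual_id = as.character(individualOf(ds))),
    file.path(dir, "sample_map.tsv"))
  meta <- as.data.frame(testMeta(ds))
  writeResultTable(cbind(data.frame(test_id = rownames(ds)), meta),
                   file.path(dir, "test_meta.tsv"))
  writeMatrixTsv(sim$truth$U, file.path(dir, "truth_U.tsv"))
  writeMatrixTsv(sim$truth$V, file.path(dir, "truth_V.tsv"))
  writeMatrixTsv(sim$truth$theta, file.path(dir, "truth_theta.tsv"))
  writeResultTable(
    data.frame(test = rownames(ds), mu = sim$truth$mu, beta = sim$truth$beta,
               af = sim$truth$af),
    file.path(dir, "truth_scalars.tsv"))
  invisible(dir)
}
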