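#' Assemble model-ready matrices from a dataset
#'
#' Packs the matrices the coordinate-ascent engine consumes: expression `Y`,
#' main-effect genotype `Gm`, interaction genotype `Gi` (identical to `Gm`
#' except under the individual-level genotype permutation, which replaces the
#' interaction copy only), covariates, and the integer sample-to-individual
#' map.
#'
#' @param dataset a preprocessed [EQTLDataset-class].
#' @param gInteraction optional N x T matrix replacing the genotype in the
#'   interaction term (see [permuteGenotypeByIndividual()]).
#' @param useRandomIntercept `TRUE`/`FALSE`/`NA`; `NA` enables per-individual
#'   random intercepts exactly when repeat structure exists.
#' @return a list with elements `Y`, `Gm`, `Gi`, `X`, `ind`, `I`, `useAlpha`,
#'   `N`, `T`, `L`.
#' @export
surgeModelData <- function(dataset, gInteraction = NULL,
                           useRandomIntercept = NA) {
  stopifnot(is(dataset, "EQTLDataset"))
  Y <- unname(exprMatrix(dataset))
  Gm <- unname(dosageMatrix(dataset))
  Gi <- if (is.null(gInteraction)) Gm else unname(as.matrix(gInteraction))
  if (!all(dim(Gi) == dim(Gm)))
    stop("gInteraction must match the dosage matrix dimensions")
  X <- unname(covariateMatrix(dataset))
  ind <- as.integer(individualOf(dataset))
  I <- nlevels(individualOf(dataset))
  useAlpha <- if (is.na(useRandomIntercept)) I < nrow(Y) else isTRUE(useRandomIntercept)
  list(Y = Y, Gm = Gm, Gi = Gi, X = X, ind = ind, I = I,
       useAlpha = useAlpha, N = nrow(Y), T = ncol(Y), L = ncol(X))
}

#' Initialize the variational state
#'
#' Gaussian latents start at mean 0 and variance 1, except the context
#' loadings U whose means are drawn from a standard normal (breaking symmetry
#' between contexts); the Gamma factors start at their prior parameters.
#' Bit-identical across calls with the same seed.
#'
#' @param data list from [surgeModelData()].
#' @param K number of latent contexts to initialize.
#' @param seed integer seed.
#' @param alpha0,beta0 Gamma prior shape and rate.
#' @return named list of variational parameters.
#' @export
initSurgeState <- function(data, K, seed, alpha0 = 1e-3, beta0 = 1e-3) {
  stopifnot(K >= 1)
  N <- data$N; T <- data$T; L <- data$L; I <- data$I
  set.seed(seed)
  list(
    Umu = matrix(rnorm(N * K), N, K), Us2 = matrix(1, N, K),
    Vmu = matrix(0, K, T), Vs2 = matrix(1, K, T),
    Fmu = numeric(T), Fs2 = rep(1, T),
    mumu = numeric(T), mus2 = rep(1, T),
    Wmu = matrix(0, L, T), Ws2 = matrix(1, L, T),
    Amu = matrix(0, I, T), As2 = matrix(1, I, T),
    ga = rep(alpha0, K), gb = rep(beta0, K),
    pa = rep(alpha0, T), pb = rep(beta0, T),
    sa = rep(alpha0, T), sb = rep(beta0, T)
  )
}

.blockOrder <- function(data) {
  blocks <- c("V", "F", "mu", "W", "alpha", "U", "gamma", "psi", "sigma")
  if (data$L == 0) blocks <- setdiff(blocks, "W")
  if (!data$useAlpha) blocks <- setdiff(blocks, c("alpha", "psi"))
  blocks
}

#' One full coordinate-ascent sweep
#'
#' Updates every variational block once, in the fixed order V, F, mu, W,
#' alpha, U, then the gamma, psi and sigma precisions (covariate and
#' random-intercept blocks are skipped when absent). Each block update is the
#' closed-form conjugate optimum, so the ELBO cannot decrease.
#'
#' @param state variational state list.
#' @param data list from [surgeModelData()].
#' @param alpha0,beta0 Gamma prior shape and rate.
#' @return updated state list.
#' @export
caviIteration <- function(state, data, alpha0 = 1e-3, beta0 = 1e-3) {
  .cpp_update_blocks(state, data$Y, data$Gm, data$Gi, data$X, data$ind,
                     data$I, data$useAlpha, alpha0, beta0, .blockOrder(data))
}

#' Update a single variational block
#'
#' Exposed so a block's closed-form update can be compared against direct
#' numeric maximization of the ELBO over that block's parameters.
#'
#' @param state variational state list.
#' @param data list from [surgeModelData()].
#' @param block one of `"V"`, `"F"`, `"mu"`, `"W"`, `"alpha"`, `"U"`,
#'   `"gamma"`, `"psi"`, `"sigma"`.
#' @param alpha0,beta0 Gamma prior shape and rate.
#' @return updated state list.
#' @export
caviUpdateBlock <- function(state, data, block, alpha0 = 1e-3, beta0 = 1e-3) {
  block <- match.arg(block, c("V", "F", "mu", "W", "alpha", "U",
                              "gamma", "psi", "sigma"))
  .cpp_update_blocks(state, data$Y, data$Gm, data$Gi, data$X, data$ind,
                     data$I, data$useAlpha, alpha0, beta0, block)
}

#' Evidence lower bound of a variational state
#'
#' Exact ELBO `E_q[log p(Y, Z)] - E_q[log q(Z)]` computed from Gaussian and
#' Gamma moment identities — no Monte Carlo.
#'
#' @inheritParams caviIteration
#' @return finite numeric scalar.
#' @export
computeElbo <- function(state, data, alpha0 = 1e-3, beta0 = 1e-3) {
  .cpp_elbo(state, data$Y, data$Gm, data$Gi, data$X, data$ind,
            data$I, data$useAlpha, alpha0, beta0)
}

# single optimization run: iterate to convergence or the cap; the sweep and
# its end-of-sweep ELBO come from one fused C++ call
.fitOnce <- function(data, K, seed, config) {
  state <- initSurgeState(data, K, seed, config$alpha0, config$beta0)
  trace <- numeric(config$maxIter)
  converged <- FALSE
  blocks <- .blockOrder(data)
  for (iter in seq_len(config$maxIter)) {
    state <- .cpp_update_blocks(state, data$Y, data$Gm, data$Gi, data$X,
                                data$ind, data$I, data$useAlpha,
                                config$alpha0, config$beta0, blocks,
                                returnElbo = TRUE)
    e <- attr(state, "elbo")
    if (!is.finite(e)) return(list(diverged = TRUE))
    trace[iter] <- e
    if (iter >= 2 && abs(trace[iter] - trace[iter - 1]) < config$elboTol) {
      converged <- TRUE
      break
    }
  }
  trace <- trace[seq_len(iter)]
  list(diverged = FALSE, state = state, trace = trace,
       elbo = trace[length(trace)], converged = converged)
}

#' Fit the latent-context eQTL model
#'
#' Runs `nRestarts` independent coordinate-ascent optimizations from random
#' initializations (restart seeds derived deterministically from
#' `config$seed`), keeps the restart with the largest final ELBO, computes
#' per-context PVE, and prunes contexts whose PVE falls at or below
#' `config$pveThreshold`. Convergence is declared when the ELBO changes by
#' less than `config$elboTol` between sweeps.
#'
#' @param dataset an [EQTLDataset-class]; standardized automatically if not
#'   yet preprocessed.
#' @param config a [surgeConfig()] list.
#' @param gInteraction optional permuted interaction genotype matrix (the
#'   genotype main effect keeps the original dosages).
#' @return a [SurgeFit-class].
#' @examples
#' sim <- simulateEqtlData(simConfig(N = 60, T = 60, K = 1, gamma = 1,
#'                                   p = 0.5, seed = 3))
#' fit <- fitSurge(sim$dataset, surgeConfig(kInit = 2, nRestarts = 1,
#'                                          maxIter = 50, seed = 3))
#' contextPve(fit)
#' @export
fitSurge <- function(dataset, config = surgeConfig(), gInteraction = NULL) {
  stopifnot(is(dataset, "EQTLDataset"))
  if (!dataset@preprocessed) {
    message("standardizing dataset before fitting")
    dataset <- preprocessDataset(dataset)
  }
  data <- surgeModelData(dataset, gInteraction = gInteraction,
                         useRandomIntercept = config$useRandomIntercept)
  if (data$T < 2) stop("need at least 2 tests")
  if (data$N <= data$L + 2) stop("need more samples than covariates + 2")
  set.seed(config$seed)
  restartSeeds <- sample.int(.Machine$integer.max - 1L, config$nRestarts)
  runs <- lapply(restartSeeds, function(s) .fitOnce(data, config$kInit, s, config))
  ok <- !vapply(runs, `[[`, logical(1), "diverged")
  if (!any(ok)) stop("all restarts diverged (non-finite ELBO)")
  winner <- which(ok)[which.max(vapply(runs[ok], `[[`, numeric(1), "elbo"))]
  run <- runs[[winner]]
  pv <- computePve(run$state, dataset, gInteraction = gInteraction)
  .buildSurgeFit(run, winner, pv, dataset, config)
}

.buildSurgeFit <- function(run, winner, pv, dataset, config) {
  state <- run$state
  retained <- which(pv$pve > config$pveThreshold)
  retained <- retained[order(pv$pve[retained], decreasing = TRUE)]
  K2 <- length(retained)
  samples <- colnames(dataset)
  tests <- rownames(dataset)
  U <- state$Umu[, retained, drop = FALSE]
  V <- state$Vmu[retained, , drop = FALSE]
  ctxNames <- if (K2) paste0("context", seq_len(K2)) else character()
  dimnames(U) <- list(samples, ctxNames)
  dimnames(V) <- list(ctxNames, tests)
  Fhat <- setNames(as.numeric(state$Fmu), tests)
  psmveRet <- if (K2) pv$s[retained] / sum(pv$s[retained]) else numeric()
  new("SurgeFit",
      U = U, V = V, F = Fhat,
      pve = unname(pv$pve[retained]), psmve = unname(psmveRet),
      pveAll = unname(pv$pve), psmveAll = unname(pv$psmve),
      retained = as.integer(retained), sigmaSq = unname(pv$sigmaSq),
      state = state, elbo = run$elbo, elboTrace = run$trace,
      restart = as.integer(winner), converged = run$converged,
      config = unclass(config))
}

#' Proportion of variance explained per latent context
#'
#' The signal carried by context k is summarized as
#' `s_k = sum_nt (G_nt * Uhat_nk * Vhat_kt)^2` (posterior means as plug-ins);
#' `pve_k = s_k / (sum_k s_k + N * sum_t sigmahat_t^2)` relates it to total
#' residual variance and `psmve_k = s_k / sum_k s_k` to the model-mediated
#' part only. `strict = TRUE` instead uses the signed sum
#' `s_k = sum_nt G_nt Uhat_nk Vhat_kt`, which can be negative; the squared
#' form is the default because a variance share must be non-negative.
#'
#' @param x a [SurgeFit-class] or a variational state list.
#' @param dataset the preprocessed [EQTLDataset-class] the state was fit to.
#' @param strict use the literal signed sum for `s_k`.
#' @param gInteraction optional permuted interaction genotype matrix; must
#'   match what the fit used.
#' @return list with `pve`, `psmve`, `s` (per context, original order) and
#'   `sigmaSq` (per-test posterior-mean residual variance). When every `s_k`
#'   is exactly zero, `psmve` is `NaN` with a warning.
#' @export
computePve <- function(x, dataset, strict = FALSE, gInteraction = NULL) {
  state <- if (is(x, "SurgeFit")) x@state else x
  Gi <- if (is.null(gInteraction)) unname(dosageMatrix(dataset))
        else unname(as.matrix(gInteraction))
  U <- state$Umu
  V <- state$Vmu
  K <- ncol(U)
  sa <- as.numeric(state$sa); sb <- as.numeric(state$sb)
  sigmaSq <- sb / (sa - 1)  # posterior mean of sigma_t^2 (sa > 1 whenever N >= 3)
  if (strict) {
    GtU <- crossprod(Gi, U)                      # T x K
    s <- vapply(seq_len(K), function(k) sum(GtU[, k] * V[k, ]), numeric(1))
  } else {
    A <- crossprod(Gi^2, U^2)                    # T x K
    s <- vapply(seq_len(K), function(k) sum(A[, k] * V[k, ]^2), numeric(1))
  }
  denom <- sum(s) + nrow(Gi) * sum(sigmaSq)
  if (denom <= 0) stop("degenerate variance decomposition: non-positive denominator")
  pve <- s / denom
  if (sum(s) == 0) {
    warning("all contexts carry zero signal; psmve is undefined")
    psmve <- rep(NaN, K)
  } else {
    psmve <- s / sum(s)
  }
  list(pve = pve, psmve = psmve, s = s, sigmaSq = sigmaSq)
}

#' Prune low-signal latent contexts
#'
#' Removes contexts whose PVE is at or below `threshold` and renormalizes
#' PSMVE over the survivors. Zero survivors is allowed; downstream
#' interaction testing then refuses with a clear message.
#'
#' @param fit a [SurgeFit-class].
#' @param threshold PVE cutoff.
#' @return a [SurgeFit-class] with the new retention set.
#' @export
pruneContexts <- function(fit, threshold = 1e-5) {
  stopifnot(is(fit, "SurgeFit"))
  retained <- which(fit@pveAll > threshold)
  retained <- retained[order(fit@pveAll[retained], decreasing = TRUE)]
  K2 <- length(retained)
  samples <- rownames(fit@U)
  if (is.null(samples) && nrow(fit@state$Umu) > 0)
    samples <- paste0("sample", seq_len(nrow(fit@state$Umu)))
  tests <- names(fit@F)
  U <- fit@state$Umu[, retained, drop = FALSE]
  V <- fit@state$Vmu[retained, , drop = FALSE]
  ctxNames <- if (K2) paste0("context", seq_len(K2)) else character()
  dimnames(U) <- list(samples, ctxNames)
  dimnames(V) <- list(ctxNames, tests)
  psmve <- if (K2) fit@psmveAll[retained] / sum(fit@psmveAll[retained]) else numeric()
  methods::initialize(fit, U = U, V = V,
                      pve = unname(fit@pveAll[retained]),
                      psmve = unname(psmve),
                      retained = as.integer(retained),
                      config = modifyList(fit@config, list(pveThreshold = threshold)))
}

#' Number of latent contexts surviving the PVE threshold
#'
#' @param fit a [SurgeFit-class].
#' @param threshold PVE cutoff; defaults to the fit's configured threshold.
#' @return integer count of contexts with PVE strictly above the threshold.
#' @export
countRecoveredContexts <- function(fit, threshold = NULL) {
  stopifnot(is(fit, "SurgeFit"))
  if (is.null(threshold)) threshold <- fit@config$pveThreshold
  sum(fit@pveAll > threshold)
}

#' @rdname accessors
#' @export
setMethod("contextLoadings", "SurgeFit", function(x) x@U)

#' @rdname accessors
#' @export
setMethod("contextEffects", "SurgeFit", function(x) x@V)

#' @rdname accessors
#' @export
setMethod("sharedEffects", "SurgeFit", function(x) x@F)

#' @rdname accessors
#' @export
setMethod("contextPve", "SurgeFit", function(x) x@pve)

#' @rdname accessors
#' @export
setMethod("contextPsmve", "SurgeFit", function(x) x@psmve)

#' @rdname accessors
#' @export
setMethod("elboTrace", "SurgeFit", function(x) x@elboTrace)

setMethod("show", "SurgeFit", function(object) {
  cat(sprintf(
    "SurgeFit: %d of %d contexts retained (PVE > %g)\n",
    ncol(object@U), length(object@pveAll), object@config$pveThreshold))
  cat(sprintf("  samples: %d, tests: %d\n", nrow(object@U), length(object@F)))
  cat(sprintf("  ELBO %.4f after %d iterations (restart %d%s)\n",
              object@elbo, length(object@elboTrace), object@restart,
              if (object@converged) ", converged" else ", iteration cap reached"))
  if (length(object@pve))
    cat("  PVE:", paste(sprintf("%.3g", object@pve), collapse = ", "), "\n")
})
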