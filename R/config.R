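#' Configuration for model fitting
#'
#' Bundles and validates every tunable of [fitSurge()].
#'
#' @param kInit number of latent contexts to initialize; should exceed the
#'   number of contexts plausibly present, irrelevant ones are pruned.
#' @param nRestarts independent random restarts; the restart with the largest
#'   final ELBO wins.
#' @param elboTol convergence threshold on the absolute change in ELBO
#'   between consecutive iterations.
#' @param maxIter iteration cap per restart.
#' @param pveThreshold contexts with PVE at or below this are pruned.
#' @param alpha0,beta0 shape and rate of the Gamma priors on the precisions
#'   (1/gamma_k^2, 1/psi_t^2, 1/sigma_t^2); small values give near
#'   non-informative priors.
#' @param useRandomIntercept `TRUE`, `FALSE`, or `NA` (default) to include
#'   per-individual random intercepts; `NA` enables them exactly when some
#'   individual contributes more than one sample.
#' @param seed integer seed; restart seeds are derived from it
#'   deterministically.
#' @param efdrMode `"per-context"` (recommended) or `"all-context"`.
#' @param efdrLevel target empirical FDR for significance calls.
#'
#' @return a validated named list of class `surgeConfig`.
#' @examples
#' surgeConfig(kInit = 10, seed = 1)
#' @export
surgeConfig <- function(kInit = 10L, nRestarts = 3L, elboTol = 1e-2,
                        maxIter = 1000L, pveThreshold = 1e-5,
                        alpha0 = 1e-3, beta0 = 1e-3,
                        useRandomIntercept = NA, seed = 1L,
                        efdrMode = c("per-context", "all-context"),
                        efdrLevel = 0.05) {
  efdrMode <- match.arg(efdrMode)
  cfg <- list(
    kInit = as.integer(kInit), nRestarts = as.integer(nRestarts),
    elboTol = elboTol, maxIter = as.integer(maxIter),
    pveThreshold = pveThreshold, alpha0 = alpha0, beta0 = beta0,
    useRandomIntercept = useRandomIntercept, seed = as.integer(seed),
    efdrMode = efdrMode, efdrLevel = efdrLevel
  )
  if (cfg$kInit < 1L) stop("kInit must be at least 1")
  if (cfg$nRestarts < 1L) stop("nRestarts must be at least 1")
  if (cfg$elboTol <= 0) stop("elboTol must be positive")
  if (cfg$maxIter < 1L) stop("maxIter must be at least 1")
  if (cfg$pveThreshold < 0) stop("pveThreshold must be non-negative")
  if (cfg$alpha0 <= 0 || cfg$beta0 <= 0) stop("alpha0 and beta0 must be positive")
  if (cfg$efdrLevel <= 0 || cfg$efdrLevel >= 1) stop("efdrLevel must be in (0, 1)")
  class(cfg) <- "surgeConfig"
  cfg
}

#' Configuration for the generative simulator
#'
#' Parameters of the simulation framework used both for power evaluation and
#' as the package's test-fixture generator; see [simulateEqtlData()] for the
#' generative distributions.
#'
#' @param N number of RNA samples.
#' @param T number of variant-gene pairs (tests).
#' @param K number of simulated latent contexts.
#' @param gamma standard deviation of the context-specific eQTL effects
#'   `V_k ~ N(0, gamma^2)`; the "interaction variance" scale is `gamma^2`.
#' @param p per-test, per-context probability that the context-eQTL indicator
#'   is active.
#' @param afLow,afHigh bounds of the uniform allele-frequency distribution.
#' @param nIndividuals number of individuals samples are assigned to
#'   (round-robin); defaults to `N`, i.e. no repeat structure, matching the
#'   generative description. Smaller values exist to exercise the
#'   random-intercept and permutation machinery.
#' @param seed integer seed.
#' @return a validated named list of class `simConfig`.
#' @examples
#' simConfig(N = 100, T = 50, K = 2, gamma = 0.5, p = 0.3, seed = 7)
#' @export
simConfig <- function(N, T = 1000L, K = 5L, gamma = 0.5, p = 0.3,
                      afLow = 0.05, afHigh = 0.95, nIndividuals = N,
                      seed = 1L) {
  cfg <- list(N = as.integer(N), T = as.integer(T), K = as.integer(K),
              gamma = gamma, p = p, afLow = afLow, afHigh = afHigh,
              nIndividuals = as.integer(nIndividuals), seed = as.integer(seed))
  if (cfg$N < 2L) stop("N must be at least 2")
  if (cfg$T < 1L) stop("T must be at least 1")
  if (cfg$K < 0L) stop("K must be non-negative")
  if (cfg$gamma < 0) stop("gamma must be non-negative")
  if (cfg$p < 0 || cfg$p > 1) stop("p must be in [0, 1]")
  if (cfg$afLow <= 0 || cfg$afHigh >= 1 || cfg$afLow >= cfg$afHigh)
    stop("require 0 < afLow < afHigh < 1")
  if (cfg$nIndividuals < 1L || cfg$nIndividuals > cfg$N)
    stop("nIndividuals must be in [1, N]")
  class(cfg) <- "simConfig"
  cfg
}
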