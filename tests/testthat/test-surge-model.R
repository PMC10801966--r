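test_that("initialization is seed-deterministic with unit-scale loadings", {
  m <- makeTinyModel(N = 50, T = 10, K = 10, L = 0, seed = 31)
  s1 <- initSurgeState(m$data, K = 10, seed = 99)
  s2 <- initSurgeState(m$data, K = 10, seed = 99)
  expect_identical(s1, s2)
  s3 <- initSurgeState(m$data, K = 10, seed = 100)
  expect_false(identical(s1$Umu, s3$Umu))
  expect_identical(dim(s1$Umu), c(50L, 10L))
  expect_gt(sd(s1$Umu), 0.7)
  expect_lt(sd(s1$Umu), 1.3)
  expect_true(all(s1$Us2 == 1))
  expect_true(all(s1$ga == 1e-3) && all(s1$gb == 1e-3))
})

test_that("the analytic ELBO matches a quadrature-moment oracle", {
  # no covariates, one sample per individual
  m <- makeTinyModel(N = 6, T = 4, K = 1, L = 0, I = 6, seed = 32,
                     iterations = 2)
  expect_equal(computeElbo(m$state, m$data),
               elboQuadratureOracle(m$state, m$data), tolerance = 1e-6)
  # with covariates and repeat structure (random intercepts active)
  m2 <- makeTinyModel(N = 6, T = 4, K = 1, L = 2, I = 3, seed = 33,
                      iterations = 2)
  expect_true(m2$data$useAlpha)
  expect_equal(computeElbo(m2$state, m2$data),
               elboQuadratureOracle(m2$state, m2$data), tolerance = 1e-6)
})

test_that("ELBO is invariant to permuting test order", {
  m <- makeTinyModel(N = 10, T = 6, K = 2, L = 1, seed = 34, iterations = 1)
  e0 <- computeElbo(m$state, m$data)
  perm <- c(4, 1, 6, 2, 5, 3)
  d2 <- m$data
  for (f in c("Y", "Gm", "Gi")) d2[[f]] <- d2[[f]][, perm]
  s2 <- m$state
  s2$Vmu <- s2$Vmu[, perm, drop = FALSE]; s2$Vs2 <- s2$Vs2[, perm, drop = FALSE]
  for (f in c("Fmu", "Fs2", "mumu", "mus2", "sa", "sb", "pa", "pb"))
    s2[[f]] <- as.numeric(s2[[f]])[perm]
  s2$Wmu <- s2$Wmu[, perm, drop = FALSE]; s2$Ws2 <- s2$Ws2[, perm, drop = FALSE]
  s2$Amu <- s2$Amu[, perm, drop = FALSE]; s2$As2 <- s2$As2[, perm, drop = FALSE]
  expect_equal(computeElbo(s2, d2), e0, tolerance = 1e-9)
})

test_that("single-block updates never decrease the ELBO", {
  m <- makeTinyModel(N = 12, T = 8, K = 2, L = 1, I = 6, seed = 35)
  st <- m$state
  e <- computeElbo(st, m$data)
  for (rep in 1:3) {
    for (b in c("V", "F", "mu", "W", "alpha", "U", "gamma", "psi", "sigma")) {
      st <- caviUpdateBlock(st, m$data, b)
      e2 <- computeElbo(st, m$data)
      expect_gte(e2, e - 1e-8 * abs(e))
      e <- e2
    }
  }
})

test_that("a full iteration strictly increases the ELBO from a fresh start", {
  m <- makeTinyModel(N = 15, T = 10, K = 2, L = 0, seed = 36)
  e0 <- computeElbo(m$state, m$data)
  s1 <- caviIteration(m$state, m$data)
  expect_gt(computeElbo(s1, m$data), e0)
})

test_that("each closed-form block update matches numeric ELBO maximization", {
  # N=8, T=5, K=1 instance with one covariate and repeat structure so every
  # block is exercised; K=1/L=1 keeps blocks free of internal coupling
  m <- makeTinyModel(N = 8, T = 5, K = 1, L = 1, I = 4, seed = 37,
                     iterations = 1)
  fields <- list(
    V = c("Vmu", "Vs2"), F = c("Fmu", "Fs2"), mu = c("mumu", "mus2"),
    W = c("Wmu", "Ws2"), alpha = c("Amu", "As2"), U = c("Umu", "Us2"),
    gamma = c("ga", "gb"), psi = c("pa", "pb"), sigma = c("sa", "sb"))
  for (b in names(fields)) {
    closed <- caviUpdateBlock(m$state, m$data, b)
    numeric <- numericBlockOptimum(m$state, m$data, b)
    got1 <- as.matrix(closed[[fields[[b]][1]]])
    got2 <- as.matrix(closed[[fields[[b]][2]]])
    expect_lt(max(abs(got1 - numeric$par1)), 1e-4)
    expect_lt(max(abs(got2 - numeric$par2) / pmax(1, abs(numeric$par2))), 1e-4)
  }
})

test_that("zero genotype leaves eQTL effects at their prior mean", {
  m <- makeTinyModel(N = 20, T = 8, K = 2, L = 0, seed = 38)
  d <- m$data
  d$Gm <- d$Gm * 0
  d$Gi <- d$Gi * 0
  st <- m$state
  for (i in 1:60) st <- caviIteration(st, d)
  expect_lt(max(abs(as.numeric(st$Fmu))), 1e-6)
  expect_lt(max(abs(st$Vmu)), 1e-6)
  expect_lt(max(abs(st$Umu)), 1e-6)
})

test_that("PVE formula limits and oracle re-evaluation hold", {
  # hand-crafted state: two contexts with equal signal c and N*sum(sigma2)=2c
  ds <- EQTLDataset(expression = matrix(0, 1, 1), dosage = matrix(1, 1, 1),
                    individual = "i1", preprocessed = TRUE)
  st <- list(Umu = matrix(c(1, 1), 1, 2), Vmu = matrix(c(1, 1), 2, 1),
             sa = 2, sb = 2)  # E[sigma^2] = sb/(sa-1) = 2
  pv <- computePve(st, ds)
  expect_equal(pv$pve, c(0.25, 0.25))
  expect_equal(pv$psmve, c(0.5, 0.5))
  expect_equal(sum(pv$psmve), 1, tolerance = 1e-10)

  # single context, near-zero residual variance
  st1 <- list(Umu = matrix(1, 1, 1), Vmu = matrix(1, 1, 1),
              sa = 1e12, sb = 1)
  pv1 <- computePve(st1, ds)
  expect_equal(pv1$pve, 1, tolerance = 1e-9)
  expect_equal(pv1$psmve, 1)

  # fitted toy model: formula re-evaluation from exported posterior means
  m <- makeSimFit(N = 60, T = 40, K = 1, gamma = 1, p = 0.5, seed = 39)
  fit <- fitSurge(m$dataset, surgeConfig(kInit = 2, nRestarts = 1,
                                         maxIter = 150, seed = 39))
  G <- dosageMatrix(m$dataset)
  s <- vapply(seq_len(ncol(fit@state$Umu)), function(k) {
    sum((G * outer(fit@state$Umu[, k], as.numeric(fit@state$Vmu[k, ])))^2)
  }, numeric(1))
  pveOracle <- s / (sum(s) + nrow(G) * sum(fit@sigmaSq))
  expect_equal(fit@pveAll, pveOracle, tolerance = 1e-10)
})

test_that("pruning keeps exactly the contexts above threshold", {
  m <- makeSimFit(N = 50, T = 30, K = 1, gamma = 1, p = 0.5, seed = 40)
  fit <- fitSurge(m$dataset, surgeConfig(kInit = 4, nRestarts = 1,
                                         maxIter = 150, seed = 40))
  for (thr in c(1e-7, 1e-5, 1e-2, 0.99)) {
    pruned <- pruneContexts(fit, thr)
    expect_identical(ncol(contextLoadings(pruned)), sum(fit@pveAll > thr))
    expect_identical(countRecoveredContexts(fit, thr), sum(fit@pveAll > thr))
    if (ncol(contextLoadings(pruned)) > 0)
      expect_equal(sum(contextPsmve(pruned)), 1, tolerance = 1e-10)
  }
  empty <- pruneContexts(fit, 1)
  expect_identical(ncol(contextLoadings(empty)), 0L)
  expect_error(testInteractions(m$dataset, contextLoadings(empty)),
               "zero contexts")
})

test_that("a single strong context is recovered by a K=1 fit", {
  m <- makeSimFit(N = 150, T = 150, K = 1, gamma = 1, p = 0.5, seed = 41)
  fit <- fitSurge(m$dataset, surgeConfig(kInit = 1, nRestarts = 2,
                                         maxIter = 300, seed = 41))
  expect_identical(countRecoveredContexts(fit), 1L)
  r <- cor(m$sim$truth$U[, 1], contextLoadings(fit)[, 1])
  expect_gt(abs(r), 0.9)
})

test_that("restarts are deterministic and the best ELBO wins", {
  m <- makeSimFit(N = 40, T = 30, K = 1, gamma = 1, p = 0.5, seed = 42)
  cfg <- surgeConfig(kInit = 2, nRestarts = 3, maxIter = 100, seed = 7)
  f1 <- fitSurge(m$dataset, cfg)
  f2 <- fitSurge(m$dataset, cfg)
  expect_identical(f1@elbo, f2@elbo)
  expect_identical(f1@restart, f2@restart)
  expect_identical(contextLoadings(f1), contextLoadings(f2))
})
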