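test_that("with no contexts and no repeat structure the test is textbook OLS", {
  set.seed(51)
  N <- 80
  g <- rbinom(N, 2, 0.4)
  X <- cbind(rnorm(N))
  y <- 0.3 * g + 0.5 * X[, 1] + rnorm(N)
  fit <- fitInteractionModel(y, g, X, contexts = NULL,
                             individual = paste0("i", 1:N))
  ref <- summary(lm(y ~ X + g))$coefficients
  expect_identical(fit$method, "ols")
  gRow <- fit$coefficients[fit$coefficients$term == "g", ]
  expect_equal(gRow$estimate, ref["g", 1], tolerance = 1e-10)
  expect_equal(gRow$se, ref["g", 2], tolerance = 1e-10)
  expect_equal(gRow$p, ref["g", 4], tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected with the offending column", {
  set.seed(52)
  N <- 40
  g <- rbinom(N, 2, 0.5)
  y <- rnorm(N)
  ctx <- cbind(rep(0, N))  # constant context column
  expect_error(
    fitInteractionModel(y, g, contexts = ctx, individual = paste0("i", 1:N)),
    "rank-deficient.*ctx1")
  expect_error(
    fitInteractionModel(y, rep(1, N), contexts = NULL,
                        individual = paste0("i", 1:N)),
    "rank-deficient.*g")
})

test_that("the LMM recovers a known interaction effect under repeat structure", {
  set.seed(53)
  I <- 200; reps <- 2; N <- I * reps
  ind <- rep(seq_len(I), each = reps)
  g <- rbinom(I, 2, 0.4)[ind]      # genotype constant within individual
  u <- rnorm(N)
  aInt <- rnorm(I, sd = 0.5)[ind]  # individual intercepts, sd 0.5
  y <- 0.2 * g + 0.1 * u + 0.5 * g * u + aInt + rnorm(N)
  fit <- fitInteractionModel(y, g, contexts = cbind(u), individual = ind,
                             useRandomIntercept = TRUE)
  expect_identical(fit$method, "lmm")
  est <- fit$interactions$estimate
  expect_lt(abs(est - 0.5), 3 * fit$interactions$se)
  expect_gt(fit$psiSq, 0.05)  # intercept variance detected
})

test_that("interaction tests are equivariant to joint sample permutation", {
  set.seed(54)
  N <- 60
  ind <- rep(1:30, each = 2)
  g <- rbinom(30, 2, 0.4)[ind]
  u <- rnorm(N)
  y <- 0.4 * g * u + rnorm(N) + rnorm(30, sd = 0.3)[ind]
  f1 <- fitInteractionModel(y, g, contexts = cbind(u), individual = ind,
                            useRandomIntercept = TRUE)
  perm <- sample(N)
  f2 <- fitInteractionModel(y[perm], g[perm], contexts = cbind(u[perm]),
                            individual = ind[perm], useRandomIntercept = TRUE)
  expect_equal(f1$interactions$estimate, f2$interactions$estimate,
               tolerance = 1e-6)
  expect_equal(f1$interactions$p, f2$interactions$p, tolerance = 1e-5)
})

test_that("testInteractions aggregates gene-level Bonferroni correctly", {
  set.seed(55)
  N <- 50; T <- 10
  G <- matrix(rbinom(N * T, 2, 0.4), N, T)
  Y <- matrix(rnorm(N * T), N, T)
  # gene g1 gets 5 variants, the rest are singleton genes
  meta <- data.frame(gene = c(rep("g1", 5), paste0("g", 2:6)),
                     variant = paste0("v", 1:T))
  ds <- EQTLDataset(expression = Y, dosage = G,
                    individual = paste0("i", 1:N), testMeta = meta)
  ctx <- cbind(context1 = rnorm(N))
  tbl <- testInteractions(ds, ctx)
  g1 <- tbl[tbl$gene == "g1", ]
  expect_equal(unique(g1$gene_p), min(1, 5 * min(g1$p)), tolerance = 1e-12)
  single <- tbl[tbl$gene == "g2", ]
  expect_equal(single$gene_p, single$p, tolerance = 1e-12)
  # matches a looped single-pair oracle
  for (t in c(1, 7)) {
    f <- fitInteractionModel(Y[, t], G[, t], contexts = ctx,
                             individual = paste0("i", 1:N))
    row <- tbl[tbl$variant == paste0("v", t), ]
    expect_equal(row$p, f$interactions$p, tolerance = 1e-12)
    expect_equal(row$beta_interaction, f$interactions$estimate,
                 tolerance = 1e-12)
  }
})

test_that("genotype permutation acts on individuals, uniformly across variants", {
  sim <- simulateEqtlData(simConfig(N = 30, T = 12, K = 1, seed = 56,
                                    nIndividuals = 10))
  ds <- sim$dataset
  pm <- permuteGenotypeByIndividual(ds, seed = 5)
  G <- dosageMatrix(ds)
  ind <- as.integer(individualOf(ds))
  # samples of one individual stay identical at every variant
  for (i in unique(ind)) {
    rows <- which(ind == i)
    for (r in rows[-1])
      expect_identical(unname(pm$Gint[r, ]), unname(pm$Gint[rows[1], ]))
  }
  # the same individual-level permutation at every variant
  rep1 <- match(seq_len(10), ind)
  for (t in c(1, 12))
    expect_identical(unname(pm$Gint[rep1, t]), unname(G[rep1[pm$perm], t]))
  # identity permutation is a fixed point
  pid <- permuteGenotypeByIndividual(ds, perm = seq_len(10))
  expect_identical(pid$Gint, G)
})

test_that("empirical FDR counting matches a direct threshold scan", {
  obs <- data.frame(gene = paste0("g", 1:3), context = "context1",
                    p = c(0.001, 0.2, 0.5))
  perm <- data.frame(gene = paste0("g", 1:3), context = "context1",
                     p = c(0.3, 0.6, 0.9))
  res <- runEfdr(obs, perm, level = 0.05)
  oracle <- efdrScanOracle(obs$p, perm$p, 0.05)
  expect_identical(res@calls$significant, oracle$calls)
  expect_equal(res@thresholds$threshold, oracle$threshold)
  expect_true(all(res@calls$p[res@calls$significant] <=
                    res@thresholds$threshold))

  # exchangeable case: observed equals permuted, nothing can be called
  same <- data.frame(gene = paste0("g", 1:20), context = "context1",
                     p = seq(0.01, 0.95, length.out = 20))
  res0 <- runEfdr(same, same, level = 0.05)
  expect_identical(sum(res0@calls$significant), 0L)

  expect_error(runEfdr(obs, perm[0, ], level = 0.05), "empty permuted")
})

test_that("eFDR calls match the scan oracle on mixtures and nest across levels", {
  set.seed(57)
  obsP <- c(rbeta(60, 0.2, 5), runif(140))   # enriched near zero
  permP <- runif(200)
  obs <- data.frame(gene = paste0("g", 1:200), context = "context1", p = obsP)
  perm <- data.frame(gene = paste0("g", 1:200), context = "context1", p = permP)
  res <- runEfdr(obs, perm, level = 0.05)
  oracle <- efdrScanOracle(obsP, permP, 0.05)
  expect_identical(res@calls$significant, oracle$calls)
  # nesting: calls at a stricter level are a subset
  strict <- runEfdr(obs, perm, level = 0.01)
  expect_true(all(strict@calls$significant <= res@calls$significant))
  # estimated eFDR at the returned threshold is at or below the level
  expect_lte(res@thresholds$efdr, 0.05)

  # all-context mode pools the tables
  obs2 <- rbind(obs, transform(obs, context = "context2", p = runif(200)))
  perm2 <- rbind(perm, transform(perm, context = "context2"))
  pooled <- runEfdr(obs2, perm2, level = 0.05, mode = "all-context")
  oracle2 <- efdrScanOracle(obs2$p, perm2$p, 0.05)
  expect_identical(pooled@calls$significant, oracle2$calls)
})

test_that("expression PCs match an SVD oracle and validate K", {
  set.seed(58)
  # rank-1 expression: PC1 recovers the generating axis
  u <- rnorm(40); v <- rnorm(25)
  Y1 <- u %*% t(v)
  pc <- expressionPcContexts(Y1, 1)
  expect_gt(abs(cor(pc[, 1], u)), 1 - 1e-8)

  Y <- matrix(rnorm(100 * 50), 100, 50)
  K <- 5
  scores <- expressionPcContexts(Y, K)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  sv <- svd(Yc)
  ref <- sv$u[, 1:K] %*% diag(sv$d[1:K])
  for (k in 1:K)
    expect_lt(min(max(abs(scores[, k] - ref[, k])),
                  max(abs(scores[, k] + ref[, k]))), 1e-8)
  expect_error(expressionPcContexts(Y[1:10, 1:20], 10), "exceeds")
})
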