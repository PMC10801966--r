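# Independent oracles. These deliberately avoid the package's vectorized
# code paths: moments come from numeric quadrature and assemblies are plain
# scalar loops.

.quadGaussMoments <- function(m, s2) {
  s <- sqrt(s2)
  lo <- m - 12 * s; hi <- m + 12 * s
  f <- function(g) integrate(g, lo, hi, rel.tol = 1e-12,
                             abs.tol = 1e-14)$value
  dens <- function(x) dnorm(x, m, s)
  E1 <- f(function(x) x * dens(x))
  E2 <- f(function(x) x^2 * dens(x))
  H <- f(function(x) {
    d <- dens(x)
    ifelse(d > 0, -d * log(d), 0)
  })
  list(E1 = E1, E2 = E2, H = H)
}

.quadGammaMoments <- function(a, b) {
  hi <- qgamma(1 - 1e-14, shape = a, rate = b)
  lo <- qgamma(1e-14, shape = a, rate = b)
  f <- function(g) integrate(g, lo, hi, rel.tol = 1e-12,
                             abs.tol = 1e-14)$value
  dens <- function(x) dgamma(x, shape = a, rate = b)
  E <- f(function(x) x * dens(x))
  Elog <- f(function(x) log(x) * dens(x))
  H <- f(function(x) {
    d <- dens(x)
    ifelse(d > 0, -d * log(d), 0)
  })
  list(E = E, Elog = Elog, H = H)
}

# ELBO assembled factor by factor from quadrature moments, scalar loops
# throughout. Matches computeElbo() only if the analytic moment identities
# in the C++ engine are right.
elboQuadratureOracle <- function(state, data, a0 = 1e-3, b0 = 1e-3) {
  N <- data$N; T <- data$T; L <- data$L; I <- data$I
  K <- ncol(state$Umu)
  useAlpha <- data$useAlpha
  l2pi <- log(2 * pi)

  gm <- function(mus, s2s) {
    mus <- as.matrix(mus); s2s <- as.matrix(s2s)
    E1 <- E2 <- H <- matrix(0, nrow(mus), ncol(mus))
    for (i in seq_len(nrow(mus))) for (j in seq_len(ncol(mus))) {
      q <- .quadGaussMoments(mus[i, j], s2s[i, j])
      E1[i, j] <- q$E1; E2[i, j] <- q$E2; H[i, j] <- q$H
    }
    list(E1 = E1, E2 = E2, H = H)
  }
  U <- gm(state$Umu, state$Us2)
  V <- gm(state$Vmu, state$Vs2)
  Ff <- gm(state$Fmu, state$Fs2)
  Mu <- gm(state$mumu, state$mus2)
  W <- if (L > 0) gm(state$Wmu, state$Ws2) else NULL
  A <- if (useAlpha) gm(state$Amu, state$As2) else NULL
  gam <- lapply(seq_len(K), function(k)
    .quadGammaMoments(as.numeric(state$ga)[k], as.numeric(state$gb)[k]))
  sig <- lapply(seq_len(T), function(t)
    .quadGammaMoments(as.numeric(state$sa)[t], as.numeric(state$sb)[t]))
  psi <- if (useAlpha) lapply(seq_len(T), function(t)
    .quadGammaMoments(as.numeric(state$pa)[t], as.numeric(state$pb)[t]))

  elbo <- 0
  for (t in seq_len(T)) {
    for (n in seq_len(N)) {
      i <- data$ind[n]
      mPred <- Mu$E1[t, 1] + data$Gm[n, t] * Ff$E1[t, 1]
      vPred <- (Mu$E2[t, 1] - Mu$E1[t, 1]^2) +
        data$Gm[n, t]^2 * (Ff$E2[t, 1] - Ff$E1[t, 1]^2)
      if (L > 0) for (l in seq_len(L)) {
        mPred <- mPred + data$X[n, l] * W$E1[l, t]
        vPred <- vPred + data$X[n, l]^2 * (W$E2[l, t] - W$E1[l, t]^2)
      }
      if (useAlpha) {
        mPred <- mPred + A$E1[i, t]
        vPred <- vPred + A$E2[i, t] - A$E1[i, t]^2
      }
      for (k in seq_len(K)) {
        mPred <- mPred + data$Gi[n, t] * U$E1[n, k] * V$E1[k, t]
        vPred <- vPred + data$Gi[n, t]^2 *
          (U$E2[n, k] * V$E2[k, t] - (U$E1[n, k] * V$E1[k, t])^2)
      }
      esq <- (data$Y[n, t] - mPred)^2 + vPred
      elbo <- elbo + 0.5 * (sig[[t]]$Elog - l2pi) - 0.5 * sig[[t]]$E * esq
    }
  }
  for (n in seq_len(N)) for (k in seq_len(K))
    elbo <- elbo + 0.5 * (gam[[k]]$Elog - l2pi) - 0.5 * gam[[k]]$E * U$E2[n, k]
  for (k in seq_len(K)) for (t in seq_len(T))
    elbo <- elbo - 0.5 * l2pi - 0.5 * V$E2[k, t]
  for (t in seq_len(T)) {
    elbo <- elbo - 0.5 * l2pi - 0.5 * Ff$E2[t, 1]
    elbo <- elbo - 0.5 * l2pi - 0.5 * Mu$E2[t, 1]
  }
  if (L > 0) for (l in seq_len(L)) for (t in seq_len(T))
    elbo <- elbo - 0.5 * l2pi - 0.5 * W$E2[l, t]
  if (useAlpha) for (i in seq_len(I)) for (t in seq_len(T))
    elbo <- elbo + 0.5 * (psi[[t]]$Elog - l2pi) - 0.5 * psi[[t]]$E * A$E2[i, t]

  gPrior <- function(mom) a0 * log(b0) - lgamma(a0) +
    (a0 - 1) * mom$Elog - b0 * mom$E
  for (k in seq_len(K)) elbo <- elbo + gPrior(gam[[k]])
  for (t in seq_len(T)) elbo <- elbo + gPrior(sig[[t]])
  if (useAlpha) for (t in seq_len(T)) elbo <- elbo + gPrior(psi[[t]])

  ent <- sum(U$H) + sum(V$H) + sum(Ff$H) + sum(Mu$H)
  if (L > 0) ent <- ent + sum(W$H)
  if (useAlpha) ent <- ent + sum(A$H)
  ent <- ent + sum(vapply(gam, `[[`, numeric(1), "H")) +
    sum(vapply(sig, `[[`, numeric(1), "H"))
  if (useAlpha) ent <- ent + sum(vapply(psi, `[[`, numeric(1), "H"))

  elbo + ent
}

# Derivative-free maximization of the ELBO over one scalar latent's
# variational parameters, everything else held fixed.
.optimScalar <- function(state, data, field, idx, kind = c("gauss", "gamma"),
                         a0 = 1e-3, b0 = 1e-3) {
  kind <- match.arg(kind)
  muField <- field[1]; s2Field <- field[2]
  obj <- function(par) {
    st <- state
    m <- as.matrix(st[[muField]]); v <- as.matrix(st[[s2Field]])
    if (kind == "gauss") {
      m[idx[1], idx[2]] <- par[1]
      v[idx[1], idx[2]] <- exp(par[2])
    } else {
      m[idx[1], idx[2]] <- exp(par[1])
      v[idx[1], idx[2]] <- exp(par[2])
    }
    st[[muField]] <- m; st[[s2Field]] <- v
    -computeElbo(st, data, a0, b0)
  }
  m0 <- as.matrix(state[[muField]])[idx[1], idx[2]]
  v0 <- as.matrix(state[[s2Field]])[idx[1], idx[2]]
  start <- if (kind == "gauss") c(m0, log(v0)) else c(log(m0), log(v0))
  fit <- optim(start, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  if (kind == "gauss") c(mean = fit$par[1], s2 = exp(fit$par[2]))
  else c(shape = exp(fit$par[1]), rate = exp(fit$par[2]))
}

# Numeric block oracle: optimize every scalar of a block independently from
# the same starting state (valid when the block has no internal likelihood
# coupling, which holds for the instances used: K = 1, L = 1).
numericBlockOptimum <- function(state, data, block, a0 = 1e-3, b0 = 1e-3) {
  dims <- list(
    V = c("Vmu", "Vs2"), F = c("Fmu", "Fs2"), mu = c("mumu", "mus2"),
    W = c("Wmu", "Ws2"), alpha = c("Amu", "As2"), U = c("Umu", "Us2"),
    gamma = c("ga", "gb"), psi = c("pa", "pb"), sigma = c("sa", "sb"))
  fields <- dims[[block]]
  kind <- if (block %in% c("gamma", "psi", "sigma")) "gamma" else "gauss"
  m <- as.matrix(state[[fields[1]]])
  out1 <- matrix(NA_real_, nrow(m), ncol(m))
  out2 <- matrix(NA_real_, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    r <- .optimScalar(state, data, fields, c(i, j), kind, a0, b0)
    out1[i, j] <- r[1]; out2[i, j] <- r[2]
  }
  list(par1 = out1, par2 = out2)
}

# Greedy reference implementation of representative-pair selection.
greedySelectOracle <- function(tbl, fdrCut, maxTests) {
  sig <- tbl[tbl$q <= fdrCut, , drop = FALSE]
  geneP <- tapply(sig$gene_p, sig$gene, min)
  genes <- names(sort(geneP))
  ord <- order(geneP[genes], genes)
  genes <- genes[ord][seq_len(min(maxTests, length(genes)))]
  used <- character(); res <- NULL
  for (g in genes) {
    sub <- sig[sig$gene == g, ]
    sub <- sub[order(sub$p_nominal, sub$variant), ]
    v <- sub$variant[1]
    if (v %in% used) next
    used <- c(used, v)
    res <- rbind(res, data.frame(gene = g, variant = v))
  }
  res
}

# Exhaustive threshold-scan reference for the empirical FDR.
efdrScanOracle <- function(obsP, permP, level) {
  cand <- sort(unique(obsP))
  raw <- vapply(cand, function(p) sum(permP <= p) / sum(obsP <= p), numeric(1))
  adj <- vapply(seq_along(cand), function(i) min(raw[i:length(raw)]), numeric(1))
  pass <- cand[adj <= level]
  thr <- if (length(pass)) max(pass) else NA_real_
  list(threshold = thr,
       calls = if (is.na(thr)) logical(length(obsP)) else obsP <= thr)
}
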