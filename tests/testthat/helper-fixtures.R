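# Small programmatic fixtures shared across test files.

# A tiny preprocessed dataset plus model-ready data list and an initial
# variational state, for engine-level tests.
makeTinyModel <- function(N = 8, T = 5, K = 1, L = 1, I = N, seed = 42,
                          useRandomIntercept = NA, iterations = 0) {
  set.seed(seed)
  ind <- rep_len(seq_len(I), N)
  G <- matrix(rbinom(N * T, 2, 0.4), N, T)
  Y <- matrix(rnorm(N * T), N, T)
  X <- if (L > 0) matrix(rnorm(N * L), N, L) else NULL
  Ystd <- apply(Y, 2, standardizeExpression)
  # redraw dosage columns whose ratio scaling is degenerate at tiny N
  Gstd <- matrix(0, N, T)
  for (t in seq_len(T)) {
    repeat {
      g <- tryCatch(standardizeGenotype(G[, t], Ystd[, t]),
                    error = function(e) NULL)
      if (!is.null(g)) break
      G[, t] <- rbinom(N, 2, 0.4)
    }
    Gstd[, t] <- g
  }
  ds <- EQTLDataset(expression = Ystd, dosage = Gstd, covariates = X,
                    individual = paste0("ind", ind), preprocessed = TRUE)
  data <- surgeModelData(ds, useRandomIntercept = useRandomIntercept)
  state <- initSurgeState(data, K, seed = seed + 1)
  for (i in seq_len(iterations)) state <- caviIteration(state, data)
  list(dataset = ds, data = data, state = state, rawG = G)
}

# Simulated dataset preprocessed and ready to fit.
makeSimFit <- function(N, T, K, gamma, p, seed, nIndividuals = N) {
  sim <- simulateEqtlData(simConfig(N = N, T = T, K = K, gamma = gamma,
                                    p = p, nIndividuals = nIndividuals,
                                    seed = seed))
  list(sim = sim, dataset = preprocessDataset(sim$dataset))
}

# Write a dataset's four input files as TSV, optionally shuffling the sample
# order of individual files (alignment tests).
writeDatasetFiles <- function(dir, Y, G, X, individual,
                              shuffleGeno = FALSE, shuffleCovar = FALSE,
                              dropGenoSample = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- rownames(Y)
  write1 <- function(m, path) {
    df <- data.frame(test_id = colnames(m), check.names = FALSE)
    df[rownames(m)] <- as.data.frame(t(m))
    con <- file(path, "wt")
    on.exit(close(con))
    write.table(format(df, digits = 17, trim = TRUE), con, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write1(Y, file.path(dir, "expr.tsv"))
  gOrder <- if (shuffleGeno) rev(samples) else samples
  Gout <- G[gOrder, , drop = FALSE]
  if (!is.null(dropGenoSample))
    Gout <- Gout[setdiff(rownames(Gout), dropGenoSample), , drop = FALSE]
  write1(Gout, file.path(dir, "geno.tsv"))
  if (!is.null(X)) {
    xOrder <- if (shuffleCovar) sample(samples) else samples
    write1(X[xOrder, , drop = FALSE], file.path(dir, "covar.tsv"))
  }
  write.table(data.frame(sample_id = samples, individual_id = individual),
              file.path(dir, "map.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  dir
}
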