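test_that("predicted effect size and context grid follow their definitions", {
  expect_identical(predictedEffect(0.5, 0.2, -1), 0.3)
  expect_identical(predictedEffect(0.7, 0.4, 0), 0.7)
  set.seed(61)
  b <- rnorm(20); bx <- rnorm(20); u <- rnorm(20)
  expect_identical(predictedEffect(b, bx, u), b + u * bx)

  g <- contextGrid(c(-2, 0.5, 2), nPoints = 200)
  expect_identical(g[1], -2)
  expect_identical(g[200], 2)
  expect_equal(unique(round(diff(g), 12)), round(4 / 199, 12))
  expect_identical(contextGrid(c(1, 5), nPoints = 2), c(1, 5))
  u2 <- rnorm(30)
  expect_equal(contextGrid(u2, 17),
               seq(min(u2), max(u2), length.out = 17), tolerance = 1e-14)
  expect_error(contextGrid(rep(1, 5)), "constant")
})

test_that("annotations sum squared predicted effects over mapped genes", {
  fits <- data.frame(gene = c("a", "b"), variant = c("v1", "v1"),
                     beta_g = c(0.3, 0.4), beta_gx = c(0, 0))
  map <- data.frame(variant = c("v1", "v1"), gene = c("a", "b"))
  ann <- buildAnnotation(fits, map, uStar = 0, variants = c("v1", "v2"))
  expect_equal(unname(ann), c(0.09 + 0.16, 0))  # v2 maps to nothing

  # missing fit for a mapped pair is an error
  expect_error(buildAnnotation(fits, rbind(map, data.frame(variant = "v9",
                                                           gene = "a")), 0),
               "v9")

  # brute-force double-loop oracle on a random map
  set.seed(62)
  fits2 <- expand.grid(gene = paste0("g", 1:10), variant = paste0("v", 1:50),
                       stringsAsFactors = FALSE)
  fits2$beta_g <- rnorm(nrow(fits2))
  fits2$beta_gx <- rnorm(nrow(fits2))
  map2 <- fits2[sample(nrow(fits2), 120), c("variant", "gene")]
  map2 <- unique(map2)
  uStar <- 0.7
  ann2 <- buildAnnotation(fits2, map2, uStar)
  for (v in names(ann2)) {
    rows <- map2[map2$variant == v, ]
    tot <- 0
    for (r in seq_len(nrow(rows))) {
      f <- fits2[fits2$variant == v & fits2$gene == rows$gene[r], ]
      tot <- tot + (f$beta_g + uStar * f$beta_gx)^2
    }
    expect_equal(unname(ann2[v]), tot, tolerance = 1e-12)
  }
  expect_true(all(ann2 >= 0))
})

test_that(".annot files round-trip and parse with an independent reader", {
  meta <- data.frame(chr = c(1, 1, 2), bp = c(100L, 200L, 300L),
                     snp = c("rs1", "rs2", "rs3"), cm = c(0, 0.1, 0.2))
  ann <- c(0.25, 0, 1.5e-3)
  tf <- withr::local_tempfile(fileext = ".annot")
  writeAnnot(ann, meta, tf, name = "ctx1_grid007")
  back <- readAnnot(tf)
  expect_identical(colnames(back), c("CHR", "BP", "SNP", "CM", "ctx1_grid007"))
  expect_equal(back$ctx1_grid007, ann, tolerance = 1e-14)
  expect_identical(nrow(back), 3L)

  # minimal independent parser: raw line splitting
  lines <- readLines(tf)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  expect_identical(length(hdr), 5L)
  vals <- vapply(lines[-1], function(l)
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]][5]), numeric(1),
    USE.NAMES = FALSE)
  expect_equal(vals, ann, tolerance = 1e-12)

  # gzip variant
  tgz <- withr::local_tempfile(fileext = ".annot.gz")
  writeAnnot(ann, meta, tgz)
  expect_equal(readAnnot(tgz)$ANNOT, ann, tolerance = 1e-12)

  expect_error(writeAnnot(ann[1:2], meta, tf), "lengths differ")
})

test_that("grid annotations are flat exactly for non-interacting genes", {
  # genes with beta_gx = 0 give a constant annotation along the grid equal
  # to the squared static effect; interacting genes vary
  fits <- data.frame(gene = c("flat", "inter"), variant = c("v1", "v2"),
                     beta_g = c(0.5, 0.5), beta_gx = c(0, 0.6))
  map <- data.frame(variant = c("v1", "v2"), gene = c("flat", "inter"))
  u <- seq(-2, 2, length.out = 50)
  grid <- contextGrid(u, 9)
  flat <- vapply(grid, function(us)
    buildAnnotation(fits, map, us)[["v1"]], numeric(1))
  inter <- vapply(grid, function(us)
    buildAnnotation(fits, map, us)[["v2"]], numeric(1))
  expect_true(all(abs(flat - 0.25) < 1e-14))
  expect_gt(max(inter) / min(inter), 2)
})

test_that("annotation varies along the grid for true interaction eQTLs", {
  # one strong simulated context: interacting tests show >2x grid variation
  # on average, non-interacting tests stay nearly flat
  m <- makeSimFit(N = 300, T = 40, K = 1, gamma = 1, p = 0.5, seed = 63)
  ds <- m$dataset
  u <- m$sim$truth$U[, 1]
  Y <- exprMatrix(ds); G <- dosageMatrix(ds)
  meta <- as.data.frame(testMeta(ds))
  fits <- do.call(rbind, lapply(seq_len(ncol(Y)), function(t) {
    f <- fitInteractionModel(Y[, t], G[, t], contexts = cbind(u),
                             individual = individualOf(ds))
    data.frame(gene = meta$gene[t], variant = meta$variant[t],
               beta_g = f$coefficients$estimate[f$coefficients$term == "g"],
               beta_gx = f$interactions$estimate)
  }))
  map <- meta[, c("variant", "gene")]
  grid <- contextGrid(u, 21)
  annGrid <- vapply(grid, function(us)
    buildAnnotation(fits, map, us, variants = meta$variant),
    numeric(nrow(meta)))
  ratio <- apply(annGrid, 1, function(a) max(a) / max(min(a), 1e-12))
  active <- m$sim$truth$theta[1, ] == 1
  expect_gt(mean(ratio[active] > 2), 0.5)
  expect_gt(mean(ratio[active]), 2)
  expect_lt(median(ratio[!active]), mean(ratio[active]))
  expect_true(all(annGrid >= 0))
})

test_that("annotateAcrossGrid writes one file per grid point plus an index", {
  fits <- data.frame(gene = "a", variant = "v1", beta_g = 0.2, beta_gx = 0.3)
  map <- data.frame(variant = "v1", gene = "a")
  meta <- data.frame(chr = 1, bp = 10L, snp = "v1", cm = 0)
  dir <- withr::local_tempdir()
  idx <- annotateAcrossGrid(fits, map, uColumn = c(-1, 0, 2), variantMeta = meta,
                            dir = dir, nPoints = 5)
  expect_identical(nrow(idx), 5L)
  expect_true(all(file.exists(file.path(dir, idx$file))))
  a3 <- readAnnot(file.path(dir, idx$file[3]))
  expect_equal(a3[[5]], (0.2 + idx$u_star[3] * 0.3)^2, tolerance = 1e-12)
})
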