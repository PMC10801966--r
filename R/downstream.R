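#' Expected eQTL effect size at a latent-context value
#'
#' `beta* = beta_g + u* x beta_gxk`: the expected genotype effect on
#' expression for a variant-gene pair when the k-th latent context takes the
#' value `u*`, using the joint interaction fit's estimates as plug-ins.
#'
#' @param betaG estimated genotype main effect.
#' @param betaGx estimated genotype-by-context interaction effect for the
#'   chosen context.
#' @param uStar latent-context value.
#' @return predicted effect size (vectorized over inputs).
#' @examples
#' predictedEffect(0.5, 0.2, -1)  # 0.3
#' @export
predictedEffect <- function(betaG, betaGx, uStar) {
  betaG + uStar * betaGx
}

#' Equally spaced grid over a latent context's range
#'
#' @param uColumn numeric vector of latent-context values (non-constant).
#' @param nPoints number of grid positions (at least 2).
#' @return numeric vector from `min(uColumn)` to `max(uColumn)` inclusive
#'   with spacing `(max - min) / (nPoints - 1)`.
#' @examples
#' contextGrid(c(-2, 0.3, 2), nPoints = 5)
#' @export
contextGrid <- function(uColumn, nPoints = 200L) {
  if (nPoints < 2) stop("nPoints must be at least 2")
  lo <- min(uColumn); hi <- max(uColumn)
  if (hi - lo <= 0) stop("constant context column: grid undefined")
  seq(lo, hi, length.out = nPoints)
}

#' Per-variant squared expected effect-size annotation
#'
#' For each variant, sums the squared expected eQTL effect size
#' `predictedEffect(beta_g, beta_gxk, uStar)^2` over every gene the variant
#' maps to; variants mapping to no gene get 0. This is the annotation value
#' consumed by stratified LD-score regression at one latent-context grid
#' position.
#'
#' @param fits data.frame with one row per (gene, variant) pair and columns
#'   `gene`, `variant`, `beta_g`, `beta_gx` (interaction effect for the
#'   chosen context).
#' @param variantGeneMap data.frame with columns `variant`, `gene` listing
#'   which genes each variant maps to (many-to-many).
#' @param uStar latent-context value at which to evaluate.
#' @param variants character vector of variants defining the output order;
#'   defaults to the unique variants of the map.
#' @return named numeric vector of annotation values, one per variant.
#' @examples
#' fits <- data.frame(gene = c("a", "b"), variant = "v1",
#'                    beta_g = c(0.3, 0.4), beta_gx = 0)
#' buildAnnotation(fits, data.frame(variant = "v1", gene = c("a", "b")), 0)
#' @export
buildAnnotation <- function(fits, variantGeneMap, uStar, variants = NULL) {
  need <- c("gene", "variant", "beta_g", "beta_gx")
  if (!all(need %in% colnames(fits)))
    stop("fits must have columns ", paste(need, collapse = ", "))
  if (!all(c("variant", "gene") %in% colnames(variantGeneMap)))
    stop("variantGeneMap must have columns variant, gene")
  if (is.null(variants)) variants <- unique(variantGeneMap$variant)
  key <- paste(fits$variant, fits$gene, sep = "\r")
  mapKey <- paste(variantGeneMap$variant, variantGeneMap$gene, sep = "\r")
  hit <- match(mapKey, key)
  if (anyNA(hit)) {
    bad <- which(is.na(hit))[1]
    stop(sprintf("no interaction fit for mapped pair (variant %s, gene %s)",
                 variantGeneMap$variant[bad], variantGeneMap$gene[bad]))
  }
  bStar <- predictedEffect(fits$beta_g[hit], fits$beta_gx[hit], uStar)
  perVariant <- tapply(bStar^2, variantGeneMap$variant, sum)
  out <- setNames(rep(0, length(variants)), variants)
  shared <- intersect(variants, names(perVariant))
  out[shared] <- as.numeric(perVariant[shared])
  out
}

#' Write a per-variant annotation in LDSC .annot layout
#'
#' Tab-separated with header `CHR BP SNP CM <name>` and one row per variant.
#' A `.gz` path is compressed transparently.
#'
#' @param annotation numeric vector of annotation values.
#' @param variantMeta data.frame with columns `chr`, `bp`, `snp`, `cm`,
#'   aligned with `annotation`.
#' @param path output path (gzip when it ends in `.gz`).
#' @param name annotation column name.
#' @return `path`, invisibly.
#' @export
writeAnnot <- function(annotation, variantMeta, path, name = "ANNOT") {
  if (!all(c("chr", "bp", "snp", "cm") %in% colnames(variantMeta)))
    stop("variantMeta must have columns chr, bp, snp, cm")
  if (length(annotation) != nrow(variantMeta))
    stop("annotation and variantMeta lengths differ")
  df <- data.frame(CHR = variantMeta$chr, BP = variantMeta$bp,
                   SNP = variantMeta$snp, CM = variantMeta$cm)
  df[[name]] <- sprintf("%.17g", as.numeric(annotation))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' @rdname writeAnnot
#' @export
readAnnot <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
}

#' Annotations along a latent-context grid
#'
#' Builds the annotation of [buildAnnotation()] at `nPoints` equally spaced
#' positions along the observed range of one latent context and writes one
#' .annot file per grid position plus an index of grid values.
#'
#' @param fits see [buildAnnotation()].
#' @param variantGeneMap see [buildAnnotation()].
#' @param uColumn latent-context values across samples (defines the grid
#'   range).
#' @param variantMeta see [writeAnnot()]; row order defines variant order.
#' @param dir output directory.
#' @param nPoints grid size.
#' @param gzip write .annot.gz instead of .annot.
#' @return data.frame index with columns `position`, `u_star`, `file`,
#'   invisibly written to `grid_index.tsv` in `dir`.
#' @export
annotateAcrossGrid <- function(fits, variantGeneMap, uColumn, variantMeta,
                               dir, nPoints = 200L, gzip = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  grid <- contextGrid(uColumn, nPoints)
  ext <- if (gzip) ".annot.gz" else ".annot"
  files <- sprintf("grid_%03d%s", seq_along(grid), ext)
  for (i in seq_along(grid)) {
    ann <- buildAnnotation(fits, variantGeneMap, grid[i],
                           variants = variantMeta$snp)
    writeAnnot(ann, variantMeta, file.path(dir, files[i]))
  }
  idx <- data.frame(position = seq_along(grid), u_star = grid, file = files)
  writeResultTable(idx, file.path(dir, "grid_index.tsv"))
  invisible(idx)
}
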