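#' Write and read result tables and matrices as TSV
#'
#' All package outputs are tab-delimited text with a header row. Numeric
#' columns are written with 17 significant digits so a write-read round trip
#' reproduces every value to better than 1e-12.
#'
#' `writeResultTable` handles data.frames (and `DataFrame`s); matrices go
#' through `writeMatrixTsv`, which stores row names in a leading `id` column.
#'
#' @param x data.frame (or S4Vectors `DataFrame`) to write.
#' @param path output file path.
#' @return `writeResultTable`/`writeMatrixTsv` return `path` invisibly;
#'   readers return a data.frame or matrix.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeResultTable(data.frame(gene = "g1", p = 0.012345), tf)
#' readResultTable(tf)
#' @export
writeResultTable <- function(x, path) {
  if (is(x, "DataFrame")) x <- as.data.frame(x)
  if (!is.data.frame(x)) stop("writeResultTable expects a data.frame")
  out <- x
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' @rdname writeResultTable
#' @export
readResultTable <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
}

#' @rdname writeResultTable
#' @export
writeMatrixTsv <- function(x, path) {
  x <- as.matrix(x)
  if (is.null(dimnames(x))) dimnames(x) <- list(NULL, NULL)
  if (is.null(rownames(x)) && nrow(x) > 0)
    rownames(x) <- paste0("row", seq_len(nrow(x)))
  if (is.null(colnames(x)) && ncol(x) > 0)
    colnames(x) <- paste0("col", seq_len(ncol(x)))
  df <- data.frame(id = rownames(x), check.names = FALSE)
  df[colnames(x)] <- as.data.frame(x, optional = TRUE)
  writeResultTable(df, path)
}

#' @rdname writeResultTable
#' @export
readMatrixTsv <- function(path) {
  df <- readResultTable(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write a fitted model's factor matrices and diagnostics to a directory
#'
#' Writes `U.tsv` (retained posterior-mean context loadings), `V.tsv`
#' (context-specific effects), `F.tsv` (shared effects), `pve.tsv` (per
#' retained context PVE and PSMVE) and `elbo_trace.tsv`.
#'
#' @param fit a [SurgeFit-class].
#' @param dir output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
writeSurgeFit <- function(fit, dir) {
  stopifnot(is(fit, "SurgeFit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeMatrixTsv(fit@U, file.path(dir, "U.tsv"))
  writeMatrixTsv(fit@V, file.path(dir, "V.tsv"))
  writeResultTable(data.frame(test = names(fit@F), F = as.numeric(fit@F)),
                   file.path(dir, "F.tsv"))
  writeResultTable(
    data.frame(context = colnames(fit@U), pve = fit@pve, psmve = fit@psmve),
    file.path(dir, "pve.tsv"))
  writeResultTable(
    data.frame(iteration = seq_along(fit@elboTrace), elbo = fit@elboTrace),
    file.path(dir, "elbo_trace.tsv"))
  invisible(dir)
}

#' Write a JSON provenance sidecar for a pipeline run
#'
#' Records the configuration, seed and package version next to a result file
#' so every run is reproducible from its outputs alone.
#'
#' @param path path of the result the sidecar describes; the sidecar is
#'   written to `<path>.provenance.json`.
#' @param config named list of configuration values (must include `seed` when
#'   randomness is involved).
#' @return sidecar path, invisibly.
#' @export
writeProvenance <- function(path, config) {
  sidecar <- paste0(path, ".provenance.json")
  payload <- list(
    package = "surgelite",
    version = as.character(utils::packageVersion("surgelite")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config
  )
  jsonlite::write_json(payload, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(sidecar)
}
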