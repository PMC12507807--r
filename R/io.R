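#' Read a 10x-style Matrix Market count directory
#'
#' Expects \code{matrix.mtx}, \code{features.tsv} (gene id and optionally
#' symbol columns) and \code{barcodes.tsv}, each optionally gzipped.
#' Gene identifiers are taken from the symbol column when present (second
#' column), falling back to the id column; duplicates are made unique with
#' \code{make.unique}.
#'
#' @param dir Directory containing the triplet.
#' @param mito_prefix Prefix marking mitochondrial gene symbols
#'   (case-insensitive; default the mouse \code{"mt-"}).
#' @return A \code{\link{count_matrix}}.
#' @export
read_10x_counts <- function(dir, mito_prefix = "mt-") {
  find1 <- function(base) {
    for (f in file.path(dir, c(base, paste0(base, ".gz"))))
      if (file.exists(f)) return(f)
    stop("missing input file: ", file.path(dir, base), "[.gz]")
  }
  m <- Matrix::readMM(find1("matrix.mtx"))
  feats <- utils::read.table(find1("features.tsv"), sep = "\t",
                             stringsAsFactors = FALSE, quote = "",
                             comment.char = "")
  barcodes <- utils::read.table(find1("barcodes.tsv"), sep = "\t",
                                stringsAsFactors = FALSE, quote = "",
                                comment.char = "")[, 1]
  symbols <- if (ncol(feats) >= 2) feats[, 2] else feats[, 1]
  gene_ids <- make.unique(as.character(symbols))
  count_matrix(m, gene_ids, as.character(barcodes),
               mito_mask = grepl(paste0("^", mito_prefix), gene_ids,
                                 ignore.case = TRUE))
}

#' Read a dense CSV/TSV count matrix
#'
#' Genes in rows (first column = gene id), cells in columns (header row =
#' cell ids).
#'
#' @param path File path; delimiter inferred from the extension
#'   (\code{.csv} vs anything else = tab).
#' @param mito_prefix Prefix marking mitochondrial genes.
#' @return A \code{\link{count_matrix}}.
#' @export
read_dense_counts <- function(path, mito_prefix = "mt-") {
  if (!file.exists(path)) stop("missing input file: ", path)
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                          check.names = FALSE, quote = "", comment.char = "")
  m <- as.matrix(df)
  count_matrix(m, rownames(df), colnames(df),
               mito_mask = grepl(paste0("^", mito_prefix), rownames(df),
                                 ignore.case = TRUE))
}

#' Write a count matrix as a 10x-style Matrix Market triplet
#'
#' @param counts A \code{\link{count_matrix}}.
#' @param dir Output directory (created if absent). Writes
#'   \code{matrix.mtx}, \code{features.tsv}, \code{barcodes.tsv}
#'   (uncompressed).
#' @return Invisibly, the vector of files written.
#' @export
write_10x_counts <- function(counts, dir) {
  stopifnot(inherits(counts, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(counts$values, mtx)
  feats <- file.path(dir, "features.tsv")
  utils::write.table(
    data.frame(id = counts$gene_ids, symbol = counts$gene_ids,
               type = "Gene Expression"),
    feats, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  bars <- file.path(dir, "barcodes.tsv")
  utils::write.table(data.frame(counts$cell_ids), bars, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(mtx, feats, bars))
}
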