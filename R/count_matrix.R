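#' Construct a gene-by-cell count matrix
#'
#' Container for raw UMI counts with gene/cell identifiers and a per-gene
#' mitochondrial flag. Counts are stored as a sparse \code{dgCMatrix}
#' (genes in rows, cells in columns).
#'
#' @param values Non-negative integer matrix (dense or sparse), genes x cells.
#' @param gene_ids Character vector of unique gene identifiers, one per row.
#' @param cell_ids Character vector of unique cell barcodes, one per column.
#' @param mito_mask Optional logical vector flagging mitochondrial genes. If
#'   \code{NULL}, genes whose id starts with \code{"mt-"} (case-insensitive,
#'   the mouse convention) are flagged.
#'
#' @return An object of class \code{count_matrix} with elements
#'   \code{values}, \code{gene_ids}, \code{cell_ids}, \code{mito_mask}.
#' @export
count_matrix <- function(values, gene_ids, cell_ids, mito_mask = NULL) {
  if (is.matrix(values)) storage.mode(values) <- "double"
  values <- methods::as(Matrix::Matrix(values, sparse = TRUE),
                        "CsparseMatrix")
  if (nrow(values) != length(gene_ids))
    stop("gene_ids length (", length(gene_ids),
         ") does not match row count (", nrow(values), ")")
  if (ncol(values) != length(cell_ids))
    stop("cell_ids length (", length(cell_ids),
         ") does not match column count (", ncol(values), ")")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids")
  x <- values@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    stop("counts must be non-negative integers")
  if (is.null(mito_mask)) {
    mito_mask <- grepl("^mt-", gene_ids, ignore.case = TRUE)
  } else {
    mito_mask <- as.logical(mito_mask)
    if (length(mito_mask) != length(gene_ids))
      stop("mito_mask length does not match gene count")
    if (anyNA(mito_mask)) stop("mito_mask contains NA")
  }
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(
    list(values = values, gene_ids = as.character(gene_ids),
         cell_ids = as.character(cell_ids), mito_mask = mito_mask),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", length(x$gene_ids), " genes x ", length(x$cell_ids),
      " cells (", sum(x$mito_mask), " mitochondrial genes)\n", sep = "")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Construct a cell embedding
#'
#' A cells-by-d coordinate matrix (typically PCA scores) on which distances
#' and silhouettes are computed.
#'
#' @param coords Numeric matrix, cells in rows.
#' @param cell_ids Character vector aligned to rows.
#' @return An object of class \code{cell_embedding}.
#' @export
cell_embedding <- function(coords, cell_ids) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) != length(cell_ids))
    stop("cell_ids length does not match row count")
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids")
  if (!all(is.finite(coords))) stop("embedding contains non-finite values")
  if (ncol(coords) < 1L) stop("embedding must have at least one dimension")
  rownames(coords) <- cell_ids
  structure(list(coords = coords, cell_ids = as.character(cell_ids),
                 d = ncol(coords)),
            class = "cell_embedding")
}

#' Construct a cluster partition
#'
#' A labeling of cells into clusters, with provenance. Labels are stored as
#' contiguous integers \code{0..k-1}.
#'
#' @param labels Integer-valued cluster id per cell.
#' @param cell_ids Character vector aligned to \code{labels}.
#' @param resolution Resolution parameter that produced the partition
#'   (\code{NA} for externally supplied labelings).
#' @param seed RNG seed used, if any.
#' @param algorithm \code{"leiden"}, \code{"louvain"}, or \code{"external"}.
#' @return An object of class \code{cell_partition} with fields \code{labels},
#'   \code{cell_ids}, \code{resolution}, \code{seed}, \code{algorithm},
#'   \code{k}.
#' @export
cell_partition <- function(labels, cell_ids, resolution = NA_real_,
                           seed = NA_integer_, algorithm = "external") {
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("labels contain NA")
  if (length(labels) != length(cell_ids))
    stop("labels length does not match cell_ids length")
  uniq <- sort(unique(labels))
  k <- length(uniq)
  if (!identical(uniq, seq_len(k) - 1L)) {
    # relabel to contiguous 0..k-1 preserving order of ids
    labels <- match(labels, uniq) - 1L
  }
  structure(list(labels = labels, cell_ids = as.character(cell_ids),
                 resolution = resolution, seed = seed,
                 algorithm = algorithm, k = k),
            class = "cell_partition")
}

#' @export
print.cell_partition <- function(x, ...) {
  cat("cell_partition: ", length(x$labels), " cells, k = ", x$k,
      " (algorithm = ", x$algorithm, ", resolution = ",
      format(x$resolution), ")\n", sep = "")
  invisible(x)
}

# Align a partition to an embedding on cell ids; error on mismatch.
align_partition <- function(embedding, partition) {
  if (!identical(embedding$cell_ids, partition$cell_ids)) {
    if (!setequal(embedding$cell_ids, partition$cell_ids))
      stop("cell ids of embedding and partition do not match")
    idx <- match(embedding$cell_ids, partition$cell_ids)
    partition$labels <- partition$labels[idx]
    partition$cell_ids <- partition$cell_ids[idx]
  }
  partition
}
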