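#' Read a marker table
#'
#' A marker table maps cell-type names to ordered lists of marker gene
#' symbols. The TSV format has columns \code{cell_type} and \code{markers}
#' (comma-separated symbols); lines starting with \code{#} are comments.
#'
#' @param path TSV path. The default is the packaged mouse skin wound
#'   panel (see \code{\link{default_marker_table}}).
#' @return An object of class \code{marker_table}: named list of character
#'   vectors, in table order.
#' @export
read_marker_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("cell_type", "markers") %in% names(df)))
    stop("marker table must have columns cell_type, markers")
  entries <- lapply(strsplit(df$markers, ","), trimws)
  names(entries) <- df$cell_type
  marker_table(entries)
}

#' Construct a marker table from a named list
#'
#' @param entries Named list: cell-type name -> character vector of marker
#'   gene symbols. Names must be unique and no marker list may be empty.
#' @return A \code{marker_table}.
#' @export
marker_table <- function(entries) {
  if (!length(entries) || is.null(names(entries)))
    stop("marker table needs named entries")
  if (anyDuplicated(names(entries))) stop("cell-type names must be unique")
  if (any(vapply(entries, length, 1L) == 0L) ||
      any(vapply(entries, function(e) any(!nzchar(e)), TRUE)))
    stop("every cell type needs at least one non-empty marker symbol")
  structure(entries, class = "marker_table")
}

#' The packaged mouse skin wound-healing marker panel
#'
#' Canonical marker genes for the cell types of mouse skin during wound
#' healing (fibroblast and keratinocyte subsets, T-cell states, myeloid
#' populations, endothelium, muscle, melanocytes). Two hair-follicle
#' keratinocyte entries are published under the same name with different
#' markers; they are kept as distinct entries disambiguated by their
#' marker gene.
#'
#' @return A \code{marker_table}.
#' @export
default_marker_table <- function() {
  read_marker_table(system.file("extdata", "mouse_skin_markers.tsv",
                                package = "silsweep", mustWork = TRUE))
}

#' Score clusters against a marker table and assign cell types
#'
#' For each marker gene present in the data, the cluster-mean expression is
#' z-scored across clusters; the score of (cluster, type) is the mean
#' z-score over that type's present markers. Each cluster is assigned the
#' argmax type, with ties broken by marker-table order. Markers absent from
#' the matrix are excluded and reflected in the coverage fraction.
#'
#' This numeric score is this package's formalization of the common visual
#' feature-plot annotation workflow; it is intentionally simple and can be
#' replaced by any clusters x types scoring function upstream of the
#' argmax.
#'
#' @param norm Genes x cells matrix of log-normalized expression.
#' @param partition A \code{\link{cell_partition}} aligned to the columns.
#' @param markers A \code{\link{marker_table}}.
#' @return An object of class \code{annotation_result}: list with
#'   \code{score_matrix} (clusters x types), \code{assignment} (named
#'   character vector, one type per cluster), \code{coverage}
#'   (clusters x types fraction of markers present in the data), and
#'   \code{missing_markers}.
#' @export
score_clusters <- function(norm, partition, markers) {
  stopifnot(inherits(partition, "cell_partition"),
            inherits(markers, "marker_table"))
  if (ncol(norm) != length(partition$labels))
    stop("partition not aligned to matrix columns")
  genes <- rownames(norm)
  if (is.null(genes)) stop("matrix must have gene row names")
  k <- partition$k
  # cluster-mean expression per gene
  Z <- Matrix::sparseMatrix(i = seq_len(ncol(norm)),
                            j = partition$labels + 1L, x = 1,
                            dims = c(ncol(norm), k))
  sizes <- tabulate(partition$labels + 1L, nbins = k)
  cm <- as.matrix(norm %*% Z) %*% diag(1 / sizes, k)

  match_markers <- function(syms) {
    idx <- match(syms, genes)            # exact, case-sensitive first
    miss <- which(is.na(idx))
    if (length(miss)) {
      ci <- match(tolower(syms[miss]), tolower(genes))
      hit <- !is.na(ci)
      if (any(hit)) {
        warning("marker symbol(s) matched case-insensitively: ",
                paste(syms[miss][hit], collapse = ", "))
        idx[miss[hit]] <- ci[hit]
      }
    }
    idx
  }

  types <- names(markers)
  score <- matrix(NA_real_, k, length(types),
                  dimnames = list(paste0("cluster", seq_len(k) - 1L), types))
  coverage <- matrix(0, k, length(types), dimnames = dimnames(score))
  missing <- list()
  for (t in seq_along(types)) {
    idx <- match_markers(markers[[t]])
    present <- !is.na(idx)
    coverage[, t] <- mean(present)
    if (any(!present)) missing[[types[t]]] <- markers[[t]][!present]
    if (!any(present)) { score[, t] <- -Inf; next }
    zs <- vapply(idx[present], function(g) {
      v <- cm[g, ]
      sdv <- stats::sd(v)
      if (is.na(sdv) || sdv == 0) rep(0, k) else (v - mean(v)) / sdv
    }, numeric(k))
    zs <- matrix(zs, nrow = k)
    score[, t] <- rowMeans(zs)
  }
  if (all(!is.finite(score)))
    stop("marker table disjoint from data")
  assignment <- types[apply(score, 1L, which.max)]  # first max = table order
  names(assignment) <- rownames(score)
  structure(list(score_matrix = score, assignment = assignment,
                 coverage = coverage, missing_markers = missing),
            class = "annotation_result")
}

#' Long-form feature-plot data
#'
#' One row per (cell, requested-and-present gene) with the cell's 2-D
#' layout coordinates and its normalized expression of the gene, ready for
#' any plotting layer. Rows are ordered by cell, then by requested gene
#' order. Requested genes absent from the matrix yield no rows and a
#' warning.
#'
#' @param norm Genes x cells matrix of log-normalized expression.
#' @param embedding2d A 2-D \code{\link{cell_embedding}} (e.g. UMAP or the
#'   first two PCs) aligned to the columns.
#' @param genes Character vector of gene symbols to extract.
#' @return A data frame with columns \code{cell_id}, \code{x}, \code{y},
#'   \code{gene}, \code{value}.
#' @export
feature_plot_data <- function(norm, embedding2d, genes) {
  stopifnot(inherits(embedding2d, "cell_embedding"))
  if (embedding2d$d != 2L) stop("feature plots need a 2-D embedding")
  if (!identical(colnames(norm), embedding2d$cell_ids))
    stop("matrix columns and embedding cell ids do not match")
  present <- genes[genes %in% rownames(norm)]
  absent <- setdiff(genes, present)
  if (length(absent))
    warning("requested gene(s) absent from matrix: ",
            paste(absent, collapse = ", "))
  n <- ncol(norm)
  out <- data.frame(
    cell_id = rep(embedding2d$cell_ids, each = length(present)),
    x = rep(embedding2d$coords[, 1], each = length(present)),
    y = rep(embedding2d$coords[, 2], each = length(present)),
    gene = rep(present, times = n),
    value = if (length(present))
      as.vector(as.matrix(norm[present, , drop = FALSE])) else numeric(0),
    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Write annotation results
#'
#' @param result An \code{annotation_result}.
#' @param score_path,assignment_path,coverage_path Optional TSV paths.
#' @return Invisibly, the result.
#' @export
write_annotation_result <- function(result, score_path = NULL,
                                    assignment_path = NULL,
                                    coverage_path = NULL) {
  stopifnot(inherits(result, "annotation_result"))
  wm <- function(m, path) {
    df <- data.frame(cluster = rownames(m), m, check.names = FALSE,
                     row.names = NULL)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(score_path)) wm(result$score_matrix, score_path)
  if (!is.null(coverage_path)) wm(result$coverage, coverage_path)
  if (!is.null(assignment_path))
    utils::write.table(
      data.frame(cluster = names(result$assignment),
                 cell_type = result$assignment),
      assignment_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(result)
}
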