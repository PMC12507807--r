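#' Quality-control parameters
#'
#' Defaults follow the common mouse skin scRNA-seq practice of discarding
#' cells with fewer than 200 or more than 2500 total UMIs, or with more than
#' 10\% of counts from mitochondrial genes. Bounds are strict on the
#' discarding side, so a cell at exactly 200 UMIs and exactly 10\% mito is
#' kept.
#'
#' @param min_umi Minimum total UMI count per cell (inclusive).
#' @param max_umi Maximum total UMI count per cell (inclusive).
#' @param max_mito_frac Maximum mitochondrial count fraction (inclusive).
#' @return A list of class \code{qc_params}.
#' @export
qc_params <- function(min_umi = 200L, max_umi = 2500L, max_mito_frac = 0.10) {
  min_umi <- as.integer(min_umi); max_umi <- as.integer(max_umi)
  if (min_umi < 0L || min_umi > max_umi)
    stop("require 0 <= min_umi <= max_umi")
  if (max_mito_frac < 0 || max_mito_frac > 1)
    stop("max_mito_frac must be in [0, 1]")
  structure(list(min_umi = min_umi, max_umi = max_umi,
                 max_mito_frac = max_mito_frac),
            class = "qc_params")
}

#' Filter cells on UMI totals and mitochondrial fraction
#'
#' Retains cells with \code{min_umi <= total UMI <= max_umi} and
#' mitochondrial fraction \code{<= max_mito_frac}. The gene set is
#' unchanged. Each discarded cell is annotated with its first failing
#' reason, checked in the order \code{low_umi}, \code{high_umi},
#' \code{high_mito}.
#'
#' @param counts A \code{\link{count_matrix}}.
#' @param params A \code{\link{qc_params}} object.
#' @return A list with \code{counts} (the filtered \code{count_matrix}) and
#'   \code{report}, a \code{preprocess_report}: summary counts plus a
#'   per-cell data frame (\code{cell_id}, \code{umi_total},
#'   \code{mito_frac}, \code{kept}, \code{reason}).
#' @export
qc_filter <- function(counts, params = qc_params()) {
  stopifnot(inherits(counts, "count_matrix"), inherits(params, "qc_params"))
  umi_total <- Matrix::colSums(counts$values)
  mito_total <- if (any(counts$mito_mask))
    Matrix::colSums(counts$values[counts$mito_mask, , drop = FALSE])
  else rep(0, length(umi_total))
  mito_frac <- ifelse(umi_total > 0, mito_total / umi_total, 0)

  reason <- rep(NA_character_, length(umi_total))
  reason[mito_frac > params$max_mito_frac] <- "high_mito"
  reason[umi_total > params$max_umi] <- "high_umi"
  reason[umi_total < params$min_umi] <- "low_umi"
  kept <- is.na(reason)

  per_cell <- data.frame(
    cell_id = counts$cell_ids, umi_total = as.numeric(umi_total),
    mito_frac = as.numeric(mito_frac), kept = kept, reason = reason,
    stringsAsFactors = FALSE, row.names = NULL)

  if (!any(kept))
    warning("QC filter retained 0 of ", length(kept), " cells")
  filtered <- count_matrix(
    counts$values[, kept, drop = FALSE],
    counts$gene_ids, counts$cell_ids[kept], counts$mito_mask)

  report <- structure(
    list(n_cells_in = length(kept), n_cells_kept = sum(kept),
         n_genes_hvg = NA_integer_, n_pcs = NA_integer_,
         per_cell = per_cell, params = params),
    class = "preprocess_report")
  list(counts = filtered, report = report)
}

#' Depth-normalize and log-transform counts
#'
#' Scales each cell to a common target count sum, then applies
#' \code{log1p}. This is a deliberately simple, deterministic normalizer:
#' it removes library-depth differences (proportional count vectors map to
#' identical output) and compresses dynamic range. Alternative normalizers
#' can be plugged into the pipeline via the \code{normalizer} argument of
#' \code{\link{cmd_sweep}}.
#'
#' @param counts A \code{\link{count_matrix}} (QC-filtered; every cell must
#'   have a positive total).
#' @param target_sum Per-cell count total after depth scaling.
#' @return A sparse genes x cells matrix of log-normalized values.
#' @export
normalize_counts <- function(counts, target_sum = 1e4) {
  stopifnot(inherits(counts, "count_matrix"))
  totals <- Matrix::colSums(counts$values)
  if (any(totals == 0))
    stop("cannot normalize: ", sum(totals == 0), " cell(s) with zero total count")
  norm <- counts$values %*% Matrix::Diagonal(x = target_sum / totals)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts$values)
  norm
}

#' Select highly variable genes
#'
#' Ranks genes by the variance of their log-normalized values across cells
#' and returns the indices of the top \code{n_top}. Constant genes are never
#' selected; if fewer than \code{n_top} genes vary, all varying genes are
#' returned. Ties in variance are broken toward the lower gene index.
#'
#' @param norm Genes x cells matrix of log-normalized values.
#' @param n_top Number of genes to select (default 3000).
#' @return Integer vector of selected row indices, ordered by decreasing
#'   variance.
#' @export
select_hvg <- function(norm, n_top = 3000L) {
  if (n_top < 1L) stop("n_top must be >= 1")
  n <- ncol(norm)
  if (n < 2L) stop("need at least 2 cells to estimate variance")
  mu <- Matrix::rowMeans(norm)
  mu2 <- Matrix::rowMeans(norm^2)
  v <- (mu2 - mu^2) * n / (n - 1)
  v[v < 0] <- 0                       # numerical guard
  variable <- which(v > 1e-12)
  if (!length(variable)) stop("no variable genes")
  ord <- variable[order(-v[variable], variable)]
  unname(ord[seq_len(min(n_top, length(ord)))])
}

#' PCA embedding of the HVG matrix
#'
#' Centers each gene across cells (optionally also scaling to unit
#' variance), then computes principal-component scores of the cells. The
#' default is centering only: the log-normalized input already puts genes
#' on comparable scales, and forcing unit variance amplifies pure-noise
#' genes relative to the informative high-variance genes that HVG
#' selection just chose, which measurably blurs cluster boundaries.
#' Component signs are fixed by a deterministic convention (the
#' largest-magnitude gene loading of each component is made positive), so
#' results are reproducible across linear-algebra backends. The
#' computation itself is deterministic; the \code{seed} argument is
#' accepted for pipeline-provenance uniformity and recorded but unused.
#'
#' @param norm_hvg HVG x cells matrix of log-normalized values.
#' @param n_pcs Number of principal components (default 20).
#' @param seed Recorded in provenance; the decomposition is deterministic.
#' @param scale_genes If \code{TRUE}, scale each gene to unit variance
#'   before the decomposition (default \code{FALSE}: center only).
#' @return A \code{\link{cell_embedding}} of dimension \code{n_pcs}.
#' @export
pca_embed <- function(norm_hvg, n_pcs = 20L, seed = 0L,
                      scale_genes = FALSE) {
  x <- t(as.matrix(norm_hvg))              # cells x genes
  max_pcs <- min(nrow(x) - 1L, ncol(x))
  if (n_pcs > max_pcs)
    stop("n_pcs = ", n_pcs, " exceeds admissible maximum ", max_pcs)
  if (scale_genes) {
    sds <- apply(x, 2L, stats::sd)
    sds[sds == 0] <- 1                     # constant gene: center only
    x <- scale(x, center = TRUE, scale = sds)
  } else {
    x <- scale(x, center = TRUE, scale = FALSE)
  }
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE, rank. = n_pcs)
  flip <- vapply(seq_len(n_pcs), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x[, seq_len(n_pcs), drop = FALSE], 2L, flip, "*")
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  cell_embedding(scores, colnames(norm_hvg))
}

#' Build a k-nearest-neighbor graph over cells
#'
#' Connects each cell to its \code{k_neighbors} nearest Euclidean neighbors
#' in the embedding, then symmetrizes (union of directed kNN edges). Edge
#' weights are 1. Distance ties are broken toward the lower cell index.
#'
#' @param embedding A \code{\link{cell_embedding}}.
#' @param k_neighbors Neighbors per cell (default 15).
#' @param seed Recorded for provenance; the construction is deterministic.
#' @return A list of class \code{neighbor_graph} with \code{graph} (an
#'   \code{igraph} object whose vertices are cells) and \code{k_neighbors}.
#' @export
build_neighbor_graph <- function(embedding, k_neighbors = 15L, seed = 0L) {
  n <- nrow(embedding$coords)
  if (k_neighbors >= n)
    stop("k_neighbors (", k_neighbors, ") must be < number of cells (", n, ")")
  D <- as.matrix(stats::dist(embedding$coords))
  edges <- vector("list", n)
  for (i in seq_len(n)) {
    ord <- order(D[i, ], seq_len(n))       # stable: ties to lower index
    ord <- ord[ord != i][seq_len(k_neighbors)]
    edges[[i]] <- cbind(i, ord)
  }
  em <- do.call(rbind, edges)
  # undirected union: canonical order then dedupe
  em <- cbind(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]))
  em <- unique(em)
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::V(g)$name <- embedding$cell_ids
  igraph::E(g)$weight <- 1
  structure(list(graph = g, k_neighbors = as.integer(k_neighbors),
                 cell_ids = embedding$cell_ids),
            class = "neighbor_graph")
}

#' Write a QC/preprocess report
#'
#' Writes the per-cell QC table as TSV and the summary as JSON.
#'
#' @param report A \code{preprocess_report} from \code{\link{qc_filter}}.
#' @param tsv_path,json_path Output file paths (either may be \code{NULL}).
#' @return Invisibly, the report.
#' @export
write_preprocess_report <- function(report, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "preprocess_report"))
  if (!is.null(tsv_path))
    utils::write.table(report$per_cell, tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    summary <- list(n_cells_in = report$n_cells_in,
                    n_cells_kept = report$n_cells_kept,
                    n_genes_hvg = report$n_genes_hvg,
                    n_pcs = report$n_pcs,
                    params = unclass(report$params))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE,
                         pretty = TRUE, na = "null", digits = NA)
  }
  invisible(report)
}
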