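#' Ward dendrogram over cluster centroid profiles
#'
#' Agglomerative clustering under the Ward minimum-variance objective,
#' computed with the Lance-Williams recurrence on squared inter-cluster
#' distances:
#' \deqn{d(k, i \cup j)^2 = \frac{(n_i + n_k) d_{ki}^2 + (n_j + n_k)
#'   d_{kj}^2 - n_k d_{ij}^2}{n_i + n_j + n_k}.}
#' Merge heights are on the Euclidean-distance scale: two singletons merge
#' at their Euclidean centroid distance. Ties in the minimum merge
#' distance are broken toward the lowest (i, j) node-index pair, making the
#' merge order deterministic.
#'
#' @param centroids Clusters x features numeric matrix (e.g. cluster means
#'   of the log-normalized HVG matrix).
#' @param leaf_names Optional leaf labels (default rownames or
#'   \code{"L1"...}).
#' @return An object of class \code{ward_dendrogram}: list with
#'   \code{merge} (hclust-style matrix: negative entries are leaves,
#'   positive entries earlier merges), \code{height}, \code{labels}.
#'   Convertible via \code{\link[stats]{as.hclust}}.
#' @export
ward_dendrogram <- function(centroids, leaf_names = NULL) {
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  if (n < 2L) stop("need at least 2 clusters to build a dendrogram")
  if (!all(is.finite(centroids))) stop("centroids must be finite")
  if (is.null(leaf_names))
    leaf_names <- if (!is.null(rownames(centroids))) rownames(centroids)
                  else paste0("L", seq_len(n))
  if (length(leaf_names) != n) stop("leaf_names length mismatch")

  d2 <- as.matrix(stats::dist(centroids))^2
  diag(d2) <- Inf
  sizes <- rep(1L, n)
  # node[i]: hclust code of active cluster i (-leaf or +merge index)
  node <- -seq_len(n)
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (m in seq_len(n - 1L)) {
    act <- which(active)
    sub <- d2[act, act, drop = FALSE]
    best <- which(sub == min(sub), arr.ind = TRUE)
    # lowest (i, j) pair, i < j, scanning i first
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    pick <- best[order(best[, 1], best[, 2])[1], ]
    i <- act[pick[1]]; j <- act[pick[2]]
    height[m] <- sqrt(d2[i, j])
    merge[m, ] <- sort(c(node[i], node[j]))
    ni <- sizes[i]; nj <- sizes[j]
    others <- act[act != i & act != j]
    if (length(others)) {
      nk <- sizes[others]
      d2[i, others] <- d2[others, i] <-
        ((ni + nk) * d2[i, others] + (nj + nk) * d2[j, others] -
           nk * d2[i, j]) / (ni + nj + nk)
    }
    sizes[i] <- ni + nj
    active[j] <- FALSE
    d2[j, ] <- d2[, j] <- Inf
    node[i] <- m
  }
  structure(list(merge = merge, height = height,
                 labels = as.character(leaf_names)),
            class = "ward_dendrogram")
}

#' @export
as.hclust.ward_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height,
                 order = dendro_leaf_order(x), labels = x$labels,
                 method = "ward.D2", dist.method = "euclidean"),
            class = "hclust")
}

# left-to-right leaf order implied by the merge matrix
dendro_leaf_order <- function(x) {
  rec <- function(node) {
    if (node < 0) return(-node)
    c(rec(x$merge[node, 1]), rec(x$merge[node, 2]))
  }
  rec(nrow(x$merge))
}

#' @export
print.ward_dendrogram <- function(x, ...) {
  cat("ward_dendrogram: ", length(x$labels), " leaves, heights in [",
      format(min(x$height), digits = 4), ", ",
      format(max(x$height), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Serialize a dendrogram as a Newick string
#'
#' Branch lengths are derived from merge heights: a child's branch is the
#' parent's height minus the child's height, with leaves at height 0.
#' Names needing escaping (whitespace or Newick punctuation) are
#' single-quoted, with internal quotes doubled.
#'
#' @param d A \code{ward_dendrogram}.
#' @return A Newick string ending in \code{";"}.
#' @export
dendrogram_to_newick <- function(d) {
  stopifnot(inherits(d, "ward_dendrogram"))
  quote_name <- function(s) {
    if (grepl("[][():;,'\" \t]", s))
      paste0("'", gsub("'", "''", s), "'")
    else s
  }
  node_str <- function(node, parent_height) {
    if (node < 0) {
      paste0(quote_name(d$labels[-node]), ":",
             format(parent_height, digits = 15))
    } else {
      h <- d$height[node]
      paste0("(", node_str(d$merge[node, 1], h), ",",
             node_str(d$merge[node, 2], h), "):",
             format(parent_height - h, digits = 15))
    }
  }
  root <- nrow(d$merge)
  h <- d$height[root]
  paste0("(", node_str(d$merge[root, 1], h), ",",
         node_str(d$merge[root, 2], h), ");")
}

#' Cell-type composition per condition
#'
#' Counts and percentages of each cell type within each condition. Types
#' absent from a condition are reported with count 0; percentages within a
#' condition sum to 100. Rows are ordered by condition (order of first
#' appearance, or factor levels), then by descending pooled abundance
#' (ties alphabetical).
#'
#' @param cell_types Character/factor vector, one cell-type label per cell.
#' @param conditions Character/factor vector aligned to \code{cell_types};
#'   may be a single value recycled conceptually via \code{rep} by the
#'   caller.
#' @return A data frame of class \code{composition_table} with columns
#'   \code{condition}, \code{cell_type}, \code{count}, \code{percent}.
#' @export
composition_compare <- function(cell_types, conditions) {
  if (length(cell_types) != length(conditions))
    stop("cell_types and conditions are not aligned")
  cond_levels <- if (is.factor(conditions)) levels(conditions)
                 else unique(as.character(conditions))
  conditions <- as.character(conditions)
  cell_types <- as.character(cell_types)
  pooled <- table(cell_types)
  type_order <- names(sort(pooled, decreasing = TRUE))
  type_order <- type_order[order(-pooled[type_order],
                                 type_order)]            # ties alphabetical
  rows <- list()
  for (cond in cond_levels) {
    sel <- conditions == cond
    if (!any(sel)) {
      warning("condition '", cond, "' has no cells")
      next
    }
    tab <- table(factor(cell_types[sel], levels = type_order))
    rows[[cond]] <- data.frame(
      condition = cond, cell_type = type_order,
      count = as.integer(tab),
      percent = 100 * as.numeric(tab) / sum(tab),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("composition_table", "data.frame")
  out
}
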