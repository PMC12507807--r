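#' Silhouette score of a partition on an embedding
#'
#' For each cell i in a cluster of size >= 2, let a(i) be the mean Euclidean
#' distance from i to the other members of its own cluster and b(i) the
#' smallest, over all other clusters, of the mean distance from i to that
#' cluster's members. The silhouette of i is
#' \deqn{S(i) = (b(i) - a(i)) / \max(a(i), b(i)),}
#' with S(i) = 0 for cells in singleton clusters (Rousseeuw convention) and
#' S(i) = 0 when max(a(i), b(i)) = 0 (coincident clusters). The partition
#' score is the arithmetic mean of S(i) over all n cells, singletons
#' included in the denominator.
#'
#' Distances are taken in the embedding (typically PCA) space: silhouettes on
#' raw counts are dominated by sequencing depth, and the embedding is the
#' space in which the clusters were formed.
#'
#' @param embedding A \code{\link{cell_embedding}}.
#' @param partition A \code{\link{cell_partition}} over the same cells
#'   (matched on cell ids; reordered if necessary).
#' @param metric Distance metric; only \code{"euclidean"} is supported.
#'
#' @return An object of class \code{silhouette_result}: list with
#'   \code{per_cell} (named numeric vector in [-1, 1]), \code{mean}, and
#'   \code{n_scored} (number of cells included, i.e. all of them).
#' @seealso \code{\link{brute_force_silhouette}} for the O(n^2) reference
#'   implementation used as a test oracle.
#' @export
silhouette_score <- function(embedding, partition, metric = "euclidean") {
  metric <- match.arg(metric, "euclidean")
  partition <- align_partition(embedding, partition)
  n <- length(embedding$cell_ids)
  if (n < 3L) stop("silhouette requires at least 3 cells")
  if (partition$k < 2L)
    stop("undefined silhouette: fewer than 2 clusters")
  D <- as.matrix(stats::dist(embedding$coords))
  s <- sil_from_distmat(D, partition$labels, partition$k)
  names(s) <- embedding$cell_ids
  new_silhouette_result(s)
}

# Per-cell silhouettes from a precomputed full distance matrix.
# Shared by silhouette_score and run_sweep (which amortizes D over a grid).
sil_from_distmat <- function(D, labels, k) {
  n <- length(labels)
  sizes <- tabulate(labels + 1L, nbins = k)
  # n x k matrix of summed distances from each cell to each cluster
  Z <- matrix(0, n, k)
  Z[cbind(seq_len(n), labels + 1L)] <- 1
  sums <- D %*% Z
  own <- cbind(seq_len(n), labels + 1L)
  own_size <- sizes[labels + 1L]
  a <- ifelse(own_size > 1L, sums[own] / (own_size - 1L), NA_real_)
  mean_to <- sweep(sums, 2L, sizes, "/")
  mean_to[own] <- Inf                      # exclude own cluster from b(i)
  b <- apply(mean_to, 1L, min)
  denom <- pmax(a, b)
  ifelse(own_size == 1L, 0,
         ifelse(denom == 0, 0, (b - a) / denom))
}

#' Brute-force silhouette (independent reference implementation)
#'
#' Same contract as \code{\link{silhouette_score}}, computed by an explicit
#' double loop over cells and clusters with per-pair distance evaluation.
#' Shares no code with the main implementation; intended as an O(n^2)
#' oracle for testing and for small inputs.
#'
#' @inheritParams silhouette_score
#' @return A \code{silhouette_result}.
#' @export
brute_force_silhouette <- function(embedding, partition) {
  partition <- align_partition(embedding, partition)
  n <- length(embedding$cell_ids)
  if (n < 3L) stop("silhouette requires at least 3 cells")
  if (partition$k < 2L)
    stop("undefined silhouette: fewer than 2 clusters")
  coords <- embedding$coords
  labels <- partition$labels
  clusters <- sort(unique(labels))
  s <- numeric(n)
  for (i in seq_len(n)) {
    members_own <- which(labels == labels[i])
    if (length(members_own) == 1L) { s[i] <- 0; next }
    a_i <- 0
    for (j in setdiff(members_own, i))
      a_i <- a_i + sqrt(sum((coords[i, ] - coords[j, ])^2))
    a_i <- a_i / (length(members_own) - 1L)
    b_i <- Inf
    for (cl in setdiff(clusters, labels[i])) {
      members <- which(labels == cl)
      d_sum <- 0
      for (j in members)
        d_sum <- d_sum + sqrt(sum((coords[i, ] - coords[j, ])^2))
      b_i <- min(b_i, d_sum / length(members))
    }
    s[i] <- if (max(a_i, b_i) == 0) 0 else (b_i - a_i) / max(a_i, b_i)
  }
  names(s) <- embedding$cell_ids
  new_silhouette_result(s)
}

new_silhouette_result <- function(per_cell) {
  structure(list(per_cell = per_cell, mean = mean(per_cell),
                 n_scored = length(per_cell)),
            class = "silhouette_result")
}

#' @export
print.silhouette_result <- function(x, ...) {
  cat("silhouette_result: mean = ", format(x$mean, digits = 6),
      " over ", x$n_scored, " cells\n", sep = "")
  invisible(x)
}
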