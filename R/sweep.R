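#' Resolution-sweep configuration
#'
#' The grid runs inclusively from \code{res_min} to \code{res_max} in steps
#' of \code{res_step}; grid points are generated by integer index
#' (\code{res_min + i * res_step}) so floating-point accumulation cannot
#' drop the endpoint. A step of 0.02 resolves an optimum to two decimals.
#'
#' @param res_min,res_max,res_step Grid bounds and step (defaults 0.10,
#'   1.50, 0.02).
#' @param algorithm Community-detection algorithm, \code{"leiden"}
#'   (default) or \code{"louvain"}.
#' @param seed Master seed; per-resolution seeds are derived as
#'   \code{seed + grid index}, so removing one grid point does not shift
#'   the others' results.
#' @param silhouette_subsample Optional cap on the number of cells scored
#'   per partition (stratified by cluster); \code{NULL} scores all cells.
#' @param min_k Minimum number of clusters for a partition to be scored
#'   (default 2; the silhouette is undefined below that).
#' @return A list of class \code{sweep_config}.
#' @export
sweep_config <- function(res_min = 0.10, res_max = 1.50, res_step = 0.02,
                         algorithm = c("leiden", "louvain"), seed = 0L,
                         silhouette_subsample = NULL, min_k = 2L) {
  algorithm <- match.arg(algorithm)
  if (res_min <= 0 || res_max <= 0) stop("resolutions must be positive")
  if (res_min > res_max) stop("res_min must be <= res_max")
  if (res_step <= 0) stop("res_step must be positive")
  if (!is.null(silhouette_subsample) && silhouette_subsample < 50L)
    stop("silhouette_subsample, if set, must be >= 50")
  structure(list(res_min = res_min, res_max = res_max, res_step = res_step,
                 algorithm = algorithm, seed = as.integer(seed),
                 silhouette_subsample =
                   if (is.null(silhouette_subsample)) NULL
                   else as.integer(silhouette_subsample),
                 min_k = as.integer(min_k)),
            class = "sweep_config")
}

#' Resolution grid of a sweep configuration
#' @param config A \code{\link{sweep_config}}.
#' @return Numeric vector of grid resolutions, ascending.
#' @export
resolution_grid <- function(config) {
  n_steps <- floor((config$res_max - config$res_min) / config$res_step + 1e-9)
  config$res_min + (0:n_steps) * config$res_step
}

#' Cluster the neighbor graph at one resolution
#'
#' Modularity-based community detection (Leiden or Louvain) with the
#' resolution parameter controlling granularity. Clusters are relabeled to
#' contiguous ids \code{0..k-1} by descending cluster size (ties toward the
#' community containing the earlier cell). Deterministic for fixed
#' (graph, resolution, seed): the RNG state is set from \code{seed} before
#' the community-detection call.
#'
#' @param graph A \code{neighbor_graph} from
#'   \code{\link{build_neighbor_graph}}.
#' @param resolution Positive resolution parameter.
#' @param algorithm \code{"leiden"} or \code{"louvain"}.
#' @param seed Integer seed.
#' @return A \code{\link{cell_partition}}.
#' @export
cluster_at_resolution <- function(graph, resolution,
                                  algorithm = c("leiden", "louvain"),
                                  seed = 0L) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(graph, "neighbor_graph"))
  if (igraph::vcount(graph$graph) == 0L) stop("empty graph")
  if (resolution <= 0) stop("resolution must be positive")
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  comm <- if (algorithm == "leiden")
    igraph::cluster_leiden(graph$graph, objective_function = "modularity",
                           resolution = resolution, n_iterations = 5L)
  else
    igraph::cluster_louvain(graph$graph, resolution = resolution)
  raw <- as.integer(igraph::membership(comm))
  sizes <- tabulate(raw)
  # rank communities by descending size, ties to the lower community id
  rank <- order(-sizes, seq_along(sizes))
  relabel <- integer(length(sizes)); relabel[rank] <- seq_along(sizes) - 1L
  cell_partition(relabel[raw], graph$cell_ids, resolution = resolution,
                 seed = as.integer(seed), algorithm = algorithm)
}

#' Stratified subsample of cells for silhouette scoring
#'
#' Draws \code{target_n} cells with per-cluster quotas proportional to
#' cluster sizes (largest-remainder rounding, remainders tied toward the
#' lower cluster id), guaranteeing at least one cell per cluster.
#' Deterministic for a fixed seed.
#'
#' @param partition A \code{\link{cell_partition}}.
#' @param target_n Total cells to draw; must be >= the number of clusters.
#' @param seed Integer seed.
#' @return Sorted integer vector of selected cell indices.
#' @export
stratified_subsample <- function(partition, target_n, seed = 0L) {
  k <- partition$k
  n <- length(partition$labels)
  if (target_n < k)
    stop("target_n (", target_n, ") must be >= number of clusters (", k, ")")
  if (target_n >= n) return(seq_len(n))
  sizes <- tabulate(partition$labels + 1L, nbins = k)
  exact <- target_n * sizes / n
  quota <- floor(exact)
  rem <- target_n - sum(quota)
  if (rem > 0) {
    frac_rank <- order(-(exact - quota), seq_len(k))
    quota[frac_rank[seq_len(rem)]] <- quota[frac_rank[seq_len(rem)]] + 1
  }
  # guarantee one per cluster, taking from the largest quotas
  while (any(quota == 0)) {
    donor <- which.max(quota)
    quota[which(quota == 0)[1]] <- 1
    quota[donor] <- quota[donor] - 1
  }
  quota <- pmin(quota, sizes)
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  idx <- unlist(lapply(seq_len(k), function(c) {
    members <- which(partition$labels == c - 1L)
    if (quota[c] >= length(members)) members
    else sort(sample(members, quota[c]))
  }))
  sort(idx)
}

#' Sweep resolutions and select the optimum by mean silhouette
#'
#' For each resolution in the grid, clusters the neighbor graph, scores the
#' resulting partition by mean silhouette on the embedding (optionally on a
#' stratified subsample), and selects the resolution with the highest mean
#' silhouette. Partitions with fewer than \code{min_k} clusters are
#' recorded but excluded from the optimization (the silhouette is undefined
#' for a single cluster; treating it as 0 would let the degenerate solution
#' win or lose on an arbitrary constant). Ties in mean silhouette are
#' broken toward the lowest resolution (fewer, coarser clusters preferred
#' at equal quality).
#'
#' @param embedding A \code{\link{cell_embedding}}.
#' @param graph A \code{neighbor_graph} over the same cells.
#' @param config A \code{\link{sweep_config}}.
#' @return An object of class \code{sweep_result}: list with
#'   \code{entries} (data frame: resolution, k, mean_silhouette, scored),
#'   \code{optimal_resolution}, \code{optimal_partition}, \code{config}.
#' @export
run_sweep <- function(embedding, graph, config = sweep_config()) {
  stopifnot(inherits(embedding, "cell_embedding"),
            inherits(graph, "neighbor_graph"),
            inherits(config, "sweep_config"))
  if (!identical(embedding$cell_ids, graph$cell_ids))
    stop("embedding and graph cell ids do not match")
  grid <- resolution_grid(config)
  partitions <- vector("list", length(grid))
  ks <- integer(length(grid))
  sil <- rep(NA_real_, length(grid))
  sub <- config$silhouette_subsample
  n <- length(embedding$cell_ids)
  D <- if (is.null(sub) || sub >= n)
    as.matrix(stats::dist(embedding$coords))  # amortized over the grid
  else NULL
  for (i in seq_along(grid)) {
    p <- cluster_at_resolution(graph, grid[i], config$algorithm,
                               seed = config$seed + (i - 1L))
    partitions[[i]] <- p
    ks[i] <- p$k
    if (p$k >= max(config$min_k, 2L)) {
      if (!is.null(sub) && sub < length(p$labels) && sub >= p$k) {
        idx <- stratified_subsample(p, sub, seed = config$seed + (i - 1L))
        emb_s <- cell_embedding(embedding$coords[idx, , drop = FALSE],
                                embedding$cell_ids[idx])
        part_s <- cell_partition(p$labels[idx], p$cell_ids[idx],
                                 resolution = p$resolution, seed = p$seed,
                                 algorithm = p$algorithm)
        if (part_s$k >= 2L)
          sil[i] <- silhouette_score(emb_s, part_s)$mean
      } else {
        sil[i] <- mean(sil_from_distmat(D, p$labels, p$k))
      }
    }
  }
  scored <- !is.na(sil)
  if (!any(scored)) stop("no multi-cluster partition in grid")
  best <- which(scored)[which.max(sil[scored])]  # first max = lowest res
  entries <- data.frame(resolution = grid, k = ks,
                        mean_silhouette = sil, scored = scored,
                        row.names = NULL)
  structure(list(entries = entries,
                 optimal_resolution = grid[best],
                 optimal_partition = partitions[[best]],
                 config = config),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("sweep_result: ", nrow(x$entries), " resolutions in [",
      min(x$entries$resolution), ", ", max(x$entries$resolution),
      "]\n  optimal resolution = ", format(x$optimal_resolution),
      " (k = ", x$optimal_partition$k, ", mean silhouette = ",
      format(max(x$entries$mean_silhouette, na.rm = TRUE), digits = 6),
      ")\n", sep = "")
  invisible(x)
}

#' Write a sweep result to disk
#'
#' @param result A \code{sweep_result}.
#' @param json_path Full result (grid, config echo, package version) as JSON.
#' @param tsv_path Grid table (resolution, k, mean_silhouette) as TSV.
#' @param partition_path Selected partition as two-column TSV
#'   (cell_id, cluster).
#' @return Invisibly, the result.
#' @export
write_sweep_result <- function(result, json_path = NULL, tsv_path = NULL,
                               partition_path = NULL) {
  stopifnot(inherits(result, "sweep_result"))
  if (!is.null(tsv_path))
    utils::write.table(
      result$entries[, c("resolution", "k", "mean_silhouette")],
      tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(partition_path))
    utils::write.table(
      data.frame(cell_id = result$optimal_partition$cell_ids,
                 cluster = result$optimal_partition$labels),
      partition_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    cfg <- result$config
    out <- list(
      package_version = as.character(utils::packageVersion("silsweep")),
      config = list(res_min = cfg$res_min, res_max = cfg$res_max,
                    res_step = cfg$res_step, algorithm = cfg$algorithm,
                    seed = cfg$seed,
                    silhouette_subsample = cfg$silhouette_subsample,
                    min_k = cfg$min_k),
      optimal_resolution = result$optimal_resolution,
      optimal_k = result$optimal_partition$k,
      entries = result$entries)
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, pretty = TRUE,
                         na = "null", digits = NA)
  }
  invisible(result)
}
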