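#' Configuration for the synthetic count generator
#'
#' Describes a negative-binomial (gamma-Poisson) mixture of \code{k_types}
#' cell types. Every type owns \code{markers_per_type} marker genes whose
#' mean is elevated by a fold factor set by \code{separation} (low = 2x,
#' medium = 5x, high = 20x). Per-cell depth varies log-normally. A block of
#' mitochondrial genes (named \code{mt-1}, \code{mt-2}, ...) is scaled so
#' the expected mitochondrial fraction matches \code{mito_frac_mean}.
#' Cells are split equally across the configured conditions; each
#' condition draws cell types from its own proportion vector.
#'
#' @param n_cells,n_genes Matrix dimensions (genes includes the
#'   mitochondrial block).
#' @param k_types Number of latent cell types.
#' @param markers_per_type Marker genes per type (default 5).
#' @param separation \code{"low"}, \code{"medium"} or \code{"high"}.
#' @param base_mean Baseline NB mean per gene per cell (default 0.5).
#' @param dispersion NB dispersion; variance = mu + dispersion * mu^2
#'   (default 0.5).
#' @param mito_genes Number of mitochondrial genes (default 10).
#' @param mito_frac_mean Target expected mitochondrial count fraction
#'   (default 0.05).
#' @param depth_lognormal_sigma Log-scale SD of the per-cell depth factor
#'   (default 0.3).
#' @param conditions Named list: condition name -> type-proportion vector
#'   of length \code{k_types} summing to 1. Default a single
#'   \code{"control"} condition with uniform proportions.
#' @param seed Integer seed (Mersenne-Twister).
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_cells, n_genes, k_types,
                       markers_per_type = 5L,
                       separation = c("medium", "low", "high"),
                       base_mean = 0.5, dispersion = 0.5,
                       mito_genes = 10L, mito_frac_mean = 0.05,
                       depth_lognormal_sigma = 0.3,
                       conditions = NULL, seed = 0L) {
  separation <- match.arg(separation)
  if (k_types < 1L) stop("k_types must be >= 1")
  if (base_mean <= 0 || dispersion <= 0) stop("rates must be positive")
  if (mito_frac_mean < 0 || mito_frac_mean >= 1)
    stop("mito_frac_mean must be in [0, 1)")
  if (n_genes < k_types * markers_per_type + mito_genes)
    stop("n_genes too small for the requested marker and mito blocks")
  if (is.null(conditions))
    conditions <- list(control = rep(1 / k_types, k_types))
  if (is.null(names(conditions)) || anyDuplicated(names(conditions)))
    stop("conditions must be a uniquely named list")
  for (p in conditions) {
    if (length(p) != k_types || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("each condition's type proportions must be length k_types, ",
           "non-negative, and sum to 1")
  }
  structure(list(n_cells = as.integer(n_cells),
                 n_genes = as.integer(n_genes),
                 k_types = as.integer(k_types),
                 markers_per_type = as.integer(markers_per_type),
                 separation = separation, base_mean = base_mean,
                 dispersion = dispersion, mito_genes = as.integer(mito_genes),
                 mito_frac_mean = mito_frac_mean,
                 depth_lognormal_sigma = depth_lognormal_sigma,
                 conditions = conditions, seed = as.integer(seed)),
            class = "sim_config")
}

separation_fold <- function(separation) {
  switch(separation, low = 2, medium = 5, high = 20)
}

#' Expected total count per cell under a simulation configuration
#'
#' Closed-form expectation (over genes, depth and type) of a cell's total
#' UMI count; used in law-of-large-numbers checks.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A single number.
#' @export
sim_expected_total <- function(config) {
  fold <- separation_fold(config$separation)
  n_plain <- config$n_genes - config$mito_genes - config$markers_per_type
  base_total <- config$base_mean *
    (n_plain + fold * config$markers_per_type)
  f <- config$mito_frac_mean
  mito_total <- base_total * f / (1 - f)
  (base_total + mito_total) * exp(config$depth_lognormal_sigma^2 / 2)
}

#' Simulate a gene-by-cell count matrix with known structure
#'
#' Draws, per cell: a condition (equal split), a cell type (that
#' condition's proportions), and a log-normal depth factor; then, per
#' gene, negative-binomial counts with mean
#' \code{base_mean * depth * fold}, where \code{fold} is the separation
#' fold if the gene is a marker of the cell's type and 1 otherwise.
#' Mitochondrial gene means are scaled so the expected mitochondrial
#' fraction matches the configuration. All randomness flows through R's
#' Mersenne-Twister generator seeded from \code{config$seed}, so output is
#' bit-reproducible for a given configuration.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A list of class \code{sim_output}: \code{counts}
#'   (\code{\link{count_matrix}}), \code{true_type} (integer 0-based per
#'   cell), \code{condition} (character per cell), \code{marker_assignment}
#'   (integer per gene: owning type 0-based, or NA).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed, kind = "Mersenne-Twister")
  n <- config$n_cells; g <- config$n_genes; k <- config$k_types
  fold <- separation_fold(config$separation)

  cond_names <- names(config$conditions)
  # equal split preserving configured order, remainder spread evenly
  n_per <- diff(round(seq(0, n, length.out = length(cond_names) + 1)))
  condition <- rep(cond_names, times = n_per)

  true_type <- integer(n)
  for (ci in seq_along(cond_names)) {
    sel <- which(condition == cond_names[ci])
    true_type[sel] <- sample.int(k, length(sel), replace = TRUE,
                                 prob = config$conditions[[ci]]) - 1L
  }
  depth <- exp(stats::rnorm(n, 0, config$depth_lognormal_sigma))

  n_mito <- config$mito_genes
  n_marker <- k * config$markers_per_type
  marker_assignment <- rep(NA_integer_, g)
  marker_assignment[seq_len(n_marker)] <-
    rep(seq_len(k) - 1L, each = config$markers_per_type)
  is_mito <- c(rep(FALSE, g - n_mito), rep(TRUE, n_mito))

  gene_ids <- character(g)
  gene_ids[seq_len(n_marker)] <-
    paste0("Mk", rep(seq_len(k), each = config$markers_per_type), "-",
           rep(seq_len(config$markers_per_type), times = k))
  gene_ids[which(!is_mito)[-seq_len(n_marker)]] <-
    sprintf("Gene%05d", seq_len(g - n_mito - n_marker))
  gene_ids[is_mito] <- paste0("mt-", seq_len(n_mito))

  # per-cell expected non-mito total is type-independent (each type has the
  # same number of fold-elevated markers), so one mito mean serves all cells
  base_total <- config$base_mean *
    (g - n_mito - config$markers_per_type + fold * config$markers_per_type)
  f <- config$mito_frac_mean
  mito_mean <- if (n_mito > 0)
    base_total * f / (1 - f) / n_mito else numeric(0)

  mu <- matrix(config$base_mean, g, n)
  if (n_mito > 0) mu[is_mito, ] <- mito_mean
  for (t in seq_len(k) - 1L) {
    rows <- which(marker_assignment == t)
    cols <- which(true_type == t)
    if (length(rows) && length(cols)) mu[rows, cols] <- config$base_mean * fold
  }
  mu <- sweep(mu, 2L, depth, "*")
  counts <- matrix(
    stats::rnbinom(g * n, mu = as.vector(mu), size = 1 / config$dispersion),
    g, n)
  cell_ids <- sprintf("cell%05d", seq_len(n))
  cm <- count_matrix(counts, gene_ids, cell_ids, mito_mask = is_mito)
  structure(list(counts = cm, true_type = true_type, condition = condition,
                 marker_assignment = marker_assignment, config = config),
            class = "sim_output")
}

#' A two-condition demonstration configuration
#'
#' A convenience preset with "control" and "wounded" conditions in which
#' one cell type expands sharply between conditions (0.5\% to 11\%) and
#' another contracts (17\% to 1.5\%), emulating the kind of composition
#' shift seen in skin wound-healing data. For demonstration and testing of
#' the composition tooling only; no quantitative claims attach to it.
#'
#' @param n_cells,n_genes,seed Passed through to \code{\link{sim_config}}.
#' @return A \code{sim_config} with \code{k_types = 6}.
#' @export
sim_config_wound_demo <- function(n_cells = 2000L, n_genes = 1000L,
                                  seed = 0L) {
  k <- 6L
  control <- c(0.005, 0.17, rep((1 - 0.005 - 0.17) / (k - 2), k - 2))
  wounded <- c(0.11, 0.015, rep((1 - 0.11 - 0.015) / (k - 2), k - 2))
  sim_config(n_cells = n_cells, n_genes = n_genes, k_types = k,
             separation = "high",
             conditions = list(control = control, wounded = wounded),
             seed = seed)
}

#' Adjusted Rand Index between a partition and ground truth
#'
#' Chance-corrected agreement between two labelings, from the
#' pair-counting contingency table. 1 for identical partitions, about 0
#' for independent ones.
#'
#' @param predicted A \code{\link{cell_partition}} or a label vector.
#' @param truth A label vector of the same length.
#' @return A number in [-1, 1].
#' @export
ground_truth_ari <- function(predicted, truth) {
  labels <- if (inherits(predicted, "cell_partition")) predicted$labels
            else predicted
  if (length(labels) != length(truth))
    stop("predicted and truth labelings are not aligned")
  tab <- table(labels, truth)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sum_ij <- sum_comb(tab)
  sum_a <- sum_comb(rowSums(tab))
  sum_b <- sum_comb(colSums(tab))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

#' Write simulated data as a 10x triplet plus ground-truth table
#'
#' @param sim A \code{sim_output}.
#' @param dir Output directory. Writes \code{matrix.mtx},
#'   \code{features.tsv}, \code{barcodes.tsv} and \code{truth.tsv}
#'   (cell_id, type, condition).
#' @return Invisibly, the files written.
#' @export
write_sim_output <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_output"))
  files <- write_10x_counts(sim$counts, dir)
  truth <- file.path(dir, "truth.tsv")
  utils::write.table(
    data.frame(cell_id = sim$counts$cell_ids,
               type = paste0("type", sim$true_type),
               condition = sim$condition),
    truth, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(files, truth))
}
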