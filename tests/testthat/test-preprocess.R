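# small deterministic count fixture: columns are cells with prescribed
# UMI totals and mito fractions, built from two regular genes + one mito gene
fixture_counts <- function(umi, mito_frac) {
  mito <- round(umi * mito_frac)
  other <- umi - mito
  values <- rbind(floor(other / 2), ceiling(other / 2), mito)
  count_matrix(values, c("Gene1", "Gene2", "mt-Co1"),
               sprintf("cell%d", seq_along(umi)))
}

test_that("QC discards the three canonical violators with the right reasons", {
  cm <- fixture_counts(c(150, 1200, 3000), c(0.02, 0.12, 0.05))
  expect_warning(res <- qc_filter(cm), "retained 0")
  expect_identical(res$report$n_cells_kept, 0L)
  expect_identical(res$report$per_cell$reason,
                   c("low_umi", "high_mito", "high_umi"))
  expect_identical(ncol(res$counts$values), 0L)
  expect_identical(res$counts$gene_ids, cm$gene_ids)  # gene set unchanged
})

test_that("QC bounds are inclusive: boundary and interior cells survive", {
  cm <- fixture_counts(c(200, 2500, 1000), c(0.10, 0.10, 0.0))
  res <- qc_filter(cm)
  expect_true(all(res$report$per_cell$kept))
  expect_identical(res$report$n_cells_kept, 3L)
})

test_that("QC is idempotent and its report partitions the input", {
  sim <- simulate_counts(sim_config(300, 600, 2, seed = 42))
  r1 <- qc_filter(sim$counts)
  r2 <- qc_filter(r1$counts)
  expect_identical(r2$counts$cell_ids, r1$counts$cell_ids)
  expect_identical(r2$report$n_cells_kept, r2$report$n_cells_in)
  pc <- r1$report$per_cell
  expect_identical(sum(pc$kept) + sum(!pc$kept), r1$report$n_cells_in)
  expect_true(all(!is.na(pc$reason[!pc$kept])))
  expect_true(all(is.na(pc$reason[pc$kept])))
})

test_that("mitochondrial genes fall back to the mt- prefix", {
  m <- rbind(c(10, 10), c(90, 0))
  cm <- count_matrix(m, c("Actb", "MT-Nd1"), c("a", "b"))
  expect_identical(cm$mito_mask, c(FALSE, TRUE))
  res <- qc_filter(cm, qc_params(min_umi = 1, max_umi = 1e6,
                                 max_mito_frac = 0.5))
  expect_identical(res$report$per_cell$reason, c("high_mito", NA_character_))
})

test_that("normalization has the documented closed form and depth invariance", {
  m <- cbind(c(0, 100, 0), c(0, 50, 0), c(3, 5, 2))
  cm <- count_matrix(m, c("g1", "g2", "g3"), c("a", "b", "c"))
  norm <- normalize_counts(cm, target_sum = 1e4)
  expect_equal(norm[, "a"], c(g1 = 0, g2 = log1p(1e4), g3 = 0))
  # proportional cells map identically
  expect_equal(norm[, "a"], norm[, "b"])
  cm0 <- count_matrix(cbind(c(0, 0)), c("g1", "g2"), "empty")
  expect_error(normalize_counts(cm0), "zero total")
})

test_that("HVG selection ranks by variance with stated tie and cap rules", {
  set.seed(1)
  norm <- rbind(rep(1, 10),                         # constant: never chosen
                seq(0, 9) * 2,                      # largest variance
                seq(0, 9),
                rev(seq(0, 9)),                     # tie with previous
                rnorm(10, sd = 0.01))
  rownames(norm) <- paste0("g", 1:5)
  sel <- select_hvg(norm, 3000)
  expect_length(sel, 4)                             # only 4 non-constant
  expect_identical(sel[1], 2L)                      # argmax
  expect_identical(select_hvg(norm, 1), 2L)
  tie <- which(sel %in% c(3L, 4L))
  expect_identical(sel[tie], c(3L, 4L))             # tie to lower index
  expect_error(select_hvg(matrix(1, 3, 4), 10), "no variable genes")
})

test_that("PCA is an isometry on exactly low-rank data", {
  set.seed(7)
  basis <- qr.Q(qr(matrix(rnorm(20 * 2), 20, 2)))
  scores2 <- matrix(rnorm(30 * 2, sd = 3), 30, 2)
  X <- scores2 %*% t(basis)                          # cells x genes, rank 2
  norm <- t(X); rownames(norm) <- paste0("g", 1:20)
  colnames(norm) <- paste0("c", 1:30)
  emb <- pca_embed(norm, n_pcs = 2)
  expect_lt(max(abs(dist(emb$coords) - dist(X))), 1e-8)
})

test_that("one-PC scores recover the dominant direction of the data", {
  set.seed(8)
  direction <- rnorm(15); direction <- direction / sqrt(sum(direction^2))
  t_val <- rnorm(100, sd = 5)
  X <- outer(t_val, direction) + matrix(rnorm(100 * 15, sd = 0.1), 100)
  norm <- t(X); rownames(norm) <- paste0("g", 1:15)
  colnames(norm) <- paste0("c", 1:100)
  emb <- pca_embed(norm, n_pcs = 1)
  # independent oracle: leading eigenvector of the covariance
  ev <- eigen(stats::cov(X))$vectors[, 1]
  proj <- scale(X, scale = FALSE) %*% ev
  expect_gt(abs(stats::cor(emb$coords[, 1], proj)), 0.99)
})

test_that("PCA is deterministic and enforces the component cap", {
  sim <- simulate_counts(sim_config(80, 120, 2, seed = 3))
  norm <- normalize_counts(sim$counts)
  e1 <- pca_embed(norm, n_pcs = 10)
  e2 <- pca_embed(norm, n_pcs = 10)
  expect_identical(e1$coords, e2$coords)
  expect_error(pca_embed(norm, n_pcs = 500), "admissible maximum")
})

test_that("kNN graph matches geometry and the brute-force search", {
  emb <- cell_embedding(cbind(c(0, 1, 10)), c("a", "b", "c"))
  g <- build_neighbor_graph(emb, k_neighbors = 1)
  el <- igraph::as_edgelist(g$graph)
  expect_true(any(el[, 1] == "a" & el[, 2] == "b" |
                  el[, 1] == "b" & el[, 2] == "a"))
  expect_gte(nrow(el), 2)

  dup <- cell_embedding(rbind(c(0, 0), c(0, 0), c(5, 5)), c("x", "y", "z"))
  gd <- build_neighbor_graph(dup, 1)
  eld <- igraph::as_edgelist(gd$graph)
  expect_true(any((eld[, 1] == "x" & eld[, 2] == "y") |
                  (eld[, 1] == "y" & eld[, 2] == "x")))

  blobs <- gaussian_blobs(n_per = 25, centers = rbind(c(0, 0), c(100, 100)),
                          seed = 2)
  gb <- build_neighbor_graph(blobs$embedding, 5)
  comp <- igraph::components(gb$graph)$membership
  expect_length(intersect(unique(comp[blobs$truth == 0]),
                          unique(comp[blobs$truth == 1])), 0)
  # adjacency contains every brute-force kNN edge
  ref <- oracle_knn(blobs$embedding$coords, 5)
  adj <- igraph::as_adjacency_matrix(gb$graph, sparse = FALSE)
  for (i in seq_len(nrow(ref)))
    expect_true(all(adj[i, ref[i, ]] > 0))

  expect_error(build_neighbor_graph(dup, 3), "must be <")
})

test_that("the preprocessing chain is byte-deterministic end to end", {
  sim <- simulate_counts(sim_config(150, 600, 3, seed = 9))
  once <- function() {
    qr <- qc_filter(sim$counts)
    norm <- normalize_counts(qr$counts)
    hvg <- select_hvg(norm, 50)
    pca_embed(norm[hvg, , drop = FALSE], n_pcs = 5)$coords
  }
  expect_identical(once(), once())
})
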