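test_that("the packaged marker panel loads with unique, non-empty entries", {
  mt <- default_marker_table()
  expect_s3_class(mt, "marker_table")
  expect_gte(length(mt), 21)
  expect_false(anyDuplicated(names(mt)) > 0)
  expect_true(all(vapply(mt, length, 1L) >= 1L))
  expect_identical(mt[["Pan-Fibroblast"]], c("Pdgfra", "Dpt"))
  # the two same-named hair-follicle keratinocyte entries are kept distinct
  expect_length(grep("^HFK-II", names(mt)), 2)
})

# cluster-structured expression: genes x cells, cluster c expresses the
# genes in `hot[[c]]` at `high`, everything else at `low`
structured_matrix <- function(genes, hot, cells_per = 5, high = 5, low = 1) {
  k <- length(hot)
  m <- matrix(low, length(genes), k * cells_per,
              dimnames = list(genes,
                              sprintf("cell%02d", seq_len(k * cells_per))))
  for (c in seq_len(k))
    m[hot[[c]], (c - 1) * cells_per + seq_len(cells_per)] <- high
  labels <- rep(seq_len(k) - 1L, each = cells_per)
  list(m = m, partition = cell_partition(labels, colnames(m)))
}

test_that("a cluster expressing only Pdgfra and Dpt is called Pan-Fibroblast", {
  s <- structured_matrix(c("Pdgfra", "Dpt", "Krt5", "Krt14", "Pecam1"),
                         hot = list(c("Pdgfra", "Dpt"),
                                    c("Krt5", "Krt14")))
  res <- score_clusters(s$m, s$partition, default_marker_table())
  expect_identical(unname(res$assignment[1]), "Pan-Fibroblast")
  expect_identical(unname(res$assignment[2]), "Pan-Keratinocytes")
})

test_that("single-type tables and exact ties follow the stated rules", {
  s <- structured_matrix(c("g1", "g2"), hot = list("g1", "g2"))
  one <- marker_table(list(OnlyType = "g1"))
  res <- score_clusters(s$m, s$partition, one)
  expect_identical(unname(res$assignment), rep("OnlyType", 2))

  twin <- marker_table(list(First = c("g1"), Second = c("g1")))
  res2 <- score_clusters(s$m, s$partition, twin)
  expect_equal(res2$score_matrix[, "First"], res2$score_matrix[, "Second"])
  expect_identical(unname(res2$assignment), rep("First", 2))  # table order
})

test_that("scores are invariant to relabeling and to per-gene constant shifts", {
  set.seed(20)
  genes <- sprintf("g%02d", 1:12)
  s <- structured_matrix(genes, hot = list(genes[1:3], genes[4:6]),
                         cells_per = 6)
  s$m <- s$m + matrix(rnorm(length(s$m), sd = 0.1), nrow(s$m))
  mt <- marker_table(list(A = genes[1:3], B = genes[4:6]))
  base <- score_clusters(s$m, s$partition, mt)

  flipped <- cell_partition(1L - s$partition$labels, s$partition$cell_ids)
  refl <- score_clusters(s$m, flipped, mt)
  expect_equal(unname(refl$score_matrix[2:1, ]),
               unname(base$score_matrix), tolerance = 1e-12)

  shifted <- s$m; shifted["g01", ] <- shifted["g01", ] + 7
  expect_equal(score_clusters(shifted, s$partition, mt)$score_matrix,
               base$score_matrix, tolerance = 1e-12)
})

test_that("missing markers reduce coverage and fully absent tables error", {
  s <- structured_matrix(c("g1", "g2"), hot = list("g1", "g2"))
  mt <- marker_table(list(A = c("g1", "nope"), B = "g2"))
  expect_warning(res <- score_clusters(s$m, s$partition, mt), NA)
  expect_equal(unname(res$coverage[, "A"]), rep(0.5, 2))
  expect_equal(unname(res$coverage[, "B"]), rep(1, 2))
  expect_identical(res$missing_markers$A, "nope")
  disjoint <- marker_table(list(A = "absent1", B = "absent2"))
  expect_error(score_clusters(s$m, s$partition, disjoint),
               "disjoint from data")
})

test_that("case-insensitive marker fallback warns but matches", {
  s <- structured_matrix(c("Pdgfra", "g2"), hot = list("Pdgfra", "g2"))
  mt <- marker_table(list(A = "PDGFRA", B = "g2"))
  expect_warning(res <- score_clusters(s$m, s$partition, mt),
                 "case-insensitively")
  expect_identical(unname(res$assignment[1]), "A")
})

test_that("annotation recovers true types on simulated data across seeds", {
  for (seed in 1:5) {
    sim <- simulate_counts(sim_config(400, 400, 3, separation = "high",
                                      seed = seed))
    norm <- normalize_counts(sim$counts)
    truth_part <- cell_partition(sim$true_type, sim$counts$cell_ids)
    mt <- marker_table(setNames(
      lapply(0:2, function(t)
        sim$counts$gene_ids[which(sim$marker_assignment == t)]),
      paste0("type", 0:2)))
    res <- score_clusters(norm, truth_part, mt)
    expect_identical(unname(res$assignment), paste0("type", 0:2))
  }
})

test_that("feature-plot data has one row per present (cell, gene) pair", {
  m <- matrix(c(1, 0, 2, 3), 2, 2,
              dimnames = list(c("gA", "gB"), c("c1", "c2")))
  emb <- cell_embedding(rbind(c(0, 1), c(2, 3)), c("c1", "c2"))
  df <- feature_plot_data(m, emb, c("gA", "gB"))
  expect_identical(nrow(df), 4L)
  expect_identical(df$gene, rep(c("gA", "gB"), 2))
  expect_identical(df$cell_id, rep(c("c1", "c2"), each = 2))
  expect_equal(df$value[df$cell_id == "c2" & df$gene == "gB"], 3)

  expect_warning(df2 <- feature_plot_data(m, emb, c("gA", "missing")),
                 "absent")
  expect_identical(nrow(df2), 2L)

  zero <- m; zero["gA", ] <- 0
  df3 <- feature_plot_data(zero, emb, "gA")
  expect_identical(df3$value, c(0, 0))

  emb3 <- cell_embedding(matrix(rnorm(6), 2), c("c1", "c2"))
  expect_error(feature_plot_data(m, emb3, "gA"), "2-D")
})

test_that("annotation writers produce readable TSVs", {
  s <- structured_matrix(c("g1", "g2"), hot = list("g1", "g2"))
  res <- score_clusters(s$m, s$partition,
                        marker_table(list(A = "g1", B = "g2")))
  d <- withr::local_tempdir()
  write_annotation_result(res,
                          score_path = file.path(d, "s.tsv"),
                          assignment_path = file.path(d, "a.tsv"),
                          coverage_path = file.path(d, "c.tsv"))
  a <- read.delim(file.path(d, "a.tsv"))
  expect_identical(a$cell_type, c("A", "B"))
  sc <- read.delim(file.path(d, "s.tsv"), check.names = FALSE)
  expect_identical(dim(sc), c(2L, 3L))
})
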