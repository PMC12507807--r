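# Shared fixtures and independent oracles for the test suite.
# Everything here is deliberately naive: oracles recompute objectives from
# scratch and share no code with the implementations they check.

# random embedding + partition with each cluster guaranteed non-empty
random_instance <- function(n, d, k, seed) {
  set.seed(seed)
  coords <- matrix(rnorm(n * d), n, d)
  labels <- c(seq_len(k) - 1L, sample.int(k, n - k, replace = TRUE) - 1L)
  labels <- sample(labels)
  ids <- sprintf("c%04d", seq_len(n))
  list(embedding = cell_embedding(coords, ids),
       partition = cell_partition(labels, ids))
}

# three well-separated Gaussian blobs directly in embedding space
gaussian_blobs <- function(n_per = 60, centers = rbind(c(0, 0), c(20, 0),
                                                      c(0, 20)),
                           sd = 1, seed = 0) {
  set.seed(seed)
  k <- nrow(centers)
  coords <- do.call(rbind, lapply(seq_len(k), function(i)
    sweep(matrix(rnorm(n_per * ncol(centers), sd = sd), n_per), 2L,
          centers[i, ], "+")))
  ids <- sprintf("b%04d", seq_len(k * n_per))
  list(embedding = cell_embedding(coords, ids),
       truth = rep(seq_len(k) - 1L, each = n_per), ids = ids)
}

# step-wise brute-force Ward clustering: recomputes the within-cluster
# sum-of-squares increase from the raw centroids at every step. Heights on
# the Euclidean scale (sqrt of twice the ESS increase). Ties broken toward
# the pair with the lowest minimum original leaf indices, matching the
# documented tie rule.
oracle_ward <- function(centroids) {
  n <- nrow(centroids)
  clusters <- lapply(seq_len(n), identity)   # member leaf indices
  codes <- -seq_len(n)                       # hclust codes
  merges <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  ess <- function(members) {
    x <- centroids[members, , drop = FALSE]
    sum(sweep(x, 2L, colMeans(x), "-")^2)
  }
  for (m in seq_len(n - 1L)) {
    best <- NULL; best_d <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      delta <- ess(c(clusters[[a]], clusters[[b]])) -
        ess(clusters[[a]]) - ess(clusters[[b]])
      h <- sqrt(2 * delta)
      key <- c(min(clusters[[a]]), min(clusters[[b]]))
      if (h < best_d - 1e-12 ||
          (abs(h - best_d) <= 1e-12 && !is.null(best) &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best_d <- h
        best <- list(a = a, b = b, key = key)
      }
    }
    heights[m] <- best_d
    merges[m, ] <- sort(c(codes[[best$a]], codes[[best$b]]))
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    codes[[best$a]] <- m
    clusters[[best$b]] <- NULL
    codes <- codes[-best$b]
  }
  list(merge = merges, height = heights)
}

# brute-force k nearest neighbors by full sort
oracle_knn <- function(coords, k) {
  n <- nrow(coords)
  t(vapply(seq_len(n), function(i) {
    d <- sqrt(colSums((t(coords) - coords[i, ])^2))
    ord <- order(d, seq_len(n))
    ord[ord != i][seq_len(k)]
  }, integer(k)))
}

# run the full file-free pipeline on a sim_output; returns pieces
pipeline_on_sim <- function(sim, sweep_cfg = sweep_config(seed = 0L),
                            n_pcs = 20L) {
  qr <- qc_filter(sim$counts)
  norm <- normalize_counts(qr$counts)
  hvg <- select_hvg(norm, 3000L)
  emb <- pca_embed(norm[hvg, , drop = FALSE],
                   n_pcs = min(n_pcs, ncol(norm) - 1L, length(hvg)))
  graph <- build_neighbor_graph(emb, 15L)
  sw <- run_sweep(emb, graph, sweep_cfg)
  truth <- sim$true_type[match(qr$counts$cell_ids, sim$counts$cell_ids)]
  list(qc = qr, norm = norm, hvg = hvg, embedding = emb, graph = graph,
       sweep = sw, truth = truth)
}

# exact silhouette means of the two hand examples, from the closed form
hand_example_4pt_mean <- function() {
  b <- (10 + sqrt(101)) / 2
  (b - 1) / b
}
hand_example_3pt_mean <- function() {
  sA <- (5 - 1) / 5
  sB <- (sqrt(26) - 1) / sqrt(26)
  (sA + sB + 0) / 3
}
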