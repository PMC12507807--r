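---
title: "Silhouette-guided selection of clustering resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Silhouette-guided selection of clustering resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silsweep)
```

## The problem

Graph community detection — Leiden or Louvain on a k-nearest-neighbor
cell graph — is the standard way to cluster single-cell RNA-seq data, and
its *resolution* parameter controls how finely cells are split. The choice
of resolution is usually made by eye, yet it determines the entire
downstream story: how many cell types are reported, how they are
annotated, and how their proportions are compared between conditions.

silsweep makes that choice quantitative. It sweeps a grid of resolutions,
scores the partition at each grid point by its **mean silhouette**, and
selects the resolution with the highest score.

## The silhouette criterion

For cell $i$ in a cluster with at least two members, let $a(i)$ be the
mean distance from $i$ to the other members of its own cluster and $b(i)$
the smallest, over all other clusters, of the mean distance from $i$ to
that cluster's members (the Rousseeuw definitions). Then

$$S(i) = \frac{b(i) - a(i)}{\max(a(i), b(i))}, \qquad
  S = \frac{1}{n}\sum_{i=1}^{n} S(i).$$

Conventions, fixed once and tested:

* cells in singleton clusters receive $S(i) = 0$ and still count in the
  denominator $n$;
* if $\max(a(i), b(i)) = 0$ (two coincident clusters), $S(i) = 0$;
* distances are Euclidean in **PCA space**. Silhouettes on raw counts are
  dominated by sequencing depth, and PCA space is the space in which the
  neighbor graph — hence the clustering itself — was built. This is an
  assumption of the method, exposed rather than hidden: the scoring
  function accepts any embedding.
* partitions with $k = 1$ are *unscored*, not scored 0. Assigning the
  degenerate single-cluster solution an arbitrary constant would let it
  win (or lose) every comparison for reasons unrelated to the data.
* ties in mean silhouette select the **lowest** resolution: at equal
  measured quality, prefer the coarser, more parsimonious partition.

The package carries two implementations of the same contract:
`silhouette_score()` (matrix algebra over a shared distance matrix,
amortized across the sweep) and `brute_force_silhouette()` (an explicit
double loop). They share no code; the test suite and the reproduction
script require them to agree within $10^{-9}$ on random instances. Where
hand computation is feasible the exact closed forms are asserted — for
example the two-rectangles instance with $a = 1$,
$b = (10 + \sqrt{101})/2$ gives $S(i) = 0.9002488$ for every point.

## The sweep

`run_sweep()` walks an inclusive grid built by integer index
($r_i = r_{\min} + i\,\Delta r$, so floating-point accumulation can never
drop the endpoint). Defaults: 0.10 to 1.50 in steps of 0.02 — a
two-decimal optimum needs a step of at most 0.02, and 1.5 is beyond the
granularity at which marker-based annotation of skin wound data remains
interpretable. These bounds are configuration, not claims about any
particular dataset.

Per grid point the neighbor graph is clustered (igraph's Leiden by
default, modularity objective, five iterations; Louvain selectable) with
a seed derived as `seed + grid index`, so deleting one grid point never
shifts another's result. Labels are canonicalized to `0..k-1` by
descending cluster size. All randomness flows through R's
Mersenne-Twister generator (`set.seed` immediately before each
community-detection call), which makes every sweep bit-reproducible.

For large inputs the silhouette can be evaluated on a stratified
subsample (`silhouette_subsample`): every cluster contributes at least
one cell, quotas are proportional with largest-remainder rounding, and
remainder ties go to the lower cluster id. On simulated 5,000-cell data a
2,000-cell subsample moves the mean silhouette by well under 0.05.

## Surrounding pipeline stages

**QC.** Cells are kept when
$\texttt{min\_umi} \le \text{UMI} \le \texttt{max\_umi}$ and the
mitochondrial fraction is at most `max_mito_frac` (defaults 200, 2500,
10% — the conventional bounds for mouse skin droplet data, with strict
inequalities on the discarding side, so a cell at exactly 200 UMIs and
exactly 10% passes). Each discarded cell records one first-failing
reason, checked in the order `low_umi`, `high_umi`, `high_mito`.
Mitochondrial genes come from an explicit mask or the mouse `mt-` prefix.

**Normalization.** Depth scaling to 10,000 counts per cell followed by
`log1p`. This is a deliberately simple, deterministic normalizer — the
resolution-selection logic is normalization-agnostic by contract, and
`cmd_sweep()` accepts any replacement through its `normalizer` argument.
Regression-based variance-stabilizing normalizers are intentionally not
re-implemented here.

**HVG selection.** Genes ranked by variance of the log-normalized values,
top 3000 by default, ties to the lower gene index. Constant genes are
never selected.

**PCA.** 20 components by default. Genes are centered but *not* scaled
to unit variance: the log scale already makes genes comparable, and unit
scaling promotes pure-noise genes to the same weight as the informative
high-variance genes that HVG selection just ranked highly. On simulated
data this is not a cosmetic choice — with eight equally sized types even
a supervised nearest-true-centroid classifier in unit-scaled 20-PC space
misassigns 1.5–2% of cells, while center-only PCA brings sweep recovery
to ARI 0.98–0.99. Scaling remains available (`scale_genes = TRUE`).
Component signs follow a fixed convention (largest-magnitude loading
positive) so embeddings are identical across linear-algebra backends.

**Neighbor graph.** Each cell is connected to its 15 nearest Euclidean
neighbors; the directed edge set is symmetrized by union with unit
weights; distance ties break to the lower cell index. Jaccard
shared-neighbor weighting was evaluated during development and recovered
simulated ground truth less accurately than the plain union graph, so it
was not adopted.

## Annotation, dendrogram, composition

`score_clusters()` formalizes the common visual feature-plot workflow:
each marker gene's cluster-mean expression is z-scored across clusters,
a (cluster, type) score is the mean z-score over the type's markers
present in the data, and each cluster takes the argmax type (ties to
marker-table order; missing markers lower the reported coverage rather
than erroring). This numeric score is this package's own definition —
published annotations of this kind are typically made by eye — and the
scoring function is swappable. A marker panel for mouse skin wound
healing ships as the default table; two of its hair-follicle keratinocyte
entries are published under the same name with different markers, and the
packaged TSV keeps both, disambiguated by marker gene, rather than
guessing the intent.

`ward_dendrogram()` clusters cluster-centroid profiles (means of the
log-normalized HVG matrix by default, PCA space optionally) with the
Lance–Williams recurrence for Ward's method. Heights are on the
Euclidean scale (ward.D2 convention: two singletons merge at their
centroid distance), and ties in the minimum merge distance break to the
lowest node-index pair, making the merge order deterministic. No attempt
is made to reproduce any particular published dendrogram's height axis —
that depends on the expression space of the original pipeline — but the
implementation is required by the tests to agree step-by-step with a
brute-force re-derivation of the Ward objective, and with `hclust`'s
`ward.D2` heights. `dendrogram_to_newick()` emits branch lengths as
parent-minus-child heights with leaves at height 0, quoting names per the
Newick standard.

`composition_compare()` is exact counting: per-condition percentages sum
to 100 to within $10^{-9}$, types absent from a condition appear with
count 0, and rows are ordered by condition then pooled abundance.

## The simulator

`simulate_counts()` draws a negative-binomial (gamma–Poisson) mixture:
`k_types` latent types, `markers_per_type = 5` marker genes per type
elevated by a separation fold (low/medium/high = 2×/5×/20×), a baseline
mean of 0.5 per gene, shared dispersion 0.5
($\mathrm{Var} = \mu + 0.5\mu^2$, typical of UMI count overdispersion),
log-normal per-cell depth ($\sigma = 0.3$), and a block of 10
mitochondrial genes scaled so the expected mitochondrial fraction is 5%.
Conditions split the cells equally and each draws types from its own
proportion vector; `sim_config_wound_demo()` ships a two-condition
preset in which one type expands from 0.5% to 11% and another contracts
from 17% to 1.5%, for exercising the composition tooling.

What the generator emulates: distinct marker-defined types, depth
variation, overdispersion, mitochondrial content, condition shifts. What
it does not: gene–gene correlation beyond type structure, batch effects,
doublets, ambient RNA, or continuous trajectories. Passing the recovery
tests therefore demonstrates that the selection logic finds genuinely
present, well-separated discrete structure — not that it resolves the
harder ambiguities of real tissue.

## Validation problem sizes

The test suite and `scripts/acceptance.R` validate at sizes chosen to
exercise the method fully while remaining quick to rerun: recovery runs
use 1,500 cells × 1,000 genes with $k \in \{3, 5, 8\}$ at high
separation over five generator seeds each (the selected $k$ equals the
true $k$ and ARI against ground truth exceeds 0.95 in every run); the
null control uses 800 cells with a single type, where the best mean
silhouette over the whole grid stays below 0.1 — comfortably below the
0.25 bound frozen for it. Oracle-agreement checks use 50 random
instances of up to 200 points.

## Known limitations

* The silhouette criterion favors compact, well-separated clusters; on
  continuous differentiation trajectories it will prefer coarse
  partitions.
* Mean silhouette values on real count-derived PCA embeddings are small
  in absolute terms (0.05–0.3): the noise principal components
  contribute within-cluster spread. The *argmax over resolutions* is the
  meaningful output, not the absolute score.
* Exact parity with any specific Seurat/scanpy pipeline (SNN pruning,
  variance-stabilizing normalization internals) is a non-goal; the
  contract is the sweep-and-select logic.
* Alternative selection criteria (Calinski–Harabasz, Davies–Bouldin,
  stability resampling) are future work.
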