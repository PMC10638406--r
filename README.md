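# ppnfuse

Graph-based integration of multi-modal patient data for subtype
classification. `ppnfuse` builds an **individual network** (IN) for every
sample — a weighted graph over molecular features whose edge weights are
specific to that sample — converts the INs into a **Person-to-Person
Network** (PPN, a sample-by-sample similarity matrix), fuses several data
modalities at the feature, similarity or prediction stage, classifies with
a support vector machine that operates directly on the similarity matrix,
and scores with the macro F1. Downstream, it identifies differentially
co-expressed edges with empirical-Bayes moderated t-statistics and runs
preranked gene-set enrichment on the genes of the largest differential
module.

The package is aimed at computational biologists who have two (or more)
feature matrices over the same patients — e.g. RNA-Seq expression and a
histopathology embedding — plus a binary phenotype, and who want to know
whether *interactions between features*, not just feature values, carry
class information.

## The methods in brief

**Individual networks.** Two estimators over a selected edge set:

* *Node Product*: after min-max scaling each feature to [0, 1] on the
  training data, the weight of edge (i, j) in sample x is
  `e_ij^x = i'_x * j'_x`.
* *LIONESS*: with `e_all` the Pearson co-expression network over all N
  training samples and `e_wo(x)` the network with sample x removed,
  `e_ij^x = N (e_all - e_wo) + e_wo`. Held-out samples are handled one at
  a time: each is appended alone to the training panel and all networks of
  that temporary panel are recomputed.

All IN edge weights are rescaled to [0, 1] by one global affine map so the
ordering of weights is preserved across individuals.

**Feature selection.** Nodes by training-set standard deviation; edges by
the absolute difference `D = |A_class1 - A_class2|` of condition-specific
adjacencies, keeping edges above the `t_edge` quantile of D
(`t_edge ∈ {0.25, 0.5, 0.75}`); both thresholds tunable by stratified
5-fold cross-validation on the training set.

**PPNs.** At the node level: a scaled exponential affinity kernel
(K = 20, σ = 0.05), a Gaussian kernel (σ = 1000) or the Spearman
correlation between patients' feature vectors. At the edge level: the
edge-difference distance between two INs (the Frobenius norm of the
difference of their adjacency matrices, `sqrt(2 Σ (w_a - w_b)^2)`),
converted to similarities with the same affinity construction. All PPNs
are cosine-normalized, `PPN(x,y) / sqrt(PPN(x,x) PPN(y,y))`.

**Fusion.** Early (feature concatenation with per-modality node
selection), intermediate (elementwise average of PPNs, or Similarity
Network Fusion — an iterative cross-diffusion of the per-view similarity
graphs), or late (majority vote over per-modality node/edge predictions
with seeded random tie-breaks).

**Classification.** kernlab C-SVC on the normalized PPN as a precomputed
kernel (eigenvalue-clipped to positive semidefinite), cost selected from
`C = 10^k, k = 1..5`; performance is the unweighted mean of per-class F1
scores (macro F1).

## Worked example

The package ships a generator of two-modality datasets in which class
signal can be placed in node values, in co-expression structure, or both.
The run below plants a pure co-expression difference (a 10-feature block
with within-class correlation 0.8 versus 0.0, zero mean shift) and
compares the edges-level pipeline with a node-level baseline:

```r
library(ppnfuse)

fx <- fixture_suite(seed = 1)
ds <- fx$edge_signal_only          # 150 train / 50 test per class

cfg <- run_config(level = "edges", fusion = "none",
                  edge_method = "lioness", seed = 1)
cfg$modality  <- "a"
cfg$selection <- list(a = list(n_nodes = 50, t_edge = 0.5))
run_pipeline(ds, cfg)
#> Pipeline result (level=edges, fusion=none)
#>   macro F1: 0.8499
#>   per-class F1: class1=0.8454, class2=0.8544

cfg$level <- "nodes"; cfg$node_similarity <- "spearman"
run_pipeline(ds, cfg)
#> Pipeline result (level=nodes, fusion=none)
#>   macro F1: 0.4398
#>   per-class F1: class1=0.451, class2=0.4286
```

The edge-level pipeline recovers the interaction signal (macro F1 0.85)
while the node-level Spearman baseline stays at chance (0.44) — the
premise of the workflow made falsifiable. On the mirror-image fixture
(`node_signal_only`, a pure mean shift), the ordering reverses.

Interpretation on the same networks:

```r
nets  <- lioness_networks(ds$train$a, all_edges(colnames(ds$train$a)[1:20]))
stats <- moderated_t_stats(edge_matrix(nets), ds$labels_train)
head(stats[, c("id", "coef", "t", "adj_p")])
net   <- top_edges_network(stats, n = 50)
largest_component(net)
```

## Command line

A thin wrapper over the same functions lives at `inst/cli/ppnfuse.R`:

```sh
Rscript inst/cli/ppnfuse.R simulate --out data/ --seed 1 --fixture edge_signal_only
Rscript inst/cli/ppnfuse.R classify --config config.yaml
```

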