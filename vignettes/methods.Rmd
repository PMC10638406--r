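---
title: "Individual networks, patient similarity and multi-modal fusion: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual networks, patient similarity and multi-modal fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ppnfuse` asks a specific scientific question of multi-modal patient data:
do *interactions between features* carry class information beyond the
feature values themselves? Its answer is organized around two objects —
the individual network (IN), a per-sample weighted graph over features,
and the Person-to-Person Network (PPN), a sample-by-sample similarity
matrix derived from those graphs — and a classifier that never sees raw
features, only similarities to a reference panel. This vignette explains
the models, every tunable parameter that matters, what the synthetic data
generator does and does not emulate, and the places where the design was
genuinely open and a choice had to be made.

## Individual networks

Both IN estimators operate on a selected edge set over a selected node
set (see *Feature selection* below).

**Node Product.** Each feature is min-max scaled to [0, 1] using training
minima and maxima; the weight of edge $(i, j)$ in sample $x$ is
$e^x_{ij} = i'_x \, j'_x$. Held-out samples are scaled with the *training*
ranges and clipped back into [0, 1]; without clipping, a test value below
the training minimum would yield negative "scaled" values and products
outside the weight space. This estimator is cheap — one multiplication
per edge — which is why the cross-validated feature-selection loop always
uses it.

**LIONESS.** With $e^\alpha$ the aggregate co-expression network over all
$N$ training samples and $e^{\alpha - x}$ the aggregate with sample $x$
held out, sample $x$'s network is
$e^x = N (e^\alpha - e^{\alpha-x}) + e^{\alpha-x}$. The aggregate model is
the Pearson correlation between features (the conventional default; any
symmetric edge function can be plugged in via `agg_fun`). The defining
algebraic property — if the aggregate is a per-sample mean of any edge
statistic, the formula returns each sample's own statistic exactly — is
the module's primary oracle and is tested to machine precision. For the
Pearson aggregate the leave-one-out networks are computed from running
sums (sum, sum of squares, cross-products), which makes the whole panel
cost $O(N \cdot |\text{edges}|)$ rather than $N$ full correlation
matrices; the fast path is verified against the naive recomputation.

**Held-out samples under LIONESS.** The IN of a new sample depends on the
reference panel, and adding many new samples at once would perturb the
training INs. Each test sample is therefore appended *alone* to the
training panel; all $N{+}1$ networks of that temporary panel are
recomputed, and the test sample's graph distances are taken against the
panel's refreshed training networks. Whether the temporary panel's
networks should be rescaled jointly with the original training networks
or per panel is not determined by the method; we rescale with the
*training* global minimum and maximum (clipping overflow), because a
single shared affine map is what keeps edge-weight orderings comparable
across individuals.

**Global edge scaling.** All training IN weights are mapped to [0, 1] by
one affine map built from the global minimum and maximum across all
networks. A per-network map would destroy between-individual ordering;
the shared map preserves it exactly (rank correlation 1, tested).

## Feature selection

Nodes are ranked by training-set standard deviation (ties broken
lexicographically so runs are reproducible). Edges are ranked by the
absolute difference of two *condition-specific networks* — one aggregate
adjacency per class, built on that class's training samples only — and
kept when the difference strictly exceeds the `t_edge` quantile
(0.25 / 0.5 / 0.75 on the default grid) of all differences; retained sets
are therefore nested across thresholds. Both knobs are tuned by
stratified 5-fold cross-validation inside the training set, scoring
held-out macro F1 with the fast Node Product path.

*Open choice — what is a condition network?* Two readings are
implemented: the class-wise Pearson correlation network (`"pearson"`,
default) and the class-mean Node Product network
(`"mean_node_product"`). The Pearson version is the default because the
mean-product difference is nearly blind to a pure co-expression
difference: for a correlation-0.8-versus-0 block at 150 samples per
class, the between-class difference in mean products (~0.02 on the
[0, 1] product scale) is the same order as its sampling noise, whereas
the correlation difference (0.8) is several-fold its standard error. In
simulation, the Pearson condition networks rank every planted edge first;
the mean-product networks scatter them through the list.

## Person-to-Person Networks

Node-level similarities: (i) the scaled exponential affinity kernel —
each sample's bandwidth is the mean Euclidean distance to its $K = 20$
nearest neighbours, and the affinity of $x, y$ is the normal density of
their distance at scale $\sigma \varepsilon_{xy}$ with
$\varepsilon_{xy} = (\mu_x + \mu_y + d_{xy})/3$ and $\sigma = 0.05$;
(ii) the Gaussian kernel $\exp(-d^2/\sigma^2)$ with $\sigma = 1000$
(appropriate for high-dimensional expression data, where squared
distances are of order $10^5$); (iii) the Spearman correlation between
the two samples' feature vectors, which is invariant to any strictly
monotone per-sample transform and may be negative.

Edge-level similarity starts from the **edge-difference distance**
between two INs: the Frobenius norm of the difference of their full
symmetric adjacencies, $\sqrt{2 \sum_e (w^a_e - w^b_e)^2}$ — a true
metric (checked on random triples). The conversion from distances to
similarities is an open design point; we reuse the same scaled
exponential affinity construction as the node level, with one important
difference: the bandwidth multiplier defaults to the construction's
conventional $\sigma = 0.5$ rather than the node level's empirical 0.05.
At $\sigma = 0.05$ the kernel is so sharp relative to typical
edge-distance spreads that the similarity matrix is numerically almost
diagonal; after cosine normalization it approaches the identity and the
classifier cannot generalize (on a planted-signal fixture with an
*oracle* edge set, macro F1 stays near 0.5 at $\sigma = 0.05$ and
reaches ~0.94 at $\sigma = 0.5$). Both values, and a plain Gaussian or
negative-distance conversion, are exposed as parameters.

All PPNs are cosine-normalized,
$PPN(x,y)/\sqrt{PPN(x,x)\,PPN(y,y)}$, giving unit self-similarity;
rectangular test-by-train blocks use each test sample's own
self-similarity under the same similarity function. Combining node and
edge information averages the two *normalized* PPNs elementwise.

## Fusion and classification

*Early*: per-modality node selection, then column concatenation with
modality-tagged feature IDs, so later edge selection can pair features
across modalities. *Intermediate*: elementwise average of the normalized
per-modality PPNs, or Similarity Network Fusion — per view, a
row-normalized full kernel (diagonal 1/2) and a sparse K-nearest-
neighbour kernel; iterate $P_v \leftarrow S_v \,\overline{P_{w \ne v}}\,
S_v^\top$ with renormalization, 20 iterations with an early stop when the
fused matrix changes by less than $10^{-8}$ in max norm (the update has
no stated convergence rule, so the cap and tolerance are package
choices). SNF has no canonical rectangular extension, so the fused graph
is built over training and test samples jointly — transductive but
label-free — and the train/test blocks are sliced afterwards. *Late*:
majority vote over the four per-modality node-level and edge-level
predictions; exact ties are resolved uniformly at random from a seeded
stream, and the per-set agreement rates (tied samples excluded) are
reported as modality contributions.

The classifier is a C-SVC on the normalized PPN as a precomputed kernel.
Spearman and averaged PPNs can be indefinite, and kernel-solver behaviour
on indefinite matrices is implementation-defined, so the matrix is first
clipped to positive semidefinite by zeroing negative eigenvalues — a
no-op on already-PSD inputs (tested). The cost grid is
$C = 10^k, k = 1..5$. Two selection protocols are implemented: stratified
5-fold cross-validated macro F1 inside the training set (`"cv"`, the
default, the defensible reading) and training-set performance
(`"train"`, the literal reading; with the smallest-C tie-break this
permits an exact early stop once training F1 reaches 1, since no larger
C can strictly win). Ties always go to the smallest C. Macro F1 is the
unweighted mean of per-class F1 with the convention F1 = 0 for a class
with no true and no predicted positives.

## Interpretation

The edge matrix (edges × samples) is analysed by per-edge linear models:
for the two-group design the coefficient is the difference of group
means, the residual variance $s^2_e$ has $d = n_1 + n_2 - 2$ degrees of
freedom, and the variances are shrunk towards a common prior,
$\tilde{s}^2_e = (d_0 s_0^2 + d s^2_e)/(d_0 + d)$, with $(d_0, s_0^2)$
estimated across edges by moment matching on $\log s^2$ (the package
computes the per-edge statistics itself and delegates the prior
estimation to `limma::squeezeVar`; tests verify agreement both with a
direct numerical solve of the moment equations and with the full
limma lmFit/eBayes pipeline, and the $d_0 = 0$ override reproduces the
ordinary two-sample t exactly). P-values are two-sided on $d + d_0$
degrees of freedom; the multiple-testing correction is
Benjamini–Hochberg, a package choice labelled in the output (the method
source does not state one). The top-50 edges (by $|t|$) form an
annotated graph — edge direction and $|$coefficient$|$ as colour/width
keys, node colours from a parallel gene-level moderated-t analysis
masked to white below $|t| < 1.5$ — whose largest connected component
supplies the gene list for preranked GSEA (weighted running-sum
statistic, exponent 1, gene-label permutation null with 5000
permutations, minimum set size 10, BH q-values; executed by fgsea and
verified against a brute-force running-sum oracle).

One caveat the test suite makes explicit: edges are *selected* for large
between-class differences, so re-testing the same contrast on the same
samples inflates the edge statistics by construction. The type-I
property holds — and is tested — against permuted labels; on real data
the edge p-values after selection should be read as descriptive
rankings, not calibrated error rates.

## The synthetic data generator

`simulate_dataset()` draws class-conditional multivariate Gaussians over
the concatenated feature space of two modalities: a mean shift on
designated features plants *node-level* signal; an equicorrelated block
whose within-block correlation differs between classes plants
*edge-level* signal; a cross-modality block correlation plants signal
only a cross-modality edge can see. Requested covariances are validated
by Cholesky factorization, and an equicorrelated block with
cross-correlation $c$ is positive definite only when $c < 1 - \rho$ —
the two-signal fixture uses $\rho = 0.6$, $c = 0.35$ for this reason.
`fixture_suite()` fixes four scenarios (node-only, edge-only, both,
null) at 150 training and 50 test samples per class and 50 features per
modality — large enough for the correlation structure to be estimable,
small enough that the full suite runs in minutes on one CPU; the same
scales are used by the acceptance script.

What passing tests do and do not show: the generator produces Gaussian,
homoscedastic, batch-free data with block-structured signal, so the
tests demonstrate that each estimator recovers the *kind* of signal it
targets and that the pipeline's contracts hold end to end. Real RNA-Seq
counts (overdispersion, library-size effects), histology-embedding
geometry, batch structure and label noise are deliberately not emulated;
performance numbers on fixtures say nothing quantitative about any real
cohort.

## Numerical and degenerate-input choices

Cross-sample Euclidean distances are computed by `stats::dist` on the
stacked matrix rather than the expanded-square formula, which loses all
significant digits for near-identical samples and broke the
"a training sample embedded as a test sample reproduces its training
row" invariant. Constant features are an error at min-max scaling (the
map is undefined) with a pointer to node selection; zero-variance
features are an error in any correlation network; identical condition
networks make every edge difference zero and edge selection fails with
an instruction to lower the threshold; an all-equal weight collection
cannot be globally scaled. Quantiles use R's default (type 7), ties at
the threshold are excluded ("strictly above"), and every ordering in the
package breaks ties lexicographically so that equal inputs give
byte-identical outputs. All randomness — fold splits, tie-breaks, GSEA
permutations, simulation draws — flows from one master seed through
named substreams, and two runs with the same configuration produce
byte-identical artifact files (tested).

## Known limitations

Edge selection is defined for exactly two classes (the
difference-of-adjacencies rule does not generalize without new
conventions); multiclass classification is available in principle
through the kernel machine but is untested. The LIONESS test-sample
protocol costs one panel recomputation per test sample. SNF fusion is
transductive as implemented. The moderated-t design matrix accepts only
the two-group contrast. None of the graph distances beyond the
edge-difference metric (Jaccard, DeltaCon, spectral) are implemented.
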