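---
title: "Supervised PCA classification of nested molecular subtypes"
author: "subtypePCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised PCA classification of nested molecular subtypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subtypePCA)
```

# The model

`subtypePCA` assigns an expression profile to one of a set of
hierarchically nested molecular subtypes. The classifier is defined by
three ingredients supplied by the user (or by the synthetic generator):

1. a **reference cohort**: a genes × samples matrix of normalized
   expression with a leaf-subtype label per sample;
2. a **subtype hierarchy**: a rooted tree in which every node splits its
   samples into ≥ 2 child subtypes (the default is the two-level glioma
   scheme, root → {O, G}, O → {OA, OB}, G → {GA1, GA2, GB1, GB2});
3. a **classifier gene list per node** — supervision enters the PCA only
   through this gene selection, never through the decomposition itself.

At a node, the unknown profile is restricted to the node's classifier
genes and, by default, *merged* into the node's reference submatrix. A
PCA is fitted on the merged matrix with samples as observations: genes
are centered by their mean over samples and not scaled (the covariance,
not correlation, convention of the classical PRINCOMP routine). The
proportions of total variance explained per component form the weight
vector $w$, and distances between samples are measured in score space as

$$d(U, V) = \sqrt{\sum_k w_k (u_k - v_k)^2},$$

so that components carrying more of the cohort's variation dominate the
geometry. We read the weighted Euclidean distance with the square root;
the membership probability below is not invariant to squaring, so this
choice is pinned by unit tests against hand-evaluated values.

For each child subtype $C_i$ the centroid $\bar{C}_i$ is the
component-wise mean of that child's *reference* scores (the unknown is
excluded from all centroid and dispersion computations even in merge
mode, so its own position never biases the statistics it is judged
against). The unknown's assignment and confidence are then

$$p(U, C_i) = \frac{d(U, \bar{C}_i)^{-1}}{\sum_j d(U, \bar{C}_j)^{-1}},
\qquad
r_D(U, C_i) = \frac{d(U, \bar{C}_i)}{\sigma_i},$$

with $\sigma_i$ the standard deviation of the child's own
sample-to-centroid distances. $p$ is an ordinal, inverse-distance
confidence share — it is not a generative posterior, and the package
makes no attempt to calibrate it. $r_D$ expresses how far outside a
subtype's own cloud the unknown sits; $r_D \approx 1$ is typical for a
genuine member, and large values flag outliers. The unknown is assigned
to the child with minimal distance, and classification recurses into
that child's subtree until a leaf is reached.

## Assumptions

The method assumes that (a) reference and unknown profiles come from the
same normalization pipeline (this cannot be enforced, only documented);
(b) each subtype forms a single, roughly convex cloud in the classifier
gene space, so a centroid summarizes it; and (c) the classifier gene
lists actually separate the children at their node. Heavily multimodal
subtypes or batch-shifted unknowns violate these assumptions and will
surface as low probabilities or large $r_D$ rather than as errors.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `mode` | `"merge"` | merge the unknown into the reference before PCA, or project it onto a basis frozen on the reference |
| `nComponents` | `"all"` | components retained and used in every distance |
| `sigmaDivisor` | `"n"` | population vs `"n-1"` sample standard deviation for $\sigma_i$ |
| `outlierThreshold` | 3 | flag if the assigned child's $r_D$ exceeds this at any level |
| `coverageThreshold` | 0.05 | tolerated fraction of classifier genes missing from an input |

**Merge versus project.** Merging makes the basis — and hence every
reported number — depend slightly on the unknown itself, which is the
historical behavior of PCA-merge classifiers and the default here.
Projection onto a frozen reference basis is offered for users who need
reference statistics that are strictly independent of the query; on
well-separated data the two agree (tested).

**Components in distances.** All retained components enter the distance,
each weighted by its variance proportion; nothing is truncated. The
weighting already discounts minor components smoothly, so truncation
would mostly re-discount what $w$ discounts. `nComponents` allows an
explicit cut for users who want one. Whether $\sigma_i$ should live in a
truncated space was genuinely open; we compute it in the same (full)
space as the unknown's distances so that $r_D$ compares like with like.

**$\sigma$ divisor.** The dispersion is a population standard deviation
(divide by $n$) by default — the subtype's reference samples are treated
as the cloud itself, not as a sample from a larger one. `"n-1"` is a
flag away for users who prefer the unbiased estimator; with the child
sizes in practice the difference is a few percent of $r_D$.

**Outlier threshold.** $r_D$ is defined by the method; a cutoff is not.
The default of 3 follows the familiar three-sigma convention on the
distance scale. The flag never suppresses the assignment, and raw $r_D$
values are always reported so users can apply their own rule.

**Missing genes.** Cross-platform gene lists make occasional absence
inevitable. Below the coverage threshold, missing genes are dropped from
both reference and unknown for that prediction with a warning; at or
beyond it, the prediction refuses and lists the missing genes.

# Numerical choices

- The decomposition is computed by SVD of the centered matrix rather
  than by eigendecomposition of an explicit covariance matrix, for
  numerical stability; agreement with a brute-force covariance
  eigendecomposition is a test, not an implementation detail.
- PCA signs are arbitrary, so each basis column is deterministically
  flipped to make its largest-magnitude loading positive; all equality
  tests are stated up to this convention. Fits are bit-reproducible on
  identical input.
- Exactly one zero distance receives probability 1 (the limit of the
  formula); several simultaneous zeros mean coincident centroids and
  raise an error, as does $\sigma_i = 0$ (all child samples coincide)
  and an all-identical input matrix.
- Tied minimum distances are broken deterministically in favor of the
  first child in the node's declared order, with a warning attached.
- Scale equivariance: rescaling all scores by $c > 0$ scales every $d$
  and $\sigma$ by $c$ and leaves $p$ and $r_D$ unchanged (tested).

# The synthetic cohort generator

Published reference cohorts for this family of classifiers are not
redistributable, so the package ships a seeded generator that emulates
one structurally. Each hierarchy node receives its own disjoint set of
classifier genes (default 30), split into one block per child; samples
under a child have that block's genes shifted up by `deltaMu` expression
units (default 4), and every value carries i.i.d. Gaussian noise with
standard deviation `sigmaE` (default 1). Background genes (default 100)
are pure noise. Defaults — 20 samples per leaf, 6 leaves — give a cohort
of 120 profiles, the same order of magnitude as the glioma reference
cohorts this design descends from, with block separations of several
noise standard deviations, i.e. clearly but not trivially separable
classes.

`makeUnknown()` draws a query from a leaf's generative distribution. Its
`displacement` argument shifts every gene by `displacement * sigmaE`
with an independent random sign — a random hypercube-corner direction —
so the probe moves about `displacement * sigmaE` per gene within *every*
node's classifier subspace. A single random direction in the full gene
space would project to only a small fraction of each node's subspace and
be further discounted by the variance weights, making "displaced by
10σ" fail to mean "an outlier at every level"; the per-gene reading
makes the displacement parameter do what outlier tests need it to do.

The generator exists to test the mathematics, not to imitate biology:
it produces homoskedastic Gaussian clusters with exactly disjoint,
exactly informative gene sets. Real microarray or RNA-seq data have
heavy tails, gene-gene correlation, batch structure and imperfect
classifier lists. Passing tests on synthetic data therefore demonstrate
correctness of the algorithm and its implementation — not expected
accuracy on any real cohort.

# Evaluation harnesses and problem sizes

`evaluateTrainTest()` classifies an independent cohort against a
reference built from a training cohort; `evaluateLOO()` holds each
reference sample out of basis, centroids and dispersions for its own
prediction. Accuracy at a node is computed only over samples whose
*true* path traverses that node (a true-OA sample never enters the
G-node's accuracy), matching how per-level accuracy tables are usually
reported; the two protocols correspond to validating a fixed reference
against external truth versus measuring a cohort's internal
consistency.

On the default synthetic conditions the expected qualitative pattern —
accuracy no worse at the 2-way root than at the 2-way O node than at the
4-way G node — is reproduced across replicate seeds. The test-suite and
acceptance computations use cohorts of 120 reference samples (20 per
leaf) with 30 classifier genes per node, and smaller 36-sample cohorts
for unit tests; these sizes make the full suite run in about a minute
while keeping every per-child statistic well-defined.

# Known limitations

- Membership probabilities are shares of inverse distance; two children
  at distances 1 and 3 get 0.75/0.25 regardless of how compact either
  cloud is. Use $r_D$ alongside $p$.
- In merge mode, predictions for the same unknown against the same
  bundle are reproducible, but adding unrelated samples to the reference
  changes the basis and hence all reported numbers slightly.
- Exact string matching of gene identifiers is deliberate; probe-set or
  symbol mapping across platforms is the user's responsibility.
- The hierarchy must branch at every node (≥ 2 children) and every child
  needs ≥ 2 reference samples for $\sigma_i$ to exist; degenerate nodes
  are a build-time error, not a silent fallback.
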