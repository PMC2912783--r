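# subtypePCA

Hierarchical molecular subtype classification of expression profiles by
supervised principal component analysis.

## The problem

Molecular tumor classification schemes assign a patient's expression
profile to one of a set of predefined subtypes using fixed lists of
classifier genes. For diffuse gliomas, a widely used scheme stratifies
profiles into six hierarchically nested subtypes: a first split into
oligodendroglioma-enriched (**O**) and glioblastoma-enriched (**G**)
types, then **O → {OA, OB}** and **G → {GA1, GA2, GB1, GB2}**, with a
separate classifier gene list at each level. `subtypePCA` is a general,
reusable implementation of that classification engine for anyone with a
labeled reference cohort, per-level classifier gene lists, and new
profiles to assign — at any level count and with any subtype labels, not
only the glioma scheme it ships as a default.

## The method

At each hierarchy node the unknown profile is **merged into the reference
cohort**, restricted to the node's classifier genes, and a PCA is fitted
(samples as observations, genes mean-centered, no variance scaling — the
classical PRINCOMP convention). Supervision enters through the gene
lists, not the decomposition. With per-component variance proportions
*w*, the classifier computes:

- the **weighted Euclidean distance** from the unknown *U* to each child
  subtype centroid *C̄ᵢ* in score space:
  *d(U, C̄ᵢ) = √( Σₖ wₖ (uₖ − c̄ᵢₖ)² )*
- the **membership probability**
  *p(U, Cᵢ) = d(U, C̄ᵢ)⁻¹ / Σⱼ d(U, C̄ⱼ)⁻¹* — an inverse-distance
  confidence share over the node's children,
- the **relative distance** *r_D(U, Cᵢ) = d(U, C̄ᵢ) / σᵢ*, where *σᵢ* is
  the standard deviation of the child's own sample-to-centroid distances
  — an outlier score in units of the subtype's dispersion.

The unknown is assigned to the nearest child (ties go to the first
declared child, with a warning) and the descent recurses until a leaf.
A profile whose assigned-child *r_D* exceeds a threshold (default 3) at
any level is flagged as an outlier; the assignment is reported anyway.

## Worked example

```r
library(subtypePCA)

# a seeded synthetic cohort with the default 6-leaf nested structure:
# 20 samples/leaf, 30 classifier genes/node, 4-unit child separation
spec   <- simulationSpec(nPerLeaf = 20, genesPerNode = 30, seed = 42)
cohort <- simulateCohort(spec)
bundle <- buildReference(cohort$reference, spec@hierarchy,
                         cohort$classifierSets)

u   <- makeUnknown(spec, "GA2")          # a new profile drawn from GA2
res <- classifyHierarchical(bundle, u, sampleId = "patient_1")
res
#> PredictionResult for 'patient_1': G -> GA2
#>   final subtype: GA2
#>   root   p(O)=0.030, p(G)=0.970
#>   G      p(GA1)=0.082, p(GA2)=0.742, p(GB1)=0.087, p(GB2)=0.089

nodeResults(res)$G
#> NodeResult 'G': assigned GA2
#>     distance probability relativeDistance
#> GA1   8.1364      0.0821          32.6668
#> GA2   0.9010      0.7417           2.9836
#> GB1   7.7021      0.0868          22.8522
#> GB2   7.4743      0.0894          23.3915
```

At the root the profile sits firmly in the G cloud (p = 0.97); among the
four G subtypes it is closest to GA2 (distance 0.90 versus ≥ 7.5 for the
others, hence p = 0.74), and its relative distance to GA2 (≈ 3 σ) is far
below its relative distance to any other subtype, so it is not an
outlier with respect to its assigned class. `writeReportJSON()`,
`writeReportText()` and `writePCCoordinates()` export the same numbers,
plus first-3-PC coordinates of the unknown and every reference sample,
for records and plotting.

Real data enter the same way: `readGCT()` / `readTSVMatrix()` for the
expression matrices, `readLabels()` for the reference subtype labels,
`readGeneList()` for each node's classifier genes, then
`LabeledReference()` and `buildReference()`. A bundle serializes to a
single JSON file (`writeReferenceBundle()`), and `evaluateLOO()` /
`evaluateTrainTest()` quantify per-level assignment accuracy.

A command-line wrapper with subcommands `build`, `predict`, `simulate`
and `evaluate` is installed at
`system.file("cli", "subtype", package = "subtypePCA")`.

## Scope

Expression values are taken as already normalized; gene identifiers are
matched as exact strings; missing values are an error. Deriving
classifier gene lists from data is out of scope — the lists are inputs.
The membership probability is an ordinal confidence share, not a
calibrated posterior. See the methods vignette
(`vignettes/supervised-pca-classification.Rmd`) for the model,
parameter choices and limitations.
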