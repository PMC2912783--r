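#' Create a synthetic cohort specification
#'
#' Parameters of the seeded generator emulating a nested reference cohort:
#' Gaussian clusters per subtype over disjoint per-node classifier gene
#' sets, plus pure-noise background genes. Within each node, every child
#' subtype receives an exclusive block of that node's classifier genes
#' shifted upward by `deltaMu` expression units for its own samples, so
#' sibling means differ by `deltaMu` per block gene; all values carry
#' i.i.d. Gaussian noise with standard deviation `sigmaE`.
#'
#' @param hierarchy a [SubtypeHierarchy-class] (default:
#'   [defaultHierarchy()]).
#' @param nPerLeaf samples per leaf subtype (default 20).
#' @param genesPerNode classifier genes per node (default 30).
#' @param deltaMu between-child per-gene mean shift, expression units
#'   (default 4).
#' @param sigmaE within-child noise standard deviation (default 1).
#' @param nBackground non-classifier noise genes (default 100).
#' @param seed integer seed; all draws are reproducible from it.
#' @return A [SimulationSpec-class].
#' @export
simulationSpec <- function(hierarchy = defaultHierarchy(), nPerLeaf = 20,
                           genesPerNode = 30, deltaMu = 4, sigmaE = 1,
                           nBackground = 100, seed = 1) {
  new("SimulationSpec", hierarchy = hierarchy,
      nPerLeaf = as.integer(nPerLeaf),
      genesPerNode = as.integer(genesPerNode), deltaMu = as.numeric(deltaMu),
      sigmaE = as.numeric(sigmaE), nBackground = as.integer(nBackground),
      seed = as.integer(seed))
}

# Gene ids and the per-leaf mean vector implied by a spec. Each node's
# classifier genes are split into equal child blocks; a leaf's mean is
# deltaMu on the blocks of every (node, child) pair on its path, 0
# elsewhere.
.simLayout <- function(spec) {
  h <- spec@hierarchy
  ids <- nodeIds(h)
  geneSets <- lapply(ids, function(id)
    sprintf("%s.cg%03d", id, seq_len(spec@genesPerNode)))
  names(geneSets) <- ids
  background <- if (spec@nBackground > 0L)
    sprintf("bg%04d", seq_len(spec@nBackground)) else character()
  allGenes <- c(unlist(geneSets, use.names = FALSE), background)
  leaves <- leafLabels(h)
  means <- matrix(0, length(allGenes), length(leaves),
                  dimnames = list(allGenes, leaves))
  for (id in ids) {
    cls <- childLabels(h, id)
    b <- spec@genesPerNode %/% length(cls)
    rollup <- leafToChildMap(h, id)
    for (j in seq_along(cls)) {
      block <- geneSets[[id]][((j - 1L) * b + 1L):(j * b)]
      underChild <- names(rollup)[rollup == cls[j]]
      means[block, underChild] <- spec@deltaMu
    }
  }
  list(geneSets = geneSets, background = background, allGenes = allGenes,
       means = means)
}

#' Simulate a labeled reference cohort
#'
#' Draws `nPerLeaf` samples per leaf subtype from the Gaussian cluster
#' model described in [simulationSpec()]. The output satisfies every
#' precondition of [buildReference()] by construction and is byte-identical
#' across calls with the same spec.
#'
#' @param spec a [SimulationSpec-class].
#' @return list with `reference` (a [LabeledReference-class]) and
#'   `classifierSets` (named list of per-node gene-id vectors).
#' @examples
#' cohort <- simulateCohort(simulationSpec(nPerLeaf = 5, genesPerNode = 10))
#' table(subtypeLabels(cohort$reference))
#' @export
simulateCohort <- function(spec) {
  validObject(spec)
  layout <- .simLayout(spec)
  leaves <- leafLabels(spec@hierarchy)
  labels <- rep(leaves, each = spec@nPerLeaf)
  sampleIds <- sprintf("S%03d", seq_along(labels))
  m <- withr::with_seed(spec@seed, {
    noise <- matrix(stats::rnorm(length(layout$allGenes) * length(labels),
                                 sd = spec@sigmaE),
                    nrow = length(layout$allGenes))
    layout$means[, labels, drop = FALSE] + noise
  })
  dimnames(m) <- list(layout$allGenes, sampleIds)
  list(reference = LabeledReference(m, setNames(labels, sampleIds)),
       classifierSets = layout$geneSets)
}

#' Draw an unknown sample from a leaf's generative distribution
#'
#' Produces one expression vector over all cohort genes, drawn around the
#' leaf's true mean profile with noise `sigmaE`. A non-zero `displacement`
#' additionally shifts every gene by `displacement * sigmaE` with an
#' independent random sign — a random hypercube-corner direction — so that
#' the probe is displaced by about `displacement * sigmaE` per gene within
#' every node's classifier subspace, making it an outlier at every
#' hierarchy level. Used to construct probes for outlier tests.
#'
#' @param spec a [SimulationSpec-class].
#' @param leafLabel leaf subtype to draw from.
#' @param displacement outlier displacement in multiples of `sigmaE`
#'   (default 0).
#' @param seed seed for this draw (default `spec@seed + 1`).
#' @return named numeric expression vector over all cohort genes.
#' @export
makeUnknown <- function(spec, leafLabel, displacement = 0,
                        seed = spec@seed + 1L) {
  validObject(spec)
  layout <- .simLayout(spec)
  if (!leafLabel %in% leafLabels(spec@hierarchy))
    .stopLabel("'%s' is not a leaf (valid: %s)", leafLabel,
               paste(leafLabels(spec@hierarchy), collapse = ", "))
  if (displacement < 0) .stopParameter("displacement must be >= 0")
  mu <- layout$means[, leafLabel]
  withr::with_seed(as.integer(seed), {
    x <- mu + stats::rnorm(length(mu), sd = spec@sigmaE)
    if (displacement > 0) {
      signs <- sample(c(-1, 1), length(mu), replace = TRUE)
      x <- x + displacement * spec@sigmaE * signs
    }
    setNames(x, layout$allGenes)
  })
}

setMethod("show", "SimulationSpec", function(object) {
  cat("SimulationSpec:", length(leafLabels(object@hierarchy)),
      "leaves x", object@nPerLeaf, "samples;",
      object@genesPerNode, "classifier genes/node;",
      object@nBackground, "background genes\n")
  cat(sprintf("  deltaMu = %g, sigmaE = %g, seed = %d\n", object@deltaMu,
              object@sigmaE, object@seed))
})
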