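#' @import methods
#' @importFrom stats rnorm sd var setNames cor
#' @importFrom utils packageVersion head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame
NULL

#' Subtype hierarchy
#'
#' A rooted tree of classification nodes. Each node carries an identifier,
#' an ordered vector of child subtype labels, and for each child either the
#' identifier of the child node (internal child) or `NA` (leaf child).
#'
#' @slot nodes named list; one element per node. Each element is a list with
#'   components `nodeId` (character), `children` (character vector of child
#'   labels, length >= 2) and `childNode` (named character vector parallel to
#'   `children`; `NA_character_` marks a leaf child).
#' @slot rootId identifier of the root node.
#'
#' @seealso [SubtypeHierarchy()], [defaultHierarchy()]
#' @export
setClass("SubtypeHierarchy",
  representation(nodes = "list", rootId = "character"))

setValidity("SubtypeHierarchy", function(object) {
  msg <- character()
  nodes <- object@nodes
  if (length(object@rootId) != 1L || !object@rootId %in% names(nodes))
    return("rootId must name an element of nodes")
  for (nd in nodes) {
    if (!all(c("nodeId", "children", "childNode") %in% names(nd)))
      return("each node needs nodeId, children, childNode")
    if (length(nd$children) < 2L)
      msg <- c(msg, sprintf("node '%s' has fewer than 2 children", nd$nodeId))
    if (length(nd$childNode) != length(nd$children))
      msg <- c(msg, sprintf("node '%s': childNode/children length mismatch",
                            nd$nodeId))
    internal <- nd$childNode[!is.na(nd$childNode)]
    if (!all(internal %in% names(nodes)))
      msg <- c(msg, sprintf("node '%s' references unknown child nodes",
                            nd$nodeId))
  }
  # every non-root node reachable by exactly one path; no cycles
  seen <- character()
  walk <- function(id) {
    if (id %in% seen) stop("cycle or re-used node: ", id, call. = FALSE)
    seen <<- c(seen, id)
    for (cid in nodes[[id]]$childNode)
      if (!is.na(cid)) walk(cid)
  }
  ok <- tryCatch({ walk(object@rootId); TRUE },
                 error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) msg <- c(msg, ok)
  else if (!setequal(seen, names(nodes)))
    msg <- c(msg, "unreachable nodes present")
  # leaf labels unique across the tree
  leaves <- unlist(lapply(nodes, function(nd) nd$children[is.na(nd$childNode)]))
  if (anyDuplicated(leaves))
    msg <- c(msg, "duplicate leaf labels across nodes")
  if (length(msg)) msg else TRUE
})

#' Labeled reference cohort
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay `exprs`
#' holds normalized expression (genes x samples) and whose `colData` carries
#' a `subtype` column of leaf labels. Expression values must be finite and
#' gene/sample identifiers unique.
#'
#' @seealso [LabeledReference()]
#' @export
setClass("LabeledReference", contains = "SummarizedExperiment")

setValidity("LabeledReference", function(object) {
  msg <- character()
  if (!"subtype" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'subtype' column")
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    m <- SummarizedExperiment::assay(object, "exprs")
    chk <- tryCatch({ .checkExprMatrix(m); NULL },
                    error = function(e) conditionMessage(e))
    if (!is.null(chk)) msg <- c(msg, chk)
  }
  if (length(msg)) msg else TRUE
})

#' Principal-component projection
#'
#' Result of a supervised PCA fit: orthonormal basis (gene-space
#' eigenvectors, one column per retained component), per-sample scores,
#' the per-gene centering vector, and the weight vector of per-component
#' variance proportions used to weight distances.
#'
#' @slot basis genes x components orthonormal matrix (columns of U).
#' @slot scores samples x components coordinate matrix.
#' @slot center per-gene mean over the fitted samples.
#' @slot weights per-component proportion of total variance, each in
#'   `[0, 1]`;
#'   sums to 1 when all components are retained.
#' @slot nComponents number of retained components.
#' @export
setClass("PCAProjection",
  representation(basis = "matrix", scores = "matrix", center = "numeric",
                 weights = "numeric", nComponents = "integer"))

setValidity("PCAProjection", function(object) {
  msg <- character()
  k <- object@nComponents
  if (ncol(object@basis) != k || ncol(object@scores) != k ||
      length(object@weights) != k)
    msg <- c(msg, "component count mismatch across slots")
  if (nrow(object@basis) != length(object@center))
    msg <- c(msg, "basis rows must match center length")
  if (any(object@weights < -1e-12 | object@weights > 1 + 1e-12))
    msg <- c(msg, "weights must lie in [0, 1]")
  if (sum(object@weights) > 1 + 1e-9)
    msg <- c(msg, "weights must sum to at most 1")
  if (length(msg)) msg else TRUE
})

#' Per-node reference model
#'
#' The classifier-gene expression of the reference samples belonging to one
#' hierarchy node, together with the roll-up of each sample's leaf label to
#' a child label of the node. Principal-component centroids and dispersions
#' are recomputed per prediction (the basis changes whenever an unknown
#' sample is merged), so the model stores raw expression, not scores.
#'
#' @slot nodeId hierarchy node identifier.
#' @slot classifierGenes classifier gene identifiers for this node (after
#'   any coverage filtering at build time).
#' @slot refMatrix classifier genes x node samples expression matrix.
#' @slot childLabels ordered child subtype labels of the node.
#' @slot childAssign named character vector mapping each node sample to its
#'   child label.
#' @export
setClass("ReferenceModel",
  representation(nodeId = "character", classifierGenes = "character",
                 refMatrix = "matrix", childLabels = "character",
                 childAssign = "character"))

setValidity("ReferenceModel", function(object) {
  msg <- character()
  if (!identical(rownames(object@refMatrix), object@classifierGenes))
    msg <- c(msg, "refMatrix rows must equal classifierGenes")
  if (!setequal(names(object@childAssign), colnames(object@refMatrix)))
    msg <- c(msg, "childAssign must cover exactly the node samples")
  if (!all(object@childAssign %in% object@childLabels))
    msg <- c(msg, "childAssign values must be childLabels")
  cnt <- table(factor(object@childAssign, levels = object@childLabels))
  if (any(cnt < 2L))
    msg <- c(msg, sprintf("child(ren) with < 2 samples: %s",
                          paste(names(cnt)[cnt < 2L], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Reference bundle
#'
#' The complete classifier: one [ReferenceModel-class] per hierarchy node
#' plus the [SubtypeHierarchy-class] tying them together.
#'
#' @slot hierarchy the subtype hierarchy.
#' @slot models named list of `ReferenceModel`, one per hierarchy node.
#' @export
setClass("ReferenceBundle",
  representation(hierarchy = "SubtypeHierarchy", models = "list"))

setValidity("ReferenceBundle", function(object) {
  want <- names(object@hierarchy@nodes)
  if (!setequal(names(object@models), want))
    return("models must cover exactly the hierarchy nodes")
  if (!all(vapply(object@models, is, logical(1), class2 = "ReferenceModel")))
    return("all models must be ReferenceModel objects")
  TRUE
})

#' Single-node classification result
#'
#' Distances, membership probabilities and relative distances of one unknown
#' sample against every child subtype of one hierarchy node, plus the
#' first-three-component coordinates used for plotting.
#'
#' @slot nodeId hierarchy node identifier.
#' @slot distances named weighted Euclidean distances to child centroids.
#' @slot probabilities named inverse-distance membership probabilities
#'   (sum to 1).
#' @slot relativeDistances named distances in units of each child's own
#'   sample-to-centroid dispersion.
#' @slot assignedChild the child label with minimal distance.
#' @slot pc3 list with `unknown` (coordinates of the unknown), `reference`
#'   (coordinate matrix of the reference samples) and `labels` (their child
#'   labels) on the first up-to-three components.
#' @slot tied TRUE if the minimum distance was tied (first declared child
#'   wins).
#' @export
setClass("NodeResult",
  representation(nodeId = "character", distances = "numeric",
                 probabilities = "numeric", relativeDistances = "numeric",
                 assignedChild = "character", pc3 = "list", tied = "logical"))

setValidity("NodeResult", function(object) {
  msg <- character()
  if (abs(sum(object@probabilities) - 1) > 1e-9)
    msg <- c(msg, "probabilities must sum to 1")
  if (!identical(names(object@distances), names(object@probabilities)) ||
      !identical(names(object@distances), names(object@relativeDistances)))
    msg <- c(msg, "distance/probability/relative-distance names must agree")
  if (!object@assignedChild %in% names(object@distances))
    msg <- c(msg, "assignedChild must be one of the children")
  if (object@distances[[object@assignedChild]] >
        min(object@distances) + 1e-12)
    msg <- c(msg, "assignedChild must attain the minimum distance")
  if (length(msg)) msg else TRUE
})

#' Hierarchical prediction result
#'
#' The root-to-leaf classification of one unknown sample: one
#' [NodeResult-class] per visited node, the final leaf subtype, and the
#' outlier flag with the rule that produced it.
#'
#' @slot sampleId identifier of the unknown sample.
#' @slot nodeResults ordered list of `NodeResult` along the descent path.
#' @slot finalSubtype assigned leaf label.
#' @slot outlierFlag TRUE if the assigned child's relative distance exceeded
#'   the threshold at any level.
#' @slot outlierRule text of the rule applied.
#' @slot config echo of the run configuration (list).
#' @export
setClass("PredictionResult",
  representation(sampleId = "character", nodeResults = "list",
                 finalSubtype = "character", outlierFlag = "logical",
                 outlierRule = "character", config = "list"))

#' Synthetic cohort specification
#'
#' Parameters of the seeded Gaussian-cluster generator that emulates a
#' nested reference cohort: per-leaf sample count, classifier genes per
#' node, between-child mean shift (expression units, per classifier gene),
#' within-child noise standard deviation, background gene count and seed.
#'
#' @slot hierarchy the subtype hierarchy to emulate.
#' @slot nPerLeaf samples per leaf subtype (>= 2).
#' @slot genesPerNode classifier genes per hierarchy node (>= 2).
#' @slot deltaMu between-child per-gene mean shift, expression units (>= 0).
#' @slot sigmaE within-child noise standard deviation (> 0).
#' @slot nBackground non-classifier noise genes shared by all samples.
#' @slot seed integer random seed; the generator is fully reproducible.
#' @export
setClass("SimulationSpec",
  representation(hierarchy = "SubtypeHierarchy", nPerLeaf = "integer",
                 genesPerNode = "integer", deltaMu = "numeric",
                 sigmaE = "numeric", nBackground = "integer",
                 seed = "integer"))

setValidity("SimulationSpec", function(object) {
  msg <- character()
  if (object@nPerLeaf < 2L) msg <- c(msg, "nPerLeaf must be >= 2")
  if (object@genesPerNode < 2L) msg <- c(msg, "genesPerNode must be >= 2")
  if (object@deltaMu < 0) msg <- c(msg, "deltaMu must be >= 0")
  if (object@sigmaE <= 0) msg <- c(msg, "sigmaE must be > 0")
  if (object@nBackground < 0L) msg <- c(msg, "nBackground must be >= 0")
  m <- max(vapply(object@hierarchy@nodes, function(nd) length(nd$children),
                  integer(1)))
  if (object@genesPerNode < m)
    msg <- c(msg, "genesPerNode must be >= the widest node's child count")
  if (length(msg)) msg else TRUE
})

#' Evaluation report
#'
#' Per-node assignment accuracy with confusion tables, under either the
#' train-to-test or the leave-one-out protocol. Accuracy at a node is
#' computed only over samples whose true root-to-leaf path traverses that
#' node.
#'
#' @slot protocol `"train_test"` or `"loo"`.
#' @slot perNode named list (by node id) with components `confusion`
#'   (true x predicted child table), `accuracy` and `n`.
#' @slot nEvaluated number of samples evaluated.
#' @export
setClass("EvaluationReport",
  representation(protocol = "character", perNode = "list",
                 nEvaluated = "integer"))

setValidity("EvaluationReport", function(object) {
  for (nd in object@perNode) {
    tot <- sum(nd$confusion)
    acc <- if (tot > 0) sum(diag(nd$confusion)) / tot else NA_real_
    if (tot > 0 && abs(acc - nd$accuracy) > 1e-12)
      return("accuracy must equal trace(confusion)/sum(confusion)")
  }
  TRUE
})
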