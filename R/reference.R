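#' Build per-node reference models from a labeled cohort
#'
#' For every node of the hierarchy, collects the reference samples whose
#' leaf label falls under that node, rolls their leaf labels up to the
#' node's child labels, and stores the node's classifier-gene submatrix.
#' Principal-component centroids and dispersions are computed per
#' prediction (see [classifyNode()]), because in merge mode the basis
#' changes with every unknown sample.
#'
#' Classifier genes absent from the reference matrix are tolerated up to
#' `coverageThreshold` (as a fraction of the node's list) and dropped with
#' a warning; beyond the threshold a coverage error lists the missing
#' genes. Every child of every node must keep at least 2 samples so that
#' its distance dispersion is defined.
#'
#' @param reference a [LabeledReference-class].
#' @param hierarchy a [SubtypeHierarchy-class]; every reference label must
#'   be one of its leaves.
#' @param classifierSets named list (by node id) of classifier gene-id
#'   vectors.
#' @param coverageThreshold maximum tolerated fraction of missing
#'   classifier genes per node (default 0.05).
#' @return A [ReferenceBundle-class].
#' @seealso [classifyHierarchical()], [writeReferenceBundle()]
#' @export
buildReference <- function(reference, hierarchy, classifierSets,
                           coverageThreshold = 0.05) {
  stopifnot(is(reference, "LabeledReference"),
            is(hierarchy, "SubtypeHierarchy"))
  m <- exprsMatrix(reference)
  labels <- subtypeLabels(reference)
  leaves <- leafLabels(hierarchy)
  bad <- setdiff(unique(labels), leaves)
  if (length(bad))
    .stopLabel("reference label(s) not in hierarchy: %s; valid leaves: %s",
               paste(bad, collapse = ", "), paste(leaves, collapse = ", "))
  ids <- nodeIds(hierarchy)
  missingSets <- setdiff(ids, names(classifierSets))
  if (length(missingSets))
    .stopParameter("no classifier gene list for node(s): %s",
                   paste(missingSets, collapse = ", "))
  models <- lapply(ids, function(id) {
    genes <- .resolveGenes(classifierSets[[id]], rownames(m), id,
                           coverageThreshold)
    rollup <- leafToChildMap(hierarchy, id)
    inNode <- labels %in% names(rollup)
    samples <- names(labels)[inNode]
    childAssign <- setNames(unname(rollup[labels[inNode]]), samples)
    cls <- childLabels(hierarchy, id)
    cnt <- table(factor(childAssign, levels = cls))
    if (any(cnt < 2L))
      .stopBuild("node '%s': child(ren) with < 2 reference samples: %s",
                 id, paste(names(cnt)[cnt < 2L], collapse = ", "))
    new("ReferenceModel", nodeId = id, classifierGenes = genes,
        refMatrix = m[genes, samples, drop = FALSE],
        childLabels = cls, childAssign = childAssign)
  })
  names(models) <- ids
  new("ReferenceBundle", hierarchy = hierarchy, models = models)
}

# Coverage policy shared by build and predict: drop a small fraction of
# missing genes with a warning, error beyond the threshold.
.resolveGenes <- function(wanted, available, nodeId, coverageThreshold) {
  missing <- setdiff(wanted, available)
  frac <- length(missing) / length(wanted)
  if (length(missing)) {
    if (frac >= coverageThreshold)
      .stopCoverage(
        "node '%s': %d/%d classifier genes missing (>= %.0f%% threshold): %s",
        nodeId, length(missing), length(wanted), 100 * coverageThreshold,
        paste(missing, collapse = ", "))
    warning(sprintf(
      "node '%s': dropping %d missing classifier gene(s): %s", nodeId,
      length(missing), paste(missing, collapse = ", ")), call. = FALSE)
  }
  kept <- intersect(wanted, available)
  if (length(kept) < 2L)
    .stopCoverage("node '%s': fewer than 2 classifier genes available",
                  nodeId)
  kept
}

#' Centroid of PC-score rows
#'
#' Component-wise arithmetic mean of a set of sample score rows.
#'
#' @param scores numeric matrix (samples x components), >= 1 row.
#' @return numeric vector of column means.
#' @examples
#' scoreCentroid(rbind(c(0, 0), c(2, 2)))  # c(1, 1)
#' @export
scoreCentroid <- function(scores) {
  if (!is.matrix(scores)) scores <- rbind(scores)
  if (nrow(scores) < 1L) .stopParameter("centroid of an empty sample set")
  colMeans(scores)
}

#' @describeIn ReferenceBundle the hierarchy of a bundle.
#' @param bundle a `ReferenceBundle`.
#' @export
bundleHierarchy <- function(bundle) bundle@hierarchy

#' @describeIn ReferenceBundle the named list of per-node models.
#' @export
bundleModels <- function(bundle) bundle@models

#' @describeIn ReferenceModel node sample ids of a model.
#' @param model a `ReferenceModel`.
#' @export
modelSamples <- function(model) colnames(model@refMatrix)

#' @describeIn ReferenceModel sample-to-child-label roll-up of a model.
#' @export
modelChildAssign <- function(model) model@childAssign

setMethod("show", "ReferenceModel", function(object) {
  cnt <- table(factor(object@childAssign, levels = object@childLabels))
  cat("ReferenceModel '", object@nodeId, "': ",
      length(object@classifierGenes), " classifier genes, ",
      ncol(object@refMatrix), " samples (",
      paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "), ")\n",
      sep = "")
})

setMethod("show", "ReferenceBundle", function(object) {
  cat("ReferenceBundle with", length(object@models), "node models\n")
  for (m in object@models) show(m)
})

#' Serialize / load a reference bundle as JSON
#'
#' The bundle — hierarchy, classifier gene lists and the per-node
#' expression submatrices with child assignments — is stored in a single
#' self-contained JSON file, so a prediction run needs no other input
#' besides the unknown profile.
#'
#' @param bundle a [ReferenceBundle-class].
#' @param path destination file.
#' @return `writeReferenceBundle` returns `path` invisibly;
#'   `readReferenceBundle` returns the reconstructed bundle.
#' @export
writeReferenceBundle <- function(bundle, path) {
  payload <- list(
    format = "subtypePCA-reference-bundle",
    version = as.character(utils::packageVersion("subtypePCA")),
    hierarchy = .hierarchyToList(bundle@hierarchy),
    models = lapply(unname(bundle@models), function(m) list(
      nodeId = m@nodeId,
      classifierGenes = as.list(m@classifierGenes),
      childLabels = as.list(m@childLabels),
      samples = as.list(colnames(m@refMatrix)),
      childAssign = as.list(unname(m@childAssign[colnames(m@refMatrix)])),
      values = lapply(seq_len(nrow(m@refMatrix)), function(i)
        as.list(unname(m@refMatrix[i, ]))))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeReferenceBundle
#' @export
readReferenceBundle <- function(path) {
  if (!file.exists(path)) .stopFormat("file not found: %s", path)
  x <- jsonlite::read_json(path)
  if (!identical(x$format, "subtypePCA-reference-bundle"))
    .stopFormat("not a reference bundle: %s", path)
  hierarchy <- .hierarchyFromList(x$hierarchy)
  models <- lapply(x$models, function(m) {
    genes <- unlist(m$classifierGenes)
    samples <- unlist(m$samples)
    refMatrix <- do.call(rbind, lapply(m$values, function(v)
      vapply(v, as.numeric, numeric(1))))
    dimnames(refMatrix) <- list(genes, samples)
    new("ReferenceModel", nodeId = m$nodeId,
        classifierGenes = genes, refMatrix = refMatrix,
        childLabels = unlist(m$childLabels),
        childAssign = setNames(unlist(m$childAssign), samples))
  })
  names(models) <- vapply(models, function(m) m@nodeId, character(1))
  new("ReferenceBundle", hierarchy = hierarchy, models = models)
}
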