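#' Train-to-test evaluation of per-node assignment accuracy
#'
#' Builds a reference bundle from the training cohort and classifies every
#' test sample at every node its true root-to-leaf path traverses (so a
#' sample whose true leaf is under O never enters the G node's accuracy,
#' mirroring per-level accuracy tables). Per node, the confusion table of
#' true versus predicted child labels is accumulated and accuracy is its
#' trace over its total.
#'
#' @param train,test [LabeledReference-class] cohorts with disjoint sample
#'   ids.
#' @param hierarchy a [SubtypeHierarchy-class].
#' @param classifierSets named list of per-node classifier gene vectors.
#' @inheritParams classifyNode
#' @return An [EvaluationReport-class] with protocol `"train_test"`.
#' @export
evaluateTrainTest <- function(train, test, hierarchy, classifierSets,
                              mode = c("merge", "project"),
                              nComponents = "all",
                              sigmaDivisor = c("n", "n-1"),
                              coverageThreshold = 0.05) {
  mode <- match.arg(mode)
  sigmaDivisor <- match.arg(sigmaDivisor)
  if (ncol(test) == 0L) .stopParameter("test cohort is empty")
  overlap <- intersect(colnames(train), colnames(test))
  if (length(overlap))
    .stopParameter("train and test sample ids overlap: %s",
                   paste(head(overlap, 5L), collapse = ", "))
  bundle <- buildReference(train, hierarchy, classifierSets,
                           coverageThreshold)
  .evaluateAgainst(bundle, test, mode, nComponents, sigmaDivisor,
                   coverageThreshold, protocol = "train_test",
                   holdout = FALSE)
}

#' Leave-one-out evaluation of per-node assignment accuracy
#'
#' Each reference sample is held out in turn and classified, at every node
#' on its true path, against a reference from which it has been removed:
#' the held-out sample never contributes to the basis (in project mode),
#' centroids or dispersions of its own prediction. Every child must keep
#' at least 2 samples after the holdout.
#'
#' @param reference a [LabeledReference-class].
#' @inheritParams evaluateTrainTest
#' @return An [EvaluationReport-class] with protocol `"loo"`.
#' @export
evaluateLOO <- function(reference, hierarchy, classifierSets,
                        mode = c("merge", "project"), nComponents = "all",
                        sigmaDivisor = c("n", "n-1"),
                        coverageThreshold = 0.05) {
  mode <- match.arg(mode)
  sigmaDivisor <- match.arg(sigmaDivisor)
  bundle <- buildReference(reference, hierarchy, classifierSets,
                           coverageThreshold)
  .evaluateAgainst(bundle, reference, mode, nComponents, sigmaDivisor,
                   coverageThreshold, protocol = "loo", holdout = TRUE)
}

# Shared walker: classify each evaluation sample at every node on its true
# path; with holdout = TRUE the sample is first removed from the node model.
.evaluateAgainst <- function(bundle, cohort, mode, nComponents,
                             sigmaDivisor, coverageThreshold, protocol,
                             holdout) {
  hierarchy <- bundle@hierarchy
  m <- exprsMatrix(cohort)
  labels <- subtypeLabels(cohort)
  leaves <- leafLabels(hierarchy)
  bad <- setdiff(unique(labels), leaves)
  if (length(bad))
    .stopLabel("evaluation label(s) not in hierarchy: %s",
               paste(bad, collapse = ", "))
  ids <- nodeIds(hierarchy)
  confusion <- lapply(ids, function(id) {
    cls <- childLabels(hierarchy, id)
    table(factor(character(), levels = cls),
          factor(character(), levels = cls), dnn = c("true", "predicted"))
  })
  names(confusion) <- ids
  for (s in colnames(m)) {
    u <- m[, s]
    for (id in pathToLeaf(hierarchy, labels[[s]])) {
      model <- bundle@models[[id]]
      trueChild <- leafToChildMap(hierarchy, id)[[labels[[s]]]]
      if (holdout) model <- .dropSample(model, s)
      nr <- suppressWarnings(
        classifyNode(model, u, mode = mode, nComponents = nComponents,
                     sigmaDivisor = sigmaDivisor,
                     coverageThreshold = coverageThreshold, sampleId = s))
      cls <- childLabels(hierarchy, id)
      confusion[[id]] <- confusion[[id]] +
        table(factor(trueChild, levels = cls),
              factor(nr@assignedChild, levels = cls),
              dnn = c("true", "predicted"))
    }
  }
  perNode <- lapply(ids, function(id) {
    conf <- confusion[[id]]
    n <- sum(conf)
    list(confusion = conf,
         accuracy = if (n > 0) sum(diag(conf)) / n else NA_real_,
         n = as.integer(n))
  })
  names(perNode) <- ids
  new("EvaluationReport", protocol = protocol, perNode = perNode,
      nEvaluated = ncol(m))
}

.dropSample <- function(model, sampleId) {
  keep <- setdiff(colnames(model@refMatrix), sampleId)
  if (length(keep) == ncol(model@refMatrix)) return(model)
  assign <- model@childAssign[keep]
  cnt <- table(factor(assign, levels = model@childLabels))
  if (any(cnt < 2L))
    .stopBuild(
      "holding out '%s' leaves child(ren) of node '%s' with < 2 samples: %s",
      sampleId, model@nodeId,
      paste(names(cnt)[cnt < 2L], collapse = ", "))
  new("ReferenceModel", nodeId = model@nodeId,
      classifierGenes = model@classifierGenes,
      refMatrix = model@refMatrix[, keep, drop = FALSE],
      childLabels = model@childLabels, childAssign = assign)
}

#' @describeIn evaluateTrainTest named vector of per-node accuracies from a
#'   report.
#' @param report an `EvaluationReport`.
#' @export
nodeAccuracies <- function(report)
  vapply(report@perNode, `[[`, numeric(1), "accuracy")

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport (", object@protocol, "), ", object@nEvaluated,
      " samples\n", sep = "")
  for (id in names(object@perNode)) {
    nd <- object@perNode[[id]]
    cat(sprintf("  %-6s accuracy %.3f (n = %d)\n", id, nd$accuracy, nd$n))
  }
})

#' Serialize an evaluation report
#'
#' @param report an [EvaluationReport-class].
#' @param path destination JSON file.
#' @return `path`, invisibly.
#' @export
writeEvaluationJSON <- function(report, path) {
  payload <- list(
    protocol = report@protocol,
    nEvaluated = report@nEvaluated,
    perNode = lapply(report@perNode, function(nd) list(
      accuracy = nd$accuracy, n = nd$n,
      children = rownames(nd$confusion),
      confusion = apply(unclass(nd$confusion), 1L, as.list,
                        simplify = FALSE))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
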